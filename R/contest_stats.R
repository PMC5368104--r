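#' Formula 1 score
#'
#' Sum over challenges of motorsport-style points for the rounded rank of the
#' correct candidate: ranks 1–10 earn 25, 18, 15, 12, 10, 8, 6, 4, 2, 1
#' points; ranks above 10 and missing ranks earn nothing.
#'
#' @param rounded_rank integer vector of rounded ranks (`NA` = missing).
#' @return integer score.
#' @examples
#' formula1_score(c(1, 2, 3)) # 58
#' @export
formula1_score <- function(rounded_rank) {
  weights <- c(25L, 18L, 15L, 12L, 10L, 8L, 6L, 4L, 2L, 1L)
  r <- rounded_rank[!is.na(rounded_rank) & rounded_rank >= 1 & rounded_rank <= 10]
  sum(weights[r])
}

#' Medal score
#'
#' Weighted Top-3 count: 5 points per rounded rank 1 (gold), 3 per rank 2
#' (silver), 1 per rank 3 (bronze). Distinct from the per-challenge gold-medal
#' tally that declares the contest winner.
#'
#' @inheritParams formula1_score
#' @return integer score.
#' @examples
#' medal_score(c(1, 2, 3, 10)) # 9
#' @export
medal_score <- function(rounded_rank) {
  weights <- c(5L, 3L, 1L)
  r <- rounded_rank[!is.na(rounded_rank) & rounded_rank >= 1 & rounded_rank <= 3]
  sum(weights[r])
}

#' Per-entry statistic panel
#'
#' Computes, for every entry in a rank table, the counts and location
#' statistics used to compare contest entries: Top 1/3/10 counts (on rounded
#' ranks), Top-1 counts split by ion mode, mean/median rank and RRP, rank
#' quantiles (Q10, Q25, Q50, Q75, Q90; linear interpolation between order
#' statistics), Formula 1 and Medal scores, and — when several entries are
#' present — per-challenge gold/silver/bronze medal counts from
#' [assign_medals()].
#'
#' Missing ranks are excluded from means, medians and quantiles by default;
#' `missing_rank = "candidate_count"` instead substitutes the official
#' candidate count (the rank-matrix display convention), for which
#' `candidate_counts` must be supplied.
#'
#' @param ranks tibble from [rank_correct()] with an `entry` column.
#' @param modes optional tibble (`challenge_id`, `ion_mode`) for the
#'   positive/negative Top-1 split; a solution table works as-is.
#' @param missing_rank how missing ranks enter location statistics.
#' @param candidate_counts tibble (`challenge_id`, `n_candidates`) with the
#'   official per-challenge candidate counts, required for substitution.
#' @param medal_ties passed to [assign_medals()].
#' @return one-row-per-entry tibble.
#' @export
summarize_entries <- function(ranks, modes = NULL,
                              missing_rank = c("exclude", "candidate_count"),
                              candidate_counts = NULL,
                              medal_ties = c("competition", "dense")) {
  missing_rank <- match.arg(missing_rank)
  if (nrow(ranks) == 0L) abort("Empty rank table.")
  if (missing_rank == "candidate_count") {
    if (is.null(candidate_counts)) {
      abort("`candidate_counts` is required when missing_rank = 'candidate_count'.")
    }
    ranks <- ranks |>
      dplyr::left_join(
        dplyr::select(candidate_counts, "challenge_id",
          official_n = "n_candidates"
        ),
        by = "challenge_id"
      ) |>
      dplyr::mutate(
        average_rank = dplyr::coalesce(.data$average_rank, .data$official_n),
        rounded_rank = dplyr::coalesce(
          .data$rounded_rank, as.integer(.data$official_n)
        )
      )
  }
  if (!is.null(modes)) {
    ranks <- dplyr::left_join(
      ranks, dplyr::select(modes, "challenge_id", "ion_mode"),
      by = "challenge_id"
    )
  } else {
    ranks$ion_mode <- NA_character_
  }

  panel <- ranks |>
    dplyr::summarise(
      .by = "entry",
      n_challenges = dplyr::n(),
      n_ranked = sum(!is.na(.data$average_rank)),
      top1 = sum(.data$rounded_rank == 1L, na.rm = TRUE),
      top3 = sum(.data$rounded_rank <= 3L, na.rm = TRUE),
      top10 = sum(.data$rounded_rank <= 10L, na.rm = TRUE),
      top1_pos = sum(.data$rounded_rank == 1L & .data$ion_mode == "positive",
        na.rm = TRUE
      ),
      top1_neg = sum(.data$rounded_rank == 1L & .data$ion_mode == "negative",
        na.rm = TRUE
      ),
      mean_rank = mean(.data$average_rank, na.rm = TRUE),
      median_rank = stats::median(.data$average_rank, na.rm = TRUE),
      mean_rrp = mean(.data$rrp, na.rm = TRUE),
      median_rrp = stats::median(.data$rrp, na.rm = TRUE),
      q10 = rank_quantile(.data$average_rank, 0.10),
      q25 = rank_quantile(.data$average_rank, 0.25),
      q50 = rank_quantile(.data$average_rank, 0.50),
      q75 = rank_quantile(.data$average_rank, 0.75),
      q90 = rank_quantile(.data$average_rank, 0.90),
      formula1 = formula1_score(.data$rounded_rank),
      medal_score = medal_score(.data$rounded_rank)
    )

  if (dplyr::n_distinct(ranks$entry) > 1L) {
    board <- assign_medals(ranks, ties = medal_ties)
    counts <- board |>
      dplyr::filter(.data$medal != "none") |>
      dplyr::count(.data$entry, .data$medal) |>
      tidyr::pivot_wider(
        names_from = "medal", values_from = "n", values_fill = 0L
      )
    for (m in c("gold", "silver", "bronze")) {
      if (!m %in% names(counts)) counts[[m]] <- 0L
    }
    panel <- panel |>
      dplyr::left_join(
        dplyr::select(counts, "entry", "gold", "silver", "bronze"),
        by = "entry"
      ) |>
      dplyr::mutate(dplyr::across(
        c("gold", "silver", "bronze"),
        \(x) dplyr::coalesce(x, 0L)
      ))
  }
  panel
}

rank_quantile <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  unname(stats::quantile(x, p, type = 7))
}

#' Assign per-challenge medals
#'
#' For each challenge, gold goes to the entry (or entries, joint positions are
#' possible in case of ties) with the lowest average rank among all entries —
#' so a winner exists even when nobody ranked the correct candidate Top 1.
#' With competition-style tie handling (default), joint medals skip the
#' following positions: after two joint golds the next distinct rank receives
#' bronze. `ties = "dense"` instead awards gold/silver/bronze to the first
#' three distinct ranks regardless of group sizes.
#'
#' Entries with a missing rank count as worst and never medal; a challenge
#' where every entry is missing awards nothing.
#'
#' @param ranks tibble from [rank_correct()] with `entry`, `challenge_id`,
#'   `average_rank`.
#' @param ties medal position convention after joint medals.
#' @return tibble (`challenge_id`, `entry`, `average_rank`, `medal`) where
#'   `medal` is one of `"gold"`, `"silver"`, `"bronze"`, `"none"`.
#' @export
assign_medals <- function(ranks, ties = c("competition", "dense")) {
  ties <- match.arg(ties)
  ranks |>
    dplyr::mutate(
      .by = "challenge_id",
      medal = medal_for_ranks(.data$average_rank, ties)
    ) |>
    dplyr::select("challenge_id", "entry", "average_rank", "medal") |>
    dplyr::arrange(.data$challenge_id, .data$average_rank)
}

medal_for_ranks <- function(avg_rank, ties) {
  medal <- rep("none", length(avg_rank))
  ok <- !is.na(avg_rank)
  if (!any(ok)) return(medal)
  r <- avg_rank[ok]
  position <- if (ties == "competition") {
    rank(r, ties.method = "min")
  } else {
    match(r, sort(unique(r)))
  }
  medal[ok] <- dplyr::case_match(
    position,
    1L ~ "gold", 2L ~ "silver", 3L ~ "bronze",
    .default = "none"
  )
  medal
}

#' Olympic medal tally
#'
#' Orders entries by gold count, breaking ties by silver then bronze counts —
#' the scheme used to declare the overall contest winner. When an
#' entry-to-participant mapping is given, the best overall performing
#' submission per participant can be selected, since only that one counts in
#' declaring winners.
#'
#' @param board medal board from [assign_medals()].
#' @param participants optional tibble (`entry`, `participant`).
#' @param best_per_participant keep only each participant's best entry
#'   (requires `participants`).
#' @return tibble of standings: `entry`, `gold`, `silver`, `bronze`,
#'   `position` (competition-ranked), plus `participant` when mapped.
#' @export
olympic_tally <- function(board, participants = NULL,
                          best_per_participant = FALSE) {
  tally <- board |>
    dplyr::summarise(
      .by = "entry",
      gold = sum(.data$medal == "gold"),
      silver = sum(.data$medal == "silver"),
      bronze = sum(.data$medal == "bronze")
    ) |>
    dplyr::arrange(
      dplyr::desc(.data$gold), dplyr::desc(.data$silver),
      dplyr::desc(.data$bronze)
    )
  if (!is.null(participants)) {
    tally <- dplyr::left_join(tally, participants, by = "entry")
    if (best_per_participant) {
      tally <- dplyr::slice_head(tally, n = 1L, by = "participant")
    }
  } else if (best_per_participant) {
    abort("`best_per_participant` needs a `participants` mapping.")
  }
  key <- -(tally$gold * 1e8 + tally$silver * 1e4 + tally$bronze)
  tally$position <- rank(key, ties.method = "min")
  tally
}

#' Restrict challenges to those in no method's training set
#'
#' Machine-learning entries may have seen some challenge compounds during
#' training; for a like-for-like comparison, the contest can be re-evaluated
#' on only those challenges whose solution appears in no participant's
#' training set (a "global leave-out" analysis).
#'
#' @param solutions solution table with `solution_skeleton` (or
#'   `solution_key`) and optionally `ion_mode`.
#' @param training_key_lists list of character vectors of training structures
#'   (full InChIKeys or skeleton keys), one per participant.
#' @return the subset of `solutions` whose skeleton occurs in no list; a
#'   message reports retained counts per ion mode when available.
#' @export
filter_leaveout <- function(solutions, training_key_lists) {
  if (!"solution_skeleton" %in% names(solutions)) {
    solutions <- dplyr::mutate(
      solutions,
      solution_skeleton = extract_skeleton(.data$solution_key)
    )
  }
  keys <- as.character(unlist(training_key_lists, use.names = FALSE))
  seen <- if (length(keys)) unique(extract_skeleton(keys)) else character()
  keep <- !solutions$solution_skeleton %in% seen
  out <- solutions[keep, ]
  if ("ion_mode" %in% names(out)) {
    n <- table(out$ion_mode)
    inform(paste0(
      "Leave-out subset: ", nrow(out), " challenge(s) retained (",
      paste(paste0(n, " ", names(n)), collapse = ", "), ")."
    ))
  }
  out
}
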