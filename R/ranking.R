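#' Collapse stereoisomers to their highest-scoring representative
#'
#' Candidates are grouped on the skeleton key (first InChIKey block, constant
#' across stereoisomers) and the highest score in each group is retained, since
#' the analytical methods being benchmarked cannot distinguish stereoisomers.
#'
#' @param submission tibble with `skeleton` and `score` columns, plus any of
#'   `entry` / `challenge_id`, which are preserved as grouping keys.
#' @return tibble with one row per (`entry`, `challenge_id`, `skeleton`) and
#'   the maximum `score` over its stereoisomers.
#' @examples
#' sub <- tibble::tibble(
#'   skeleton = c("AAAAAAAAAAAAAA", "AAAAAAAAAAAAAA", "BBBBBBBBBBBBBB"),
#'   score = c(0.7, 0.9, 0.5)
#' )
#' collapse_stereo(sub)
#' @export
collapse_stereo <- function(submission) {
  keys <- intersect(c("entry", "challenge_id", "skeleton"), names(submission))
  if (!"skeleton" %in% keys || !"score" %in% names(submission)) {
    abort("`submission` needs `skeleton` and `score` columns.")
  }
  submission |>
    dplyr::summarise(
      score = max(.data$score),
      .by = dplyr::all_of(keys)
    )
}

#' Tie-averaged rank of the correct candidate
#'
#' For each (`entry`, `challenge_id`) group of a collapsed submission, the
#' correct candidate's rank is computed by score (higher is better). When two
#' or more candidates share the correct candidate's score, the average rank
#' over all equally scored candidates is taken: with `B` candidates scoring
#' strictly higher and `t` candidates (including the correct one) sharing the
#' score, the average rank is `B + (t + 1) / 2`. The rounded rank — used for
#' Top-X, Formula 1 and Medal scores — rounds non-integer average ranks up
#' (rank 1.5 counts as 2).
#'
#' A challenge whose solution skeleton is absent from the submission, or with
#' no submission at all, gets a missing rank (`NA`); missing ranks are never
#' imputed here and are handled explicitly downstream (worst-case at medal
#' time, candidate-count substitution in the rank-matrix display).
#'
#' @param collapsed tibble from [collapse_stereo()] with `challenge_id`,
#'   `skeleton`, `score` (and optionally `entry`).
#' @param solutions tibble with `challenge_id` and `solution_skeleton` (full
#'   `solution_key` also accepted).
#' @param universe optional official candidate table (`challenge_id`,
#'   `skeleton`); with `strict = TRUE`, submitted skeletons outside it abort.
#' @param strict reject submitted candidates not in `universe`.
#' @param tie_epsilon scores within this absolute tolerance count as tied
#'   (default 0, exact equality of parsed values).
#' @return tibble with one row per entry and challenge: `entry`,
#'   `challenge_id`, `average_rank`, `rounded_rank`, `n_candidates`, `rrp`,
#'   `missing`. Challenges present in `solutions` but not in the submission
#'   appear with `missing = TRUE`.
#' @examples
#' col <- tibble::tibble(
#'   challenge_id = "c1",
#'   skeleton = c("AAAAAAAAAAAAAA", "BBBBBBBBBBBBBB", "CCCCCCCCCCCCCC"),
#'   score = c(10, 10, 1)
#' )
#' sol <- tibble::tibble(challenge_id = "c1", solution_skeleton = "AAAAAAAAAAAAAA")
#' rank_correct(col, sol) # average rank 1.5, rounded rank 2
#' @export
rank_correct <- function(collapsed, solutions, universe = NULL, strict = FALSE,
                         tie_epsilon = 0) {
  if (!"solution_skeleton" %in% names(solutions)) {
    solutions <- dplyr::mutate(
      solutions,
      solution_skeleton = extract_skeleton(.data$solution_key)
    )
  }
  has_entry <- "entry" %in% names(collapsed)
  if (!has_entry) collapsed$entry <- NA_character_
  if (strict && !is.null(universe)) {
    foreign <- dplyr::anti_join(
      collapsed, universe,
      by = c("challenge_id", "skeleton")
    )
    if (nrow(foreign) > 0L) {
      validation_error(paste0(
        nrow(foreign),
        " submitted candidate(s) are not in the official candidate list",
        " (strict mode)."
      ))
    }
  }

  sol <- dplyr::select(solutions, "challenge_id", "solution_skeleton")
  ranked <- collapsed |>
    dplyr::inner_join(sol, by = "challenge_id") |>
    dplyr::summarise(
      .by = c("entry", "challenge_id"),
      n_candidates = dplyr::n(),
      average_rank = {
        correct <- .data$skeleton == .data$solution_skeleton
        if (!any(correct)) {
          NA_real_
        } else {
          s0 <- .data$score[correct][1L]
          b <- sum(.data$score > s0 + tie_epsilon)
          t <- sum(abs(.data$score - s0) <= tie_epsilon)
          b + (t + 1) / 2
        }
      }
    )

  # challenges in the solution table with no submitted candidates at all
  entries <- unique(collapsed$entry)
  full <- tidyr::expand_grid(
    entry = entries,
    challenge_id = unique(sol$challenge_id)
  )
  ranked <- dplyr::left_join(full, ranked, by = c("entry", "challenge_id"))

  out <- ranked |>
    dplyr::mutate(
      missing = is.na(.data$average_rank),
      rounded_rank = as.integer(ceiling(.data$average_rank)),
      rrp = rrp(.data$average_rank, .data$n_candidates)
    ) |>
    dplyr::select(
      "entry", "challenge_id", "average_rank", "rounded_rank",
      "n_candidates", "rrp", "missing"
    )
  if (!has_entry) out$entry <- NULL
  out
}

#' Relative ranking position
#'
#' Normalises a rank to `[0, 1]` so entries are comparable across candidate
#' lists of different sizes: `rrp = (tc - rank) / (tc - 1)`, where `tc` is the
#' number of (stereo-collapsed) candidates. 1 means the correct candidate was
#' ranked best possible, 0 worst possible. A single-candidate list returns 1.
#'
#' @param rank average (tie-averaged) rank, `1 <= rank <= tc`.
#' @param tc total number of collapsed candidates.
#' @return numeric vector in `[0, 1]`.
#' @export
rrp <- function(rank, tc) {
  n <- max(length(rank), length(tc))
  rank <- rep_len(rank, n)
  tc <- rep_len(tc, n)
  bad <- !is.na(rank) & !is.na(tc) & (rank > tc | rank < 1)
  if (any(bad)) {
    abort("`rank` must lie in [1, tc].")
  }
  out <- (tc - rank) / (tc - 1)
  out[!is.na(tc) & tc == 1] <- 1
  out
}
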