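#' Evaluate a contest end to end
#'
#' Runs the full pipeline on a submissions table: stereoisomer collapse,
#' tie-averaged ranking of the correct candidate, per-entry statistic panel,
#' per-challenge medal board and Olympic tally. This is the single source of
#' truth the reporting layer writes out; no statistic is recomputed elsewhere.
#'
#' @param submissions tibble in the [read_submission()] layout (several
#'   entries and challenges stacked).
#' @param solutions solution table (see [read_solutions()]).
#' @param modes optional (`challenge_id`, `ion_mode`) table; defaults to
#'   `solutions` when it carries `ion_mode`.
#' @param tie_epsilon passed to [rank_correct()].
#' @param medal_ties passed to [assign_medals()].
#' @param participants,best_per_participant passed to [olympic_tally()].
#' @return object of class `contest_evaluation`: list with `ranks`, `summary`,
#'   `medals`, `tally`.
#' @export
evaluate_contest <- function(submissions, solutions, modes = NULL,
                             tie_epsilon = 0,
                             medal_ties = c("competition", "dense"),
                             participants = NULL,
                             best_per_participant = FALSE) {
  medal_ties <- match.arg(medal_ties)
  if (is.null(modes) && "ion_mode" %in% names(solutions)) modes <- solutions
  collapsed <- collapse_stereo(submissions)
  ranks <- rank_correct(collapsed, solutions, tie_epsilon = tie_epsilon)
  summary <- summarize_entries(ranks, modes = modes, medal_ties = medal_ties)
  medals <- assign_medals(ranks, ties = medal_ties)
  tally <- olympic_tally(
    medals,
    participants = participants,
    best_per_participant = best_per_participant
  )
  structure(
    list(ranks = ranks, summary = summary, medals = medals, tally = tally),
    class = "contest_evaluation"
  )
}

#' @export
print.contest_evaluation <- function(x, ...) {
  cat(sprintf(
    "<contest_evaluation: %d entries on %d challenge(s)>\n",
    dplyr::n_distinct(x$ranks$entry),
    dplyr::n_distinct(x$ranks$challenge_id)
  ))
  cols <- intersect(
    c("entry", "top1", "top3", "top10", "gold", "silver", "bronze",
      "formula1", "medal_score"),
    names(x$summary)
  )
  print(x$summary[, cols])
  invisible(x)
}

#' Build the rank matrix used for heat-map displays
#'
#' One row per entry, one column per challenge. Missing ranks (correct
#' solution missed, or no submission) are replaced by the challenge's official
#' candidate count, and all values are log10-scaled, so rank 1 maps to 0 and a
#' miss among 1000 candidates maps to 3.
#'
#' @param ranks rank table from [rank_correct()].
#' @param candidate_counts tibble (`challenge_id`, `n_candidates`) with
#'   official per-challenge candidate counts used for substitution.
#' @param modes optional (`challenge_id`, `ion_mode`) annotation.
#' @return object of class `rank_matrix`: long tibble (`entry`,
#'   `challenge_id`, `rank`, `display`, `substituted`, `ion_mode`); use
#'   [as.matrix()] for the wide entries-by-challenges form.
#' @export
build_rank_matrix <- function(ranks, candidate_counts, modes = NULL) {
  long <- ranks |>
    dplyr::left_join(
      dplyr::select(candidate_counts, "challenge_id",
        official_n = "n_candidates"
      ),
      by = "challenge_id"
    ) |>
    dplyr::mutate(
      substituted = is.na(.data$average_rank),
      value = dplyr::coalesce(.data$average_rank, .data$official_n),
      display = log10(.data$value)
    ) |>
    dplyr::select(
      "entry", "challenge_id",
      rank = "average_rank", "display", "substituted"
    )
  if (!is.null(modes)) {
    long <- dplyr::left_join(
      long, dplyr::select(modes, "challenge_id", "ion_mode"),
      by = "challenge_id"
    )
  } else {
    long$ion_mode <- NA_character_
  }
  if (anyNA(long$display)) {
    abort("Every (entry, challenge) cell needs a rank or a candidate count.")
  }
  structure(long, class = c("rank_matrix", class(long)))
}

#' @export
as.matrix.rank_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[, c("entry", "challenge_id", "display")],
    names_from = "challenge_id", values_from = "display"
  )
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$entry
  m
}

#' Write a rank matrix loss-free to CSV
#'
#' Writes the long table (every cell's raw rank, display value and
#' substitution flag) plus a wide entries-by-challenges matrix of display
#' values.
#'
#' @param x a `rank_matrix`.
#' @param path base path; `<path>_long.csv` and `<path>_wide.csv` are written.
#' @return the two paths, invisibly.
#' @export
write_rank_matrix <- function(x, path) {
  long_path <- paste0(path, "_long.csv")
  wide_path <- paste0(path, "_wide.csv")
  readr::write_csv(tibble::as_tibble(x), long_path)
  m <- as.matrix(x)
  readr::write_csv(
    dplyr::bind_cols(
      tibble::tibble(entry = rownames(m)),
      tibble::as_tibble(m)
    ),
    wide_path
  )
  invisible(c(long_path, wide_path))
}

#' Heat-map display of a rank matrix
#'
#' Tiles coloured from good (low log-rank, blue) to poor (red); substituted
#' cells (missing rank shown as candidate count) are outlined.
#'
#' @param object a `rank_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.rank_matrix <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(
      x = .data$challenge_id, y = .data$entry, fill = .data$display
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = \(d) d[d$substituted, ],
      colour = "grey20", linewidth = 0.3
    ) +
    ggplot2::scale_fill_gradient(
      low = "#2166ac", high = "#b2182b", name = "log10 rank"
    ) +
    ggplot2::labs(x = "challenge", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Medal-tally bar chart
#'
#' @param tally standings from [olympic_tally()].
#' @return a ggplot object.
#' @export
plot_medal_tally <- function(tally) {
  long <- tidyr::pivot_longer(
    tally[, c("entry", "gold", "silver", "bronze")],
    cols = c("gold", "silver", "bronze"),
    names_to = "medal", values_to = "count"
  )
  long$medal <- factor(long$medal, levels = c("gold", "silver", "bronze"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = stats::reorder(.data$entry, .data$count, sum),
      y = .data$count, fill = .data$medal
    )
  ) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(
      values = c(gold = "#d4af37", silver = "#a8a9ad", bronze = "#a97142")
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "medals") +
    ggplot2::theme_minimal()
}
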