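#' Normalise scores to the per-challenge maximum
#'
#' Divides every score by the maximum score of its challenge (and entry, if
#' present), giving values in `[0, 1]` so heterogeneous scoring scales become
#' commensurable before weighting. Division preserves each component's
#' candidate ordering. An all-zero challenge is returned unchanged.
#'
#' @param collapsed tibble with `challenge_id`, `skeleton`, `score` (and
#'   optionally `entry`).
#' @return the same tibble with normalised scores.
#' @export
normalize_scores <- function(collapsed) {
  keys <- intersect(c("entry", "challenge_id"), names(collapsed))
  collapsed |>
    dplyr::mutate(
      .by = dplyr::all_of(keys),
      score = if (max(.data$score) > 0) .data$score / max(.data$score) else .data$score
    )
}

#' Combine scored submissions into a consensus submission
#'
#' Builds the per-challenge union of candidates over all components, fills a
#' candidate missing from a component with `missing_value` (default 0, so
#' absence is penalised but not excluding), and returns the weighted sum of
#' (optionally max-normalised) component scores. Equal weighting of several
#' independent fragmenter scores is the classic consensus ("combined")
#' submission.
#'
#' @param components named list of collapsed submissions (tibbles with
#'   `challenge_id`, `skeleton`, `score`).
#' @param weights numeric vector of non-negative weights, recycled names from
#'   `components`; default equal weights. At least one must be positive.
#' @param normalization `"max"` (per-challenge max division, default) or
#'   `"none"`.
#' @param missing_value score contributed by a component lacking a candidate.
#' @param entry_name value of the `entry` column of the result.
#' @return collapsed-submission tibble (`entry`, `challenge_id`, `skeleton`,
#'   `score`).
#' @export
combine_submissions <- function(components, weights = NULL,
                                normalization = c("max", "none"),
                                missing_value = 0,
                                entry_name = "combined") {
  normalization <- match.arg(normalization)
  if (is.null(names(components)) || any(names(components) == "")) {
    names(components) <- paste0("component_", seq_along(components))
  }
  weights <- weights %||% rep(1, length(components))
  if (length(weights) != length(components)) {
    abort("`weights` must have one value per component.")
  }
  if (any(!is.finite(weights)) || any(weights < 0) || all(weights == 0)) {
    abort("Weights must be finite, non-negative, and not all zero.")
  }
  if (normalization == "max") {
    components <- purrr::map(components, normalize_scores)
  }
  long <- purrr::imap(components, \(x, nm) {
    dplyr::mutate(
      dplyr::select(x, "challenge_id", "skeleton", "score"),
      component = nm
    )
  }) |>
    dplyr::bind_rows()
  wtbl <- tibble::tibble(component = names(components), weight = weights)
  long |>
    tidyr::pivot_wider(
      names_from = "component", values_from = "score",
      values_fill = missing_value, values_fn = max
    ) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(names(components)),
      names_to = "component", values_to = "score"
    ) |>
    dplyr::left_join(wtbl, by = "component") |>
    dplyr::summarise(
      score = sum(.data$score * .data$weight),
      .by = c("challenge_id", "skeleton")
    ) |>
    dplyr::mutate(entry = entry_name, .before = 1L)
}

#' Literature reference-count score
#'
#' Scores every candidate by its literature reference count (identity
#' mapping): heavily referenced compounds rank first. A surprisingly strong
#' baseline, since contest compounds tend to be well-known chemicals.
#'
#' @param candidates candidate tibble with `challenge_id`, `skeleton`,
#'   `reference_count`.
#' @param entry_name value of the `entry` column of the result.
#' @return collapsed-submission tibble; absent counts score 0 with a warning.
#' @export
refs_score <- function(candidates, entry_name = "Refs") {
  if (anyNA(candidates$reference_count)) {
    warn("Candidates without a reference count scored 0.")
  }
  candidates |>
    dplyr::mutate(score = dplyr::coalesce(.data$reference_count, 0)) |>
    dplyr::summarise(
      score = max(.data$score),
      .by = c("challenge_id", "skeleton")
    ) |>
    dplyr::mutate(entry = entry_name, .before = 1L)
}

#' Lowest-database-identifier score
#'
#' Old database records tend to be common, well-studied compounds, so the
#' lowest identifier is taken as the best candidate. To fit the non-negative,
#' higher-is-better score contract the identifier is mapped through `1/id`;
#' any strictly decreasing transform induces the same ranking.
#'
#' @param candidates candidate tibble with `challenge_id`, `skeleton`,
#'   `identifier` (positive integers).
#' @param entry_name value of the `entry` column of the result.
#' @return collapsed-submission tibble.
#' @export
lowest_id_score <- function(candidates, entry_name = "Lowest_ID") {
  if (any(candidates$identifier <= 0, na.rm = TRUE) ||
    anyNA(candidates$identifier)) {
    validation_error("Candidate identifiers must be positive integers.")
  }
  candidates |>
    dplyr::mutate(score = 1 / .data$identifier) |>
    dplyr::summarise(
      score = max(.data$score),
      .by = c("challenge_id", "skeleton")
    ) |>
    dplyr::mutate(entry = entry_name, .before = 1L)
}

#' Database-presence score
#'
#' Adds 10 points per queried compound database that contains the candidate.
#' Designed to be added onto a fragmenter score (`fragmenter + db_presence`)
#' to boost candidates found in curated databases.
#'
#' @param candidates candidate tibble with `challenge_id`, `skeleton` and a
#'   `db_presence` list-column of character vectors of database names.
#' @param databases databases to count; default all databases mentioned.
#' @param points points per database hit.
#' @param entry_name value of the `entry` column of the result.
#' @return collapsed-submission tibble.
#' @export
db_presence_score <- function(candidates, databases = NULL, points = 10,
                              entry_name = "DB_score") {
  presence <- candidates$db_presence %||% rep(list(character()), nrow(candidates))
  databases <- databases %||% unique(unlist(presence, use.names = FALSE))
  hits <- vapply(
    presence,
    \(x) sum(unique(x) %in% databases),
    integer(1)
  )
  candidates |>
    dplyr::mutate(score = points * hits) |>
    dplyr::summarise(
      score = max(.data$score),
      .by = c("challenge_id", "skeleton")
    ) |>
    dplyr::mutate(entry = entry_name, .before = 1L)
}

#' Fit the retention-time prediction line
#'
#' Retention on a reversed-phase gradient correlates with hydrophobicity, so a
#' least-squares line `rt = a * descriptor + b` is fitted on training
#' compounds with known retention times and later used to score candidates by
#' how well their predicted retention time matches the challenge's observed
#' one.
#'
#' @param training tibble with `descriptor` (e.g. logP) and `rt` (minutes);
#'   at least 3 rows with non-degenerate descriptor variance.
#' @return an object of class `rt_fit` (supports [tidy()], [glance()],
#'   `predict()`).
#' @export
fit_rt_model <- function(training) {
  if (nrow(training) < 3L) abort("Need at least 3 training pairs.")
  if (stats::sd(training$descriptor) == 0) {
    abort("Degenerate training set: descriptor has zero variance.")
  }
  fit <- stats::lm(rt ~ descriptor, data = training)
  structure(
    list(fit = fit, n = nrow(training)),
    class = "rt_fit"
  )
}

#' @export
predict.rt_fit <- function(object, descriptor, ...) {
  unname(stats::predict(object$fit, newdata = data.frame(descriptor = descriptor)))
}

#' @export
print.rt_fit <- function(x, ...) {
  cf <- coef(x$fit)
  cat(sprintf(
    "Retention-time model: rt = %.4f * descriptor + %.4f  (n = %d)\n",
    cf[["descriptor"]], cf[["(Intercept)"]], x$n
  ))
  invisible(x)
}

#' @rdname fit_rt_model
#' @param x an `rt_fit` object.
#' @param ... unused.
#' @export
tidy.rt_fit <- function(x, ...) {
  s <- coef(summary(x$fit))
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname fit_rt_model
#' @export
glance.rt_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = x$n
  )
}

#' Retention-time agreement score
#'
#' Scores each candidate by how close its predicted retention time (from the
#' [fit_rt_model()] line applied to the candidate's hydrophobicity
#' descriptor) falls to the challenge's observed retention time:
#' `score = max(0, 1 - |rt_obs - rt_pred| / window)`. A perfect prediction
#' scores 1; deviations of `window` minutes or more score 0.
#'
#' @param candidates candidate tibble with `challenge_id`, `skeleton`,
#'   `descriptor`.
#' @param solutions tibble with `challenge_id` and observed `rt_min`.
#' @param fit an `rt_fit` from [fit_rt_model()].
#' @param window full-credit-to-zero half width, minutes (default 2).
#' @param entry_name value of the `entry` column of the result.
#' @return collapsed-submission tibble; candidates without a descriptor score
#'   0 with a warning.
#' @export
rt_score <- function(candidates, solutions, fit, window = 2,
                     entry_name = "Retention_time") {
  if (anyNA(candidates$descriptor)) {
    warn("Candidates without a descriptor scored 0.")
  }
  candidates |>
    dplyr::left_join(
      dplyr::select(solutions, "challenge_id", "rt_min"),
      by = "challenge_id"
    ) |>
    dplyr::mutate(
      predicted = predict(fit, .data$descriptor),
      score = dplyr::coalesce(
        pmax(0, 1 - abs(.data$rt_min - .data$predicted) / window), 0
      )
    ) |>
    dplyr::summarise(
      score = max(.data$score),
      .by = c("challenge_id", "skeleton")
    ) |>
    dplyr::mutate(entry = entry_name, .before = 1L)
}

#' Grid-search consensus weights on training challenges
#'
#' Searches weight vectors on the simplex (step `grid_step`, weights summing
#' to 1) for the combination of components that maximises the Top-1 count on
#' training challenges with known solutions, breaking ties by Formula 1 score.
#'
#' @param components named list of collapsed submissions covering the training
#'   challenges.
#' @param solutions solution table for the training challenges.
#' @param grid_step simplex grid resolution in weight units (e.g. 0.25).
#' @param normalization,missing_value passed to [combine_submissions()].
#' @return an object of class `fusion_fit`: best weights, achieved Top-1 and
#'   Formula 1 counts, and the full grid table. Supports [tidy()] /
#'   [glance()].
#' @export
fit_weights <- function(components, solutions, grid_step = 0.25,
                        normalization = "max", missing_value = 0) {
  k <- length(components)
  if (k == 0L) abort("Need at least one component.")
  steps <- round(1 / grid_step)
  if (steps < 1L) abort("Empty weight grid: `grid_step` must be <= 1.")
  grid <- simplex_grid(k, steps)
  if (is.null(names(components))) {
    names(components) <- paste0("component_", seq_len(k))
  }
  eval_one <- function(w) {
    combined <- combine_submissions(
      components, w,
      normalization = normalization, missing_value = missing_value
    )
    ranks <- rank_correct(combined, solutions)
    c(
      top1 = sum(ranks$rounded_rank == 1L, na.rm = TRUE),
      formula1 = formula1_score(ranks$rounded_rank)
    )
  }
  scores <- t(apply(grid, 1L, eval_one))
  ord <- order(-scores[, "top1"], -scores[, "formula1"])
  best <- ord[1L]
  grid_tbl <- tibble::as_tibble(grid, .name_repair = \(x) names(components))
  grid_tbl$top1 <- scores[, "top1"]
  grid_tbl$formula1 <- scores[, "formula1"]
  structure(
    list(
      weights = setNames(grid[best, ], names(components)),
      top1 = scores[best, "top1"],
      formula1 = scores[best, "formula1"],
      grid = grid_tbl,
      n_challenges = dplyr::n_distinct(solutions$challenge_id)
    ),
    class = "fusion_fit"
  )
}

# all non-negative integer compositions of `steps` into k parts, scaled to 1
simplex_grid <- function(k, steps) {
  if (k == 1L) return(matrix(1, 1L, 1L))
  parts <- compositions(steps, k)
  parts / steps
}

compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (i in 0:n) {
    rest <- compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, rest, deparse.level = 0L)
  }
  do.call(rbind, out)
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat("Consensus weight fit over", nrow(x$grid), "grid points\n")
  cat("Best weights:", paste(
    sprintf("%s = %.3g", names(x$weights), x$weights),
    collapse = ", "
  ), "\n")
  cat(sprintf(
    "Top 1 = %d, Formula 1 = %d on %d training challenge(s)\n",
    x$top1, x$formula1, x$n_challenges
  ))
  invisible(x)
}

#' @rdname fit_weights
#' @param x a `fusion_fit` object.
#' @param ... unused.
#' @export
tidy.fusion_fit <- function(x, ...) {
  tibble::tibble(component = names(x$weights), weight = unname(x$weights))
}

#' @rdname fit_weights
#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(
    top1 = as.integer(x$top1),
    formula1 = as.integer(x$formula1),
    n_grid = nrow(x$grid),
    n_challenges = x$n_challenges
  )
}
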