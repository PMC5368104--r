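#' Configuration for a synthetic contest
#'
#' Defaults emulate the scale and structure of a real contest season: 208
#' challenges of which 127 are positive mode, candidate-list sizes log-normal
#' with mean about 1100 candidates, stereoisomer duplicates sprinkled into the
#' candidate lists, heavy-tailed (Pareto) literature reference counts with a
#' multiplicative boost on the true compound (contest compounds are well-known
#' chemicals), database identifiers skewed low for true compounds, and a
#' linear hydrophobicity-to-retention-time relationship with Gaussian noise.
#'
#' @param n_challenges number of challenges.
#' @param frac_positive fraction of challenges in positive ion mode.
#' @param candidate_meanlog,candidate_sdlog log-normal parameters of
#'   per-challenge candidate counts (defaults give mean ~1114).
#' @param stereo_dup_rate expected extra stereoisomer rows per candidate
#'   skeleton (Poisson).
#' @param ref_shape Pareto shape of decoy reference counts.
#' @param ref_boost multiplicative reference-count boost of true compounds.
#' @param id_max decoy identifiers are drawn uniformly from `1..id_max`.
#' @param id_true_mean true-compound identifiers are exponential with this
#'   mean (so they tend low).
#' @param rt_slope,rt_intercept,rt_noise_sd the descriptor-to-retention-time
#'   line `rt = slope * descriptor + intercept + N(0, sd)` (minutes).
#' @param descriptor_sd spread of decoy descriptors around the true
#'   compound's (isobaric candidates differ widely in hydrophobicity).
#' @param db_names simulated compound databases.
#' @param db_prob_true,db_prob_decoy per-database presence probability for
#'   true compounds and decoys.
#' @param seed integer seed; every generator stage derives its own stream
#'   from it, so stages are individually reproducible.
#' @return a `contest_config` list.
#' @export
contest_config <- function(n_challenges = 208L,
                           frac_positive = 127 / 208,
                           candidate_meanlog = log(1114) - 0.5,
                           candidate_sdlog = 1,
                           stereo_dup_rate = 0.1,
                           ref_shape = 1,
                           ref_boost = 1000,
                           id_max = 1e7,
                           id_true_mean = 5e4,
                           rt_slope = 1.2,
                           rt_intercept = 3,
                           rt_noise_sd = 0.3,
                           descriptor_sd = 2,
                           db_names = c("dbA", "dbB", "dbC", "dbD", "dbE"),
                           db_prob_true = 0.7,
                           db_prob_decoy = 0.15,
                           seed = 1L) {
  stopifnot(
    n_challenges >= 1L, frac_positive >= 0, frac_positive <= 1,
    candidate_sdlog >= 0, stereo_dup_rate >= 0, ref_shape > 0,
    ref_boost > 0, rt_noise_sd >= 0, descriptor_sd >= 0
  )
  structure(
    list(
      n_challenges = as.integer(n_challenges), frac_positive = frac_positive,
      candidate_meanlog = candidate_meanlog, candidate_sdlog = candidate_sdlog,
      stereo_dup_rate = stereo_dup_rate, ref_shape = ref_shape,
      ref_boost = ref_boost, id_max = id_max, id_true_mean = id_true_mean,
      rt_slope = rt_slope, rt_intercept = rt_intercept,
      rt_noise_sd = rt_noise_sd, descriptor_sd = descriptor_sd,
      db_names = db_names, db_prob_true = db_prob_true,
      db_prob_decoy = db_prob_decoy, seed = as.integer(seed)
    ),
    class = "contest_config"
  )
}

#' Behavioural profile of a simulated identification method
#'
#' The true candidate's score is its quantile drawn from `Beta(alpha, 1)`
#' while decoy scores are uniform on `[0, 1]`: `alpha = 1` makes the method
#' uninformative (the true candidate's rank is uniform), larger `alpha`
#' stochastically pushes the true candidate towards the top. This is a
#' one-parameter modelling stand-in for method quality, not a claim about any
#' real fragmenter.
#'
#' @param name entry name.
#' @param alpha quality parameter (> 0).
#' @param tie_prob probability that a challenge's scores are quantised onto a
#'   coarse grid, creating ties.
#' @param coverage probability that the method submits for a given challenge.
#' @param top_k optional truncation: only the top `k` candidates are
#'   submitted, possibly losing the true one.
#' @return a `method_profile` list.
#' @export
method_profile <- function(name, alpha, tie_prob = 0, coverage = 1,
                           top_k = NULL) {
  stopifnot(
    alpha > 0, tie_prob >= 0, tie_prob <= 1, coverage >= 0, coverage <= 1,
    is.null(top_k) || top_k >= 1
  )
  structure(
    list(
      name = name, alpha = alpha, tie_prob = tie_prob,
      coverage = coverage, top_k = top_k
    ),
    class = "method_profile"
  )
}

# deterministic sub-seed per generator stage, kept below 2^31
stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

random_skeletons <- function(n) {
  draw <- function(m) {
    apply(
      matrix(sample(LETTERS, m * 14L, replace = TRUE), ncol = 14L),
      1L, paste, collapse = ""
    )
  }
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- duplicated(out)
    out[dup] <- draw(sum(dup))
  }
  out
}

random_stereo_block <- function(n) {
  apply(
    matrix(sample(LETTERS, n * 8L, replace = TRUE), ncol = 8L),
    1L, paste, collapse = ""
  )
}

make_inchikey <- function(skeleton, stereo_block) {
  paste0(skeleton, "-", stereo_block, "SA-N")
}

#' Generate a synthetic identification contest
#'
#' Produces a full contest — solution table and candidate lists with metadata —
#' with the statistical structure the evaluation machinery assumes: every
#' challenge's unique solution skeleton present in its candidate list,
#' syntactically valid (chemically meaningless, contest-unique) InChIKeys with
#' stereoisomer duplicate rows, Pareto reference counts boosted on true
#' compounds, low-skewed true-compound identifiers, and retention times on a
#' noisy linear function of a hydrophobicity descriptor. Deterministic given
#' the config seed.
#'
#' @param cfg a [contest_config()].
#' @return object of class `synthetic_contest`: list with `solutions`
#'   (tibble: `challenge_id`, `ion_mode`, `precursor_type`, `rt_min`,
#'   `solution_key`, `solution_skeleton`, `descriptor`, `monoisotopic_mass`),
#'   `candidates` (tibble: `challenge_id`, `identifier`, `structure_key`,
#'   `skeleton`, `monoisotopic_mass`, `reference_count`, `db_presence`,
#'   `descriptor`, `is_true`), and `config`.
#' @export
generate_contest <- function(cfg = contest_config()) {
  stopifnot(inherits(cfg, "contest_config"))
  set.seed(stage_seed(cfg$seed, 1L))
  n <- cfg$n_challenges
  n_pos <- round(n * cfg$frac_positive)
  ion_mode <- c(rep("positive", n_pos), rep("negative", n - n_pos))
  challenge_id <- sprintf("challenge-%03d", seq_len(n))

  tc <- pmax(1L, as.integer(round(
    rlnorm(n, cfg$candidate_meanlog, cfg$candidate_sdlog)
  )))
  total <- sum(tc)
  skeleton <- random_skeletons(total)
  chal <- rep(challenge_id, tc)
  is_true <- unlist(purrr::map(tc, \(k) c(TRUE, rep(FALSE, k - 1L))),
    use.names = FALSE
  )

  true_mass <- runif(n, 100, 600)
  mass <- rep(true_mass, tc) * (1 + runif(total, -5e-6, 5e-6))

  # heavy-tailed reference counts, true compounds boosted
  refs <- ceiling(1 / runif(total)^(1 / cfg$ref_shape))
  refs[is_true] <- ceiling(refs[is_true] * cfg$ref_boost)

  identifier <- floor(runif(total, 1, cfg$id_max)) + 1
  identifier[is_true] <- floor(rexp(n, 1 / cfg$id_true_mean)) + 1

  true_descriptor <- rnorm(n, 2.5, 1.5)
  descriptor <- rep(true_descriptor, tc) +
    rnorm(total, 0, cfg$descriptor_sd) * !is_true

  p_db <- ifelse(is_true, cfg$db_prob_true, cfg$db_prob_decoy)
  db_presence <- purrr::map(p_db, \(p) {
    cfg$db_names[runif(length(cfg$db_names)) < p]
  })

  stereo_extra <- rpois(total, cfg$stereo_dup_rate)

  candidates <- tibble::tibble(
    challenge_id = chal,
    identifier = identifier,
    structure_key = make_inchikey(skeleton, random_stereo_block(total)),
    skeleton = skeleton,
    monoisotopic_mass = mass,
    reference_count = as.numeric(refs),
    db_presence = db_presence,
    descriptor = descriptor,
    is_true = is_true
  )
  # stereoisomer duplicate rows: same skeleton, different stereo block
  if (any(stereo_extra > 0L)) {
    idx <- rep(seq_len(total), stereo_extra)
    dup <- candidates[idx, ]
    dup$structure_key <- make_inchikey(
      dup$skeleton, random_stereo_block(nrow(dup))
    )
    dup$identifier <- floor(runif(nrow(dup), 1, cfg$id_max)) + 1
    candidates <- dplyr::arrange(
      dplyr::bind_rows(candidates, dup),
      .data$challenge_id
    )
  }

  rt <- cfg$rt_slope * true_descriptor + cfg$rt_intercept +
    rnorm(n, 0, cfg$rt_noise_sd)

  solutions <- tibble::tibble(
    challenge_id = challenge_id,
    ion_mode = ion_mode,
    precursor_type = ifelse(ion_mode == "positive", "[M+H]+", "[M-H]-"),
    rt_min = rt,
    solution_key = candidates$structure_key[
      match(paste(challenge_id, TRUE), paste(candidates$challenge_id, candidates$is_true))
    ],
    descriptor = true_descriptor,
    monoisotopic_mass = true_mass
  )
  solutions$solution_skeleton <- extract_skeleton(solutions$solution_key)

  structure(
    list(solutions = solutions, candidates = candidates, config = cfg),
    class = "synthetic_contest"
  )
}

#' @export
print.synthetic_contest <- function(x, ...) {
  cat(sprintf(
    "<synthetic_contest: %d challenges (%d positive), %d candidate rows, seed %d>\n",
    nrow(x$solutions), sum(x$solutions$ion_mode == "positive"),
    nrow(x$candidates), x$config$seed
  ))
  invisible(x)
}

#' Simulate participant submissions for a synthetic contest
#'
#' For each method and each covered challenge, decoy candidates get uniform
#' scores and the true candidate's score is a `Beta(alpha, 1)` draw (see
#' [method_profile()]); optional score quantisation injects ties and `top_k`
#' truncation drops low-ranked candidates (possibly the true one). Submissions
#' are emitted on the stereo-expanded candidate list, so downstream evaluation
#' must collapse stereoisomers just as for real submissions.
#'
#' @param contest a `synthetic_contest` from [generate_contest()].
#' @param profiles list of [method_profile()] objects.
#' @param seed integer; defaults to a stream derived from the contest seed.
#' @return tibble in the [read_submission()] layout (`entry`, `challenge_id`,
#'   `structure_key`, `skeleton`, `score`).
#' @export
generate_submissions <- function(contest, profiles,
                                 seed = stage_seed(contest$config$seed, 2L)) {
  stopifnot(inherits(contest, "synthetic_contest"))
  if (inherits(profiles, "method_profile")) profiles <- list(profiles)
  set.seed(seed)
  cand <- contest$candidates
  n_chal <- nrow(contest$solutions)
  out <- purrr::map(profiles, function(p) {
    covered <- contest$solutions$challenge_id[
      runif(n_chal) < p$coverage
    ]
    rows <- cand$challenge_id %in% covered
    score <- runif(nrow(cand))
    score[cand$is_true] <- rbeta(sum(cand$is_true), p$alpha, 1)
    sub <- tibble::tibble(
      entry = p$name,
      challenge_id = cand$challenge_id,
      structure_key = cand$structure_key,
      skeleton = cand$skeleton,
      score = score
    )[rows, ]
    if (p$tie_prob > 0) {
      tied <- covered[runif(length(covered)) < p$tie_prob]
      q <- sub$challenge_id %in% tied
      sub$score[q] <- round(sub$score[q] * 50) / 50
    }
    if (!is.null(p$top_k)) {
      sub <- sub |>
        dplyr::slice_max(.data$score,
          n = p$top_k, by = "challenge_id",
          with_ties = FALSE
        )
    }
    sub
  })
  dplyr::bind_rows(out)
}

#' Simulate reference and query spectra for a synthetic contest
#'
#' Per solution, draws a reference spectrum (random peaks below the precursor,
#' exponential intensities scaled to a maximum of 1e6) and a query variant
#' with ppm-scale m/z jitter and multiplicative log-normal intensity noise —
#' enough structure to exercise [cosine_similarity()], [library_search()] and
#' [split_train_challenge()]. No fragmentation chemistry is simulated.
#'
#' @param contest a `synthetic_contest`.
#' @param mz_jitter_ppm standard deviation of query m/z jitter, ppm.
#' @param intensity_noise standard deviation of log-intensity noise.
#' @param n_peaks range (min, max) of peak counts per spectrum.
#' @param seed integer; defaults to a stream derived from the contest seed.
#' @return list with `reference` and `query`, parallel lists of [spectrum()]
#'   objects carrying `meta$structure_key` and `meta$substance`.
#' @export
generate_library_spectra <- function(contest, mz_jitter_ppm = 5,
                                     intensity_noise = 0.1,
                                     n_peaks = c(5L, 30L),
                                     seed = stage_seed(contest$config$seed, 3L)) {
  stopifnot(inherits(contest, "synthetic_contest"))
  set.seed(seed)
  proton <- 1.007276
  sol <- contest$solutions
  reference <- vector("list", nrow(sol))
  query <- vector("list", nrow(sol))
  for (i in seq_len(nrow(sol))) {
    precursor <- sol$monoisotopic_mass[i] +
      ifelse(sol$ion_mode[i] == "positive", proton, -proton)
    k <- sample(n_peaks[1]:n_peaks[2], 1L)
    mz <- sort(runif(k, 50, precursor))
    intensity <- rexp(k)
    intensity <- intensity / max(intensity) * 1e6
    meta <- list(
      structure_key = sol$solution_key[i],
      substance = sol$solution_skeleton[i]
    )
    reference[[i]] <- spectrum(
      mz, intensity,
      precursor_mz = precursor, ion_mode = sol$ion_mode[i],
      spectrum_id = paste0("ref-", sol$challenge_id[i]), meta = meta
    )
    qmz <- mz * (1 + rnorm(k, 0, mz_jitter_ppm * 1e-6))
    qint <- intensity * exp(rnorm(k, 0, intensity_noise))
    query[[i]] <- spectrum(
      qmz, qint,
      precursor_mz = precursor, ion_mode = sol$ion_mode[i],
      spectrum_id = paste0("query-", sol$challenge_id[i]), meta = meta
    )
  }
  list(reference = reference, query = query)
}

#' Write a synthetic contest to disk in the standard contest formats
#'
#' Solutions as CSV, candidate lists as one CSV per challenge, submissions (if
#' given) as two-column TSV files named `<entry>-challenge-<id>.txt`, plus a
#' `manifest.json` recording the configuration and seed, so a written contest
#' round-trips through the package readers.
#'
#' @param contest a `synthetic_contest`.
#' @param dir output directory (created if needed).
#' @param submissions optional submission tibble from [generate_submissions()].
#' @return `dir`, invisibly.
#' @export
write_contest <- function(contest, dir, submissions = NULL) {
  dir.create(file.path(dir, "candidates"), recursive = TRUE, showWarnings = FALSE)
  write_solutions(contest$solutions, file.path(dir, "solutions.csv"))
  for (ch in unique(contest$candidates$challenge_id)) {
    rows <- contest$candidates[contest$candidates$challenge_id == ch, ]
    readr::write_csv(
      tibble::tibble(
        identifier = rows$identifier,
        inchikey = rows$structure_key,
        mass = rows$monoisotopic_mass,
        refcount = rows$reference_count,
        logp = rows$descriptor
      ),
      file.path(dir, "candidates", paste0(ch, ".csv"))
    )
  }
  if (!is.null(submissions)) {
    dir.create(file.path(dir, "submissions"), showWarnings = FALSE)
    submissions |>
      dplyr::group_by(.data$entry, .data$challenge_id) |>
      dplyr::group_walk(\(rows, key) {
        write_submission(
          dplyr::mutate(rows, challenge_id = key$challenge_id),
          file.path(
            dir, "submissions",
            paste0(key$entry, "-", key$challenge_id, ".txt")
          )
        )
      })
  }
  manifest <- c(
    unclass(contest$config),
    list(
      n_candidate_rows = nrow(contest$candidates),
      entries = if (is.null(submissions)) character() else unique(submissions$entry)
    )
  )
  jsonlite::write_json(
    manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
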