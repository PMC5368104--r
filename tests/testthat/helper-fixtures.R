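# Fixtures are built in code; no data files.

# deterministic fake skeleton keys: "AAAAAAAAAAAAAB"-style, unique per index
fake_skeleton <- function(i) {
  vapply(i, function(k) {
    digits <- integer(14)
    for (p in 14:1) {
      digits[p] <- k %% 26L
      k <- k %/% 26L
    }
    paste(LETTERS[digits + 1L], collapse = "")
  }, character(1))
}

fake_inchikey <- function(i, stereo = "UHFFFAOY") {
  paste0(fake_skeleton(i), "-", stereo, "SA-N")
}

# a collapsed one-challenge submission from a named score vector;
# names are taken as indices into fake_skeleton unless already 14 chars
collapsed1 <- function(scores, challenge_id = "c1", entry = "e1") {
  keys <- names(scores)
  if (is.null(keys)) keys <- fake_skeleton(seq_along(scores))
  tibble::tibble(
    entry = entry,
    challenge_id = challenge_id,
    skeleton = keys,
    score = unname(scores)
  )
}

solution1 <- function(skeleton, challenge_id = "c1") {
  tibble::tibble(challenge_id = challenge_id, solution_skeleton = skeleton)
}

# a rank table row in the rank_correct() layout
rank_row <- function(entry, challenge_id, average_rank, n_candidates = NULL) {
  if (is.null(n_candidates)) {
    m <- suppressWarnings(max(average_rank, na.rm = TRUE))
    n_candidates <- max(100L, if (is.finite(m)) ceiling(m) else 1L)
  }
  tibble::tibble(
    entry = entry, challenge_id = challenge_id,
    average_rank = average_rank,
    rounded_rank = as.integer(ceiling(average_rank)),
    n_candidates = as.integer(n_candidates),
    rrp = molcontest::rrp(average_rank, n_candidates),
    missing = is.na(average_rank)
  )
}

rank_table <- function(...) dplyr::bind_rows(...)

# tiny spectra with well-separated m/z so greedy matching is provably optimal
toy_spectrum <- function(mz, intensity, ...) {
  molcontest::spectrum(mz, intensity, ...)
}
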