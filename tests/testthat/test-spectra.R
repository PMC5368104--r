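make_ref <- function(n = 6, seed = 1, lo = 100, hi = 500) {
  set.seed(seed)
  # spacing far above tolerance so each peak has at most one eligible partner
  mz <- sort(runif(n, lo, hi))
  while (any(diff(mz) < 1)) mz <- sort(runif(n, lo, hi))
  spectrum(mz, runif(n, 1e4, 1e6), precursor_mz = hi + 1)
}

jitter_spec <- function(s, ppm = 3, int_factor = 1) {
  spectrum(
    s$mz * (1 + ppm * 1e-6), s$intensity * int_factor,
    precursor_mz = s$precursor_mz
  )
}

test_that("spectrum construction validates and sorts peaks", {
  s <- spectrum(c(200, 100), c(1, 2))
  expect_equal(s$mz, c(100, 200))
  expect_equal(s$intensity, c(2, 1))
  expect_error(spectrum(numeric(), numeric()), class = "molcontest_validation_error")
  expect_error(spectrum(c(100, -5), c(1, 1)), class = "molcontest_validation_error")
  expect_error(spectrum(100, 0), class = "molcontest_validation_error")
})

test_that("plain peak lists round-trip through write/read", {
  s <- make_ref(5, seed = 3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_peaklist(s, path)
  back <- read_peaklist(path, format = "plain")
  expect_equal(back$mz, s$mz, tolerance = 1e-6)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-4)
})

test_that("MGF blocks round-trip with precursor, mode and key", {
  s1 <- make_ref(4, seed = 4)
  s1$ion_mode <- "positive"
  s1$spectrum_id <- "spec-1"
  s1$meta$structure_key <- fake_inchikey(1)
  s2 <- make_ref(6, seed = 5)
  s2$ion_mode <- "negative"
  s2$spectrum_id <- "spec-2"
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s1, s2), path)
  back <- read_mgf(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$spectrum_id, "spec-1")
  expect_equal(back[[1]]$precursor_mz, s1$precursor_mz, tolerance = 1e-6)
  expect_equal(back[[1]]$ion_mode, "positive")
  expect_equal(back[[1]]$meta$structure_key, fake_inchikey(1))
  expect_equal(back[[2]]$ion_mode, "negative")
  expect_equal(back[[2]]$mz, s2$mz, tolerance = 1e-6)
  # single-block MGF also reads via read_peaklist with auto-detection
  path1 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(s1, path1)
  one <- read_peaklist(path1)
  expect_equal(one$mz, s1$mz, tolerance = 1e-6)
  expect_error(read_peaklist(path), "use read_mgf")
})

test_that("cosine similarity is 1 on itself and 0 on tolerance-disjoint spectra", {
  s <- make_ref(8, seed = 6)
  expect_equal(cosine_similarity(s, s), 1)
  shifted <- spectrum(s$mz + 5, s$intensity)
  expect_equal(cosine_similarity(s, shifted, tol_ppm = 10), 0)
})

test_that("cosine similarity is symmetric, bounded, and scale-invariant", {
  set.seed(9)
  for (rep in 1:10) {
    a <- make_ref(sample(3:8, 1), seed = rep)
    b <- jitter_spec(make_ref(sample(3:8, 1), seed = rep + 100), ppm = 2)
    ab <- cosine_similarity(a, b)
    expect_equal(ab, cosine_similarity(b, a))
    expect_gte(ab, 0)
    expect_lte(ab, 1)
    scaled <- spectrum(a$mz, a$intensity * 37)
    expect_equal(cosine_similarity(scaled, b), ab, tolerance = 1e-12)
  }
})

test_that("greedy matching equals the exhaustive assignment oracle on small spectra", {
  set.seed(10)
  for (rep in 1:15) {
    a <- make_ref(sample(2:6, 1), seed = rep * 3)
    # partially overlapping partner: jittered copy of a subset plus extra peaks
    keep <- sort(sample(seq_along(a$mz), max(1, length(a$mz) - 2)))
    extra_n <- sample(1:2, 1)
    extra_mz <- runif(extra_n, 520, 600)
    b <- spectrum(
      c(a$mz[keep] * (1 + rnorm(length(keep), 0, 2e-6)), extra_mz),
      c(a$intensity[keep] * runif(length(keep), 0.5, 2), runif(extra_n, 1, 10))
    )
    for (scaling in c("sqrt", "raw")) {
      expect_equal(
        cosine_similarity(a, b, tol_ppm = 10, scaling = scaling),
        cosine_oracle(a, b, tol_ppm = 10, scaling = scaling),
        tolerance = 1e-9
      )
    }
  }
})

test_that("library search filters on the precursor window and ranks by cosine", {
  ref <- make_ref(6, seed = 20)
  ref$meta$structure_key <- fake_inchikey(1)
  ref$spectrum_id <- "lib-1"
  far <- make_ref(6, seed = 21)
  far$precursor_mz <- ref$precursor_mz * (1 + 100e-6)
  far$spectrum_id <- "lib-2"
  query <- jitter_spec(ref, ppm = 2)

  hits <- library_search(query, list(ref, far), precursor_tol_ppm = 10)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$spectrum_id, "lib-1")
  expect_equal(hits$structure_key, fake_inchikey(1))

  # no precursor in window: empty result
  none <- library_search(query, list(far), precursor_tol_ppm = 10)
  expect_equal(nrow(none), 0L)

  # a lone low-similarity candidate is still returned
  unlike <- make_ref(6, seed = 22)
  unlike$precursor_mz <- query$precursor_mz
  unlike$spectrum_id <- "lib-3"
  lone <- library_search(query, list(unlike, far), precursor_tol_ppm = 10)
  expect_equal(lone$spectrum_id, "lib-3")
})

test_that("a planted true spectrum is retrieved at rank 1 under mild noise", {
  contest <- generate_contest(contest_config(
    n_challenges = 15, candidate_meanlog = log(5), candidate_sdlog = 0.1,
    seed = 33
  ))
  lib <- generate_library_spectra(contest,
    mz_jitter_ppm = 2,
    intensity_noise = 0.05, seed = 33
  )
  top_hits <- purrr::map_chr(seq_along(lib$query), function(i) {
    hits <- library_search(lib$query[[i]], lib$reference)
    hits$spectrum_id[1]
  })
  expect_equal(top_hits, paste0("ref-", contest$solutions$challenge_id))
})

test_that("the training/challenge split is strict at the threshold and honours exceptions", {
  ref <- make_ref(8, seed = 30)
  ref$spectrum_id <- "lib"
  near <- jitter_spec(ref, ppm = 1)
  near$spectrum_id <- "near"
  far <- make_ref(8, seed = 31)
  far$spectrum_id <- "far"

  fake_sim <- function(values) {
    function(a, b) values[[a$spectrum_id]]
  }
  spectra <- list(near, far)
  split <- split_train_challenge(
    spectra, list(ref),
    similarity = fake_sim(list(near = 0.86, far = 0.20))
  )
  expect_equal(split$set[split$spectrum_id == "near"], "training")
  expect_equal(split$set[split$spectrum_id == "far"], "challenge")

  # exactly at the threshold: challenge (rule reads strictly "above")
  boundary <- split_train_challenge(
    spectra, list(ref),
    similarity = fake_sim(list(near = 0.85, far = 0.1))
  )
  expect_equal(boundary$set[boundary$spectrum_id == "near"], "challenge")

  # a named exception stays a challenge despite similarity 0.88
  excepted <- split_train_challenge(
    spectra, list(ref),
    exceptions = "near",
    similarity = fake_sim(list(near = 0.88, far = 0.1))
  )
  expect_equal(excepted$set[excepted$spectrum_id == "near"], "challenge")
})

test_that("the split is a total partition, monotone in the threshold", {
  contest <- generate_contest(contest_config(
    n_challenges = 12, candidate_meanlog = log(4), candidate_sdlog = 0.1,
    seed = 44
  ))
  lib <- generate_library_spectra(contest,
    mz_jitter_ppm = 40, intensity_noise = 0.6, seed = 44
  )
  thresholds <- c(0.3, 0.6, 0.85, 0.95)
  n_training <- vapply(thresholds, function(th) {
    split <- split_train_challenge(lib$query, lib$reference, threshold = th)
    expect_true(all(split$set %in% c("training", "challenge")))
    expect_equal(nrow(split), length(lib$query))
    sum(split$set == "training")
  }, numeric(1))
  expect_true(all(diff(n_training) <= 0))
})

test_that("deduplication drops exact duplicates and keeps the most intense repeat", {
  s <- make_ref(5, seed = 50)
  s$meta$substance <- "subst-1"
  s$ion_mode <- "positive"
  twin <- s # byte-identical peaks
  weaker <- spectrum(s$mz, s$intensity * 0.5,
    ion_mode = "positive",
    meta = list(substance = "subst-1")
  )
  other <- make_ref(5, seed = 51)
  other$meta$substance <- "subst-2"
  kept <- dedupe_spectra(list(s, twin, weaker, other))
  expect_length(kept, 2L)
  expect_equal(max(kept[[1]]$intensity), max(s$intensity))
  # same substance in a different ion mode is kept
  neg <- spectrum(s$mz, s$intensity * 0.4,
    ion_mode = "negative",
    meta = list(substance = "subst-1")
  )
  expect_length(dedupe_spectra(list(s, neg, other)), 3L)
  # no duplicates: identity
  expect_length(dedupe_spectra(list(s, other)), 2L)
})

test_that("quality filters drop single-peak and low-intensity spectra", {
  good <- spectrum(c(100, 200), c(2e5, 5e5))
  single <- spectrum(100, 2e6)
  weak <- spectrum(c(100, 200), c(10, 99))
  kept <- filter_spectra(list(good, single, weak))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$mz, good$mz)
})
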