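#' Construct an MS/MS spectrum
#'
#' A spectrum is a list of (m/z, intensity) peaks plus precursor annotations.
#' Peaks are sorted ascending by m/z; at least one peak with a positive
#' intensity is required.
#'
#' @param mz numeric vector of m/z values (Da, > 0).
#' @param intensity numeric vector of intensities (arbitrary units, >= 0).
#' @param precursor_mz precursor m/z (Da) or `NA`.
#' @param ion_mode `"positive"`, `"negative"`, or `NA`.
#' @param spectrum_id identifier string.
#' @param meta named list of extra fields (e.g. `structure_key`, `substance`).
#' @return object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity, precursor_mz = NA_real_,
                     ion_mode = NA_character_, spectrum_id = NA_character_,
                     meta = list()) {
  if (length(mz) == 0L || length(mz) != length(intensity)) {
    validation_error("A spectrum needs at least one (mz, intensity) peak.")
  }
  if (any(mz <= 0) || any(intensity < 0) || all(intensity == 0)) {
    validation_error(
      "Peaks need mz > 0, intensity >= 0, and not all intensities zero."
    )
  }
  ord <- order(mz)
  structure(
    list(
      mz = as.numeric(mz[ord]), intensity = as.numeric(intensity[ord]),
      precursor_mz = as.numeric(precursor_mz),
      ion_mode = ion_mode, spectrum_id = spectrum_id, meta = meta
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum %s: %d peaks, precursor %s, %s mode>\n",
    x$spectrum_id %||% "?", length(x$mz),
    ifelse(is.na(x$precursor_mz), "NA", sprintf("%.4f", x$precursor_mz)),
    x$ion_mode %||% "unknown"
  ))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(mz = x$mz, intensity = x$intensity)
}

#' Read a peak list from plain text or MGF
#'
#' Plain text is two whitespace-separated columns (m/z, intensity), one peak
#' per line. MGF is the Mascot Generic Format; a single `BEGIN IONS` block is
#' expected here — use [read_mgf()] for multi-spectrum files. Unsorted peaks
#' are sorted with a notice.
#'
#' @param path input file.
#' @param format `"auto"` (detect `BEGIN IONS`), `"plain"`, or `"mgf"`.
#' @param spectrum_id identifier; defaults to the file name (plain) or MGF
#'   TITLE.
#' @return a [spectrum()].
#' @export
read_peaklist <- function(path, format = c("auto", "plain", "mgf"),
                          spectrum_id = NULL) {
  format <- match.arg(format)
  lines <- readr::read_lines(path)
  if (format == "auto") {
    format <- if (any(stringr::str_detect(lines, "^BEGIN IONS"))) "mgf" else "plain"
  }
  if (format == "mgf") {
    specs <- parse_mgf_lines(lines, default_id = basename(path))
    if (length(specs) != 1L) {
      abort(paste0(
        basename(path), " holds ", length(specs),
        " spectra; use read_mgf() for multi-spectrum files."
      ))
    }
    return(specs[[1L]])
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) validation_error(paste0(path, ": no peaks."))
  parts <- stringr::str_split_fixed(stringr::str_trim(lines), "\\s+", 2L)
  mz <- as.numeric(parts[, 1])
  intensity <- as.numeric(parts[, 2])
  if (anyNA(mz) || anyNA(intensity)) {
    validation_error(paste0(path, ": non-numeric peak line."))
  }
  if (is.unsorted(mz)) inform(paste0(basename(path), ": peaks sorted by m/z."))
  spectrum(mz, intensity,
    spectrum_id = spectrum_id %||% basename(path)
  )
}

#' Read all spectra from an MGF file
#'
#' Parses `BEGIN IONS` / `END IONS` blocks with `PEPMASS`, `CHARGE`, `TITLE`
#' and `RTINSECONDS` headers. Charge polarity sets the ion mode.
#'
#' @param path MGF file.
#' @return list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  parse_mgf_lines(readr::read_lines(path), default_id = basename(path))
}

parse_mgf_lines <- function(lines, default_id = "spectrum") {
  starts <- which(stringr::str_detect(lines, "^BEGIN IONS"))
  ends <- which(stringr::str_detect(lines, "^END IONS"))
  if (length(starts) == 0L || length(starts) != length(ends)) {
    validation_error("Malformed MGF: unbalanced BEGIN IONS/END IONS.")
  }
  purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1L):(e - 1L)]
    is_header <- stringr::str_detect(block, "^[A-Z]+=")
    headers <- block[is_header]
    get <- function(key) {
      hit <- headers[stringr::str_starts(headers, paste0(key, "="))]
      if (length(hit) == 0L) NA_character_ else sub(paste0(key, "="), "", hit[1L])
    }
    peaks <- block[!is_header & !grepl("^\\s*$", block)]
    if (length(peaks) == 0L) validation_error("MGF block with no peaks.")
    parts <- stringr::str_split_fixed(stringr::str_trim(peaks), "\\s+", 2L)
    pepmass <- get("PEPMASS")
    precursor <- if (is.na(pepmass)) NA_real_ else {
      as.numeric(stringr::str_split_fixed(pepmass, "\\s+", 2L)[, 1])
    }
    charge <- get("CHARGE")
    ion_mode <- if (is.na(charge)) NA_character_ else {
      if (stringr::str_detect(charge, "-")) "negative" else "positive"
    }
    meta <- list()
    rt <- get("RTINSECONDS")
    if (!is.na(rt)) meta$rt_seconds <- as.numeric(rt)
    key <- get("INCHIKEY")
    if (!is.na(key)) meta$structure_key <- key
    spectrum(
      as.numeric(parts[, 1]), as.numeric(parts[, 2]),
      precursor_mz = precursor, ion_mode = ion_mode,
      spectrum_id = get("TITLE") %|NA|% default_id, meta = meta
    )
  })
}

`%|NA|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

#' Write a spectrum as two-column plain text
#' @param spec a [spectrum()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spec, path) {
  readr::write_lines(
    sprintf("%.6f %.6g", spec$mz, spec$intensity), path
  )
  invisible(path)
}

#' Write spectra to an MGF file
#' @param spectra a [spectrum()] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  blocks <- purrr::map_chr(spectra, function(s) {
    headers <- c(
      "BEGIN IONS",
      if (!is.na(s$spectrum_id)) paste0("TITLE=", s$spectrum_id),
      if (!is.na(s$precursor_mz)) sprintf("PEPMASS=%.6f", s$precursor_mz),
      if (!is.na(s$ion_mode)) {
        paste0("CHARGE=1", if (s$ion_mode == "negative") "-" else "+")
      },
      if (!is.null(s$meta$rt_seconds)) sprintf("RTINSECONDS=%.3f", s$meta$rt_seconds),
      if (!is.null(s$meta$structure_key)) paste0("INCHIKEY=", s$meta$structure_key)
    )
    paste(
      c(headers, sprintf("%.6f %.6g", s$mz, s$intensity), "END IONS"),
      collapse = "\n"
    )
  })
  readr::write_lines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' ppm-tolerant cosine similarity between two spectra
#'
#' Peak pairs within `tol_ppm` (relative to the midpoint m/z) are matched
#' greedily in order of decreasing intensity product, each peak used at most
#' once; the similarity is the normalised dot product over matched pairs.
#' Intensities are square-root scaled by default, a common variance-stabilising
#' convention; `scaling = "raw"` uses them as-is.
#'
#' @param a,b [spectrum()] objects.
#' @param tol_ppm match tolerance in parts per million (default 10).
#' @param scaling `"sqrt"` or `"raw"` intensity scaling.
#' @return similarity in `[0, 1]`; 1 for identical spectra, 0 when no peak
#'   pair falls within tolerance.
#' @export
cosine_similarity <- function(a, b, tol_ppm = 10, scaling = c("sqrt", "raw")) {
  scaling <- match.arg(scaling)
  stopifnot(tol_ppm > 0)
  ua <- if (scaling == "sqrt") sqrt(a$intensity) else a$intensity
  ub <- if (scaling == "sqrt") sqrt(b$intensity) else b$intensity
  dmz <- abs(outer(a$mz, b$mz, "-"))
  lim <- outer(a$mz, b$mz, \(x, y) (x + y) / 2) * tol_ppm * 1e-6
  eligible <- which(dmz <= lim, arr.ind = TRUE)
  if (nrow(eligible) == 0L) return(0)
  prod <- ua[eligible[, 1]] * ub[eligible[, 2]]
  ord <- order(prod, decreasing = TRUE)
  used_a <- logical(length(ua))
  used_b <- logical(length(ub))
  dot <- 0
  for (i in ord) {
    ia <- eligible[i, 1]
    ib <- eligible[i, 2]
    if (used_a[ia] || used_b[ib]) next
    used_a[ia] <- TRUE
    used_b[ib] <- TRUE
    dot <- dot + prod[i]
  }
  min(1, dot / (sqrt(sum(ua^2)) * sqrt(sum(ub^2))))
}

#' Spectral library search
#'
#' Filters the library to spectra whose precursor m/z lies within
#' `precursor_tol_ppm` of the query's, then ranks the survivors by
#' [cosine_similarity()]. A lone surviving candidate is returned regardless of
#' its similarity — identification can then rest on the precursor match alone.
#'
#' @param query a [spectrum()] with a precursor m/z.
#' @param library list of [spectrum()] objects, ideally carrying
#'   `meta$structure_key`.
#' @param precursor_tol_ppm precursor window in ppm (default 10).
#' @param tol_ppm peak-match tolerance passed to [cosine_similarity()].
#' @param scaling passed to [cosine_similarity()].
#' @return tibble (`spectrum_id`, `structure_key`, `precursor_mz`,
#'   `similarity`) sorted by decreasing similarity; zero rows when no
#'   precursor falls in the window.
#' @export
library_search <- function(query, library, precursor_tol_ppm = 10,
                           tol_ppm = 10, scaling = "sqrt") {
  if (length(library) == 0L) abort("Empty spectral library.")
  if (is.na(query$precursor_mz)) abort("Query has no precursor m/z.")
  pm <- purrr::map_dbl(library, "precursor_mz")
  keep <- !is.na(pm) &
    abs(pm - query$precursor_mz) <= query$precursor_mz * precursor_tol_ppm * 1e-6
  survivors <- library[keep]
  tibble::tibble(
    spectrum_id = purrr::map_chr(survivors, \(s) s$spectrum_id %|NA|% NA_character_),
    structure_key = purrr::map_chr(
      survivors, \(s) s$meta$structure_key %||% NA_character_
    ),
    precursor_mz = pm[keep],
    similarity = purrr::map_dbl(
      survivors, cosine_similarity,
      b = query, tol_ppm = tol_ppm, scaling = scaling
    )
  ) |>
    dplyr::arrange(dplyr::desc(.data$similarity))
}

#' Split spectra into training and challenge sets by library similarity
#'
#' A spectrum joins the training set when its best similarity against the
#' reference library is strictly above `threshold`; otherwise it becomes a
#' challenge. Named exceptions are forced into the challenge set even when
#' they exceed the threshold (e.g. to keep enough natural products among the
#' challenges). The partition is deterministic, total and disjoint.
#'
#' @param spectra list of [spectrum()] objects to split.
#' @param reference_library list of [spectrum()] objects.
#' @param threshold similarity cut (default 0.85; a value of exactly 0.85 is
#'   a challenge, the rule reads strictly "above").
#' @param exceptions spectrum ids forced into the challenge set.
#' @param similarity function `(a, b) -> [0,1]`; defaults to the module's
#'   ppm-tolerant cosine at `tol_ppm`.
#' @param tol_ppm tolerance for the default similarity.
#' @return tibble (`spectrum_id`, `max_similarity`, `best_match`, `set`)
#'   where `set` is `"training"` or `"challenge"`.
#' @export
split_train_challenge <- function(spectra, reference_library, threshold = 0.85,
                                  exceptions = character(),
                                  similarity = NULL, tol_ppm = 10) {
  similarity <- similarity %||%
    function(a, b) cosine_similarity(a, b, tol_ppm = tol_ppm)
  rows <- purrr::map(spectra, function(s) {
    sims <- purrr::map_dbl(reference_library, \(r) similarity(s, r))
    best <- if (length(sims)) which.max(sims) else NA_integer_
    tibble::tibble(
      spectrum_id = s$spectrum_id,
      max_similarity = if (length(sims)) sims[best] else 0,
      best_match = if (length(sims)) {
        reference_library[[best]]$spectrum_id
      } else {
        NA_character_
      }
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      set = dplyr::if_else(
        .data$max_similarity > threshold &
          !.data$spectrum_id %in% exceptions,
        "training", "challenge"
      )
    )
}

#' Remove duplicate and repeated spectra
#'
#' Drops exact-duplicate peak lists (byte-identical m/z and intensity vectors)
#' and collapses repeated measurements of the same substance in the same ion
#' mode to the spectrum with the highest maximum intensity. Substance identity
#' is read from `meta$substance` (falling back to `meta$structure_key`);
#' spectra without it are only deduplicated exactly.
#'
#' @param spectra list of [spectrum()] objects.
#' @return filtered list, original order preserved.
#' @export
dedupe_spectra <- function(spectra) {
  sig <- purrr::map_chr(
    spectra,
    \(s) paste(c(format(s$mz, digits = 12), format(s$intensity, digits = 12)),
      collapse = ";"
    )
  )
  keep <- !duplicated(sig)
  spectra <- spectra[keep]
  substance <- purrr::map_chr(
    spectra,
    \(s) (s$meta$substance %||% s$meta$structure_key %||% NA_character_)
  )
  mode <- purrr::map_chr(spectra, \(s) s$ion_mode %||% NA_character_)
  maxint <- purrr::map_dbl(spectra, \(s) max(s$intensity))
  group <- paste(substance, mode)
  keep2 <- rep(TRUE, length(spectra))
  for (g in unique(group[!is.na(substance)])) {
    idx <- which(group == g & !is.na(substance))
    if (length(idx) > 1L) {
      keep2[idx] <- FALSE
      keep2[idx[which.max(maxint[idx])]] <- TRUE
    }
  }
  spectra[keep2]
}

#' Quality-filter spectra
#'
#' Configurable predicates matching common curation rules: spectra with fewer
#' than `min_peaks` peaks or a maximum intensity below `min_max_intensity` are
#' removed (defaults: single-peak spectra and max intensity below 1e5).
#'
#' @param spectra list of [spectrum()] objects.
#' @param min_peaks minimum peak count (default 2).
#' @param min_max_intensity minimum allowed maximum intensity (default 1e5).
#' @return filtered list.
#' @export
filter_spectra <- function(spectra, min_peaks = 2L, min_max_intensity = 1e5) {
  keep <- purrr::map_lgl(
    spectra,
    \(s) length(s$mz) >= min_peaks && max(s$intensity) >= min_max_intensity
  )
  spectra[keep]
}
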