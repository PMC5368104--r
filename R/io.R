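#' Read one contest submission file
#'
#' A submission is a plain-text, tab-separated file with two columns: the
#' candidate structure (standard InChI, SMILES, or InChIKey) and a non-negative
#' score, higher meaning a better candidate. Structures are captured verbatim;
#' the stereoisomer skeleton key is derived when the structure is an InChIKey,
#' or through `key_fun` (a chemistry-toolkit adapter mapping structure strings
#' to InChIKeys) otherwise.
#'
#' An empty file is a valid "no submission" for that challenge and yields a
#' zero-row tibble. A negative or unparseable score aborts with a validation
#' error naming the offending line.
#'
#' @param path path to the submission file.
#' @param challenge_id,entry identifiers attached to every row; defaults are
#'   guessed from a `<entry>-challenge-<id>.txt` filename when possible.
#' @param key_fun optional function mapping structure strings to full
#'   InChIKeys, used when column 1 does not already hold InChIKeys.
#' @return tibble with columns `entry`, `challenge_id`, `structure`,
#'   `structure_key`, `skeleton`, `score`.
#' @seealso [write_submission()], [collapse_stereo()]
#' @export
read_submission <- function(path, challenge_id = NULL, entry = NULL,
                            key_fun = NULL) {
  if (!file.exists(path)) {
    validation_error(paste0("Submission file not found: ", path))
  }
  guessed <- parse_submission_filename(basename(path))
  entry <- entry %||% guessed$entry
  challenge_id <- challenge_id %||% guessed$challenge_id
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(
      entry = character(), challenge_id = character(),
      structure = character(), structure_key = character(),
      skeleton = character(), score = double()
    ))
  }
  parts <- stringr::str_split_fixed(lines, "\t", 3L)
  if (any(parts[, 2] == "")) {
    bad <- which(parts[, 2] == "")[1L]
    validation_error(paste0(
      "Line ", bad, " of ", basename(path),
      " does not have two tab-separated columns."
    ))
  }
  structure <- stringr::str_trim(parts[, 1])
  score <- suppressWarnings(as.numeric(stringr::str_trim(parts[, 2])))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1L]
    validation_error(paste0(
      "Line ", bad, " of ", basename(path), ": score ",
      sQuote(stringr::str_trim(parts[bad, 2])), " is not a number."
    ))
  }
  if (any(score < 0)) {
    bad <- which(score < 0)[1L]
    validation_error(paste0(
      "Line ", bad, " of ", basename(path), ": score ", score[bad],
      " is negative; scores must be non-negative (higher = better)."
    ))
  }
  structure_key <- if (is.null(key_fun)) {
    stringr::str_remove(structure, "^InChIKey=")
  } else {
    vapply(structure, key_fun, character(1), USE.NAMES = FALSE)
  }
  tibble::tibble(
    entry = entry %||% NA_character_,
    challenge_id = challenge_id %||% NA_character_,
    structure = structure,
    structure_key = structure_key,
    skeleton = extract_skeleton(structure_key),
    score = score
  )
}

parse_submission_filename <- function(fname) {
  m <- stringr::str_match(fname, "^(.*)-challenge-([^.]+)\\.[Tt][Xx][Tt]$")
  if (is.na(m[1, 1])) {
    list(entry = NULL, challenge_id = NULL)
  } else {
    list(entry = m[1, 2], challenge_id = paste0("challenge-", m[1, 3]))
  }
}

#' Read a directory of submission files for one entry
#'
#' Files are matched with the configurable pattern
#' `<entry>-challenge-<id>.txt`. Challenges in `challenge_ids` with no file on
#' disk are recorded as no-submission (zero rows); downstream ranking treats
#' them as missing.
#'
#' @param dir directory holding submission files.
#' @param entry entry name (filename prefix).
#' @param challenge_ids optional character vector of expected challenge ids.
#' @inheritParams read_submission
#' @return tibble in the [read_submission()] layout, rows from all files.
#' @export
read_submission_dir <- function(dir, entry, challenge_ids = NULL,
                                key_fun = NULL) {
  files <- list.files(dir, pattern = paste0(
    "^", stringr::str_replace_all(entry, "([.\\\\+*?\\[^\\]$(){}=!<>|:#-])", "\\\\\\1"),
    "-challenge-.*\\.txt$"
  ), full.names = TRUE)
  out <- purrr::map(files, read_submission, entry = entry, key_fun = key_fun)
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      entry = character(), challenge_id = character(),
      structure = character(), structure_key = character(),
      skeleton = character(), score = double()
    )
  }
  if (!is.null(challenge_ids)) {
    missing <- setdiff(challenge_ids, unique(out$challenge_id))
    if (length(missing)) {
      inform(paste0(
        entry, ": no submission for ", length(missing), " challenge(s)."
      ))
    }
  }
  out
}

#' Write a submission tibble to the two-column tab-separated contest format
#'
#' @param submission tibble with at least `structure_key` (or `structure`) and
#'   `score`; one challenge per file, so `challenge_id` must be constant.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_submission <- function(submission, path) {
  stopifnot(nrow(submission) == 0L ||
    length(unique(submission$challenge_id)) == 1L)
  key <- submission$structure_key %||% submission$structure
  readr::write_tsv(
    tibble::tibble(structure = key, score = submission$score),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read a candidate list CSV
#'
#' Candidate lists are CSV files with a header; column names vary between
#' contests, so a configurable column map translates them to the package's
#' canonical names. Rows whose structure key fails InChIKey validation are
#' dropped with a message giving the count (mirroring upstream removal of
#' candidates whose structure conversion failed). Duplicate identifiers
#' collapse to their first row with a warning.
#'
#' @param path CSV path.
#' @param column_map named character vector mapping canonical names
#'   (`identifier`, `inchikey`, `mass`, `refcount`, `logp`) to the file's
#'   column names. Only `identifier` and `inchikey` are required.
#' @param challenge_id optional challenge id attached to all rows.
#' @return tibble with columns `challenge_id`, `identifier`, `structure_key`,
#'   `skeleton`, `monoisotopic_mass`, `reference_count`, `descriptor`.
#' @export
read_candidates <- function(path,
                            column_map = c(
                              identifier = "identifier",
                              inchikey = "inchikey",
                              mass = "mass",
                              refcount = "refcount",
                              logp = "logp"
                            ),
                            challenge_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("identifier", "inchikey")
  for (col in need) {
    if (!col %in% names(column_map) || !column_map[[col]] %in% names(df)) {
      abort(paste0(
        "Candidate CSV ", basename(path), " lacks mapped column ",
        sQuote(column_map[col] %||% col), " for ", sQuote(col), "."
      ), class = "molcontest_config_error")
    }
  }
  pick <- function(role) {
    nm <- column_map[role]
    if (!is.na(nm) && !is.null(nm) && nm %in% names(df)) df[[nm]] else NULL
  }
  key <- as.character(df[[column_map[["inchikey"]]]])
  valid <- is_inchikey(key) | is_skeleton_key(key)
  n_dropped <- sum(!valid)
  if (n_dropped > 0L) {
    inform(paste0(
      "Dropped ", n_dropped, " candidate row(s) with invalid structure keys from ",
      basename(path), "."
    ))
  }
  out <- tibble::tibble(
    challenge_id = challenge_id %||% NA_character_,
    identifier = as.integer(df[[column_map[["identifier"]]]]),
    structure_key = key,
    monoisotopic_mass = as.numeric(pick("mass") %||% NA_real_),
    reference_count = as.numeric(pick("refcount") %||% NA_real_),
    descriptor = as.numeric(pick("logp") %||% NA_real_)
  )[valid, ]
  out$skeleton <- extract_skeleton(out$structure_key)
  if (anyDuplicated(out$identifier)) {
    warn("Duplicate candidate identifiers collapsed to their first row.")
    out <- dplyr::distinct(out, .data$identifier, .keep_all = TRUE)
  }
  dplyr::relocate(out, "skeleton", .after = "structure_key")
}

#' Read a contest solution table
#'
#' CSV with columns `challenge_id`, `inchikey`, `mode` (`positive` or
#' `negative`), `rt_min`.
#'
#' @param path CSV path.
#' @return tibble with `challenge_id`, `solution_key`, `solution_skeleton`,
#'   `ion_mode`, `rt_min`.
#' @export
read_solutions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("challenge_id", "inchikey", "mode", "rt_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0(
      "Solution CSV lacks column(s): ", paste(miss, collapse = ", ")
    ), class = "molcontest_config_error")
  }
  mode <- tolower(as.character(df$mode))
  if (!all(mode %in% c("positive", "negative"))) {
    validation_error("Solution ion modes must be 'positive' or 'negative'.")
  }
  tibble::tibble(
    challenge_id = as.character(df$challenge_id),
    solution_key = as.character(df$inchikey),
    solution_skeleton = extract_skeleton(df$inchikey),
    ion_mode = mode,
    rt_min = as.numeric(df$rt_min)
  )
}

#' Write a solution table in the layout read by [read_solutions()]
#' @param solutions tibble as returned by [read_solutions()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_solutions <- function(solutions, path) {
  readr::write_csv(
    tibble::tibble(
      challenge_id = solutions$challenge_id,
      inchikey = solutions$solution_key,
      mode = solutions$ion_mode,
      rt_min = solutions$rt_min
    ),
    path
  )
  invisible(path)
}
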