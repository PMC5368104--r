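#' Extract the first InChIKey block (skeleton key)
#'
#' The first 14 characters of an InChIKey hash the molecular skeleton and are
#' constant across stereoisomers, so candidate structures are deduplicated on
#' this block. Accepts full 27-character keys (hyphens at positions 15 and 26),
#' bare 14-character first blocks, and an optional `"InChIKey="` prefix.
#'
#' @param structure_key character vector of InChIKeys or bare first blocks.
#' @return character vector of 14-character skeleton keys.
#' @examples
#' extract_skeleton("BSYNRYMUTXBXSQ-UHFFFAOYSA-N")
#' extract_skeleton("BSYNRYMUTXBXSQ")
#' @export
extract_skeleton <- function(structure_key) {
  key <- stringr::str_remove(structure_key, "^InChIKey=")
  ok <- is_inchikey(key) | is_skeleton_key(key)
  if (any(!ok, na.rm = TRUE)) {
    bad <- utils::head(key[!ok & !is.na(key)], 3L)
    validation_error(c(
      "Malformed InChIKey(s): expected a 27-character key (XXXXXXXXXXXXXX-XXXXXXXXXX-X) or a bare 14-letter first block.",
      x = paste0("e.g. ", paste(sQuote(bad), collapse = ", "))
    ))
  }
  substr(key, 1L, 14L)
}

is_inchikey <- function(x) {
  stringr::str_detect(x, "^[A-Z]{14}-[A-Z]{8}[A-Z]{2}-[A-Z]$") & !is.na(x)
}

is_skeleton_key <- function(x) {
  stringr::str_detect(x, "^[A-Z]{14}$") & !is.na(x)
}
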