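# AIRR Rearrangement TSV input/output.
#
# One table per tool, tab-separated, booleans encoded "T"/"F" per the AIRR
# Rearrangement convention. Multiple gene calls in a *_call field are
# comma-separated, first call primary.

REARRANGEMENT_COLS <- c("sequence_id", "tool_label", "v_call", "d_call",
                        "j_call", "junction_aa", "cdr3_aa", "productive",
                        "stop_codon", "vj_in_frame", "locus",
                        "duplicate_count")
REARRANGEMENT_LOGICAL <- c("productive", "stop_codon", "vj_in_frame")

#' Read an AIRR-style rearrangement TSV
#'
#' Expects (a superset of) the columns `sequence_id`, `v_call`, `d_call`,
#' `j_call`, `junction_aa`, `cdr3_aa`, `productive`, `stop_codon`,
#' `vj_in_frame`, `locus`, `duplicate_count`, with logicals encoded as
#' `T`/`F`. Missing optional columns are filled with defaults
#' (`duplicate_count = 1`, `locus = "IGH"`, `tool_label` from the argument).
#'
#' @param path TSV file.
#' @param tool_label label assigned when the file has no `tool_label`
#'   column.
#' @return rearrangement tibble.
#' @export
read_rearrangements <- function(path, tool_label = basename(path)) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!"sequence_id" %in% names(x)) {
    stop("not a rearrangement table (no sequence_id column): ", path,
         call. = FALSE)
  }
  for (col in REARRANGEMENT_LOGICAL) {
    if (col %in% names(x)) x[[col]] <- x[[col]] %in% c("T", "TRUE", "true")
    else x[[col]] <- NA
  }
  if (!"tool_label" %in% names(x)) x$tool_label <- tool_label
  if (!"locus" %in% names(x)) x$locus <- "IGH"
  x$duplicate_count <- if ("duplicate_count" %in% names(x))
    as.integer(x$duplicate_count) else 1L
  for (col in setdiff(REARRANGEMENT_COLS, names(x))) x[[col]] <- NA_character_
  x[, REARRANGEMENT_COLS]
}

#' Write an AIRR-style rearrangement TSV
#'
#' Logical columns are serialized as `T`/`F`.
#'
#' @param records rearrangement tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  out <- records
  for (col in REARRANGEMENT_LOGICAL) {
    if (col %in% names(out)) {
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           ifelse(out[[col]], "T", "F"))
    }
  }
  readr::write_tsv(out, path)
  invisible(path)
}
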