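# Harmonization and preprocessing of rearrangement tables.
#
# Harmonization brings every tool's output to a common schema: CDR3s in the
# "core" convention (conserved junction anchors stripped), synonym-renamed
# calls, and a single naming granularity. Preprocessing then applies the
# benchmark's exclusion rules in a fixed order, attributing each removed
# record to the first rule that rejects it.

#' Normalize one CDR3 string to the core convention
#'
#' Anchored CDR3s (junctions) must begin with the conserved cysteine `C` and
#' end with the conserved tryptophan `W`; both are removed. Core CDR3s pass
#' through unchanged.
#'
#' @param cdr3 non-empty amino-acid string.
#' @param convention `"anchored"` or `"core"`.
#' @return core-convention CDR3 string.
#' @export
normalize_cdr3 <- function(cdr3, convention = c("core", "anchored")) {
  convention <- match.arg(convention)
  if (length(cdr3) != 1L || is.na(cdr3) || nchar(cdr3) == 0L) {
    stop("cdr3 must be a single non-empty string", call. = FALSE)
  }
  if (convention == "core") return(cdr3)
  if (nchar(cdr3) < 3L) {
    stop("anchored CDR3 must have length >= 3 (C + core + W)", call. = FALSE)
  }
  if (!startsWith(cdr3, "C") || !endsWith(cdr3, "W")) {
    stop("anchored CDR3 must start with C and end with W: ", cdr3,
         call. = FALSE)
  }
  substr(cdr3, 2L, nchar(cdr3) - 1L)
}

#' Harmonize a rearrangement table to the common schema
#'
#' Strips junction anchors from anchored CDR3s (records whose CDR3 does not
#' start with `C` and end with `W` are flagged and left unchanged),
#' canonicalizes all gene calls through the synonym map, and drops allele
#' suffixes at gene granularity. Record order is preserved. The result
#' carries attribute `cdr3_convention = "core"`, and re-harmonizing an
#' already-core table is a no-op on the CDR3s.
#'
#' @param records rearrangement tibble.
#' @param cdr3_convention convention of the *input* CDR3s (ignored, with the
#'   stored attribute used instead, when the table is already marked core).
#' @param synonyms optional [build_synonym_map()] result.
#' @param granularity `"gene"` (drop allele suffixes) or `"allele"`.
#' @return harmonized tibble; attribute `n_cdr3_flagged` counts anchored
#'   records whose CDR3 lacked the anchors.
#' @export
harmonize <- function(records, cdr3_convention = c("core", "anchored"),
                      synonyms = NULL, granularity = c("gene", "allele")) {
  cdr3_convention <- match.arg(cdr3_convention)
  granularity <- match.arg(granularity)
  out <- records
  if (identical(attr(records, "cdr3_convention"), "core")) {
    cdr3_convention <- "core"
  }
  n_flagged <- 0L
  if (cdr3_convention == "anchored") {
    cdr3 <- out$cdr3_aa
    ok <- !is.na(cdr3) & nchar(cdr3) >= 3L &
      startsWith(cdr3, "C") & endsWith(cdr3, "W")
    n_flagged <- sum(!ok & !is.na(cdr3))
    cdr3[ok] <- substr(cdr3[ok], 2L, nchar(cdr3[ok]) - 1L)
    out$cdr3_aa <- cdr3
  }
  fix_calls <- function(x) {
    vapply(x, function(cell) {
      if (is.na(cell) || cell == "") return(cell)
      calls <- strsplit(cell, ",", fixed = TRUE)[[1]]
      calls <- trimws(calls)
      if (granularity == "gene") calls <- strip_allele(calls)
      calls <- apply_synonyms(calls, synonyms)
      paste(calls, collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  }
  for (col in c("v_call", "d_call", "j_call")) {
    if (col %in% names(out)) out[[col]] <- fix_calls(out[[col]])
  }
  attr(out, "cdr3_convention") <- "core"
  attr(out, "n_cdr3_flagged") <- n_flagged
  out
}

PREPROCESS_RULES <- c("non_igh", "stop_codon", "out_of_frame", "unproductive",
                      "orphon", "cdr3_length", "singleton", "dedup")

#' Apply the benchmark preprocessing filter
#'
#' Removes, in order: (1) non-IgH records; (2) records with premature stop
#' codons; (3) out-of-frame records; (4) unproductive records; (5) records
#' whose primary V/D/J call is an orphon gene; (6) records with absent CDR3
#' or core CDR3 of length <= 4; (7) singleton CDR3s (total multiplicity,
#' weighted by `duplicate_count`, equal to one among the survivors of rules
#' 1--6); (8) duplicate CDR3s (first occurrence kept, `duplicate_count`
#' aggregated). Each removed record is attributed to the first rule that
#' rejects it. Because deduplicated records carry the aggregated
#' `duplicate_count`, the filter is idempotent.
#'
#' @param records harmonized rearrangement tibble (core CDR3 convention).
#' @param orphon_genes character vector of orphon gene names.
#' @return list with `records` (the filtered table, unique CDR3s) and
#'   `report` (class `filter_report`: `input_count`, `removed_per_rule`,
#'   `output_count`, `unique_cdr3_count`).
#' @export
preprocess_filter <- function(records, orphon_genes = character()) {
  n_in <- nrow(records)
  removed <- stats::setNames(integer(length(PREPROCESS_RULES)),
                             PREPROCESS_RULES)
  x <- records
  dup <- if ("duplicate_count" %in% names(x)) {
    ifelse(is.na(x$duplicate_count), 1L, as.integer(x$duplicate_count))
  } else rep(1L, n_in)
  x$duplicate_count <- dup

  drop_rule <- function(x, bad, rule) {
    removed[[rule]] <<- removed[[rule]] + sum(bad)
    x[!bad, , drop = FALSE]
  }
  na_false <- function(b) !is.na(b) & b
  x <- drop_rule(x, is.na(x$locus) | x$locus != "IGH", "non_igh")
  x <- drop_rule(x, na_false(x$stop_codon), "stop_codon")
  x <- drop_rule(x, na_false(!x$vj_in_frame), "out_of_frame")
  x <- drop_rule(x, na_false(!x$productive), "unproductive")
  if (length(orphon_genes)) {
    prim <- cbind(primary_call(x, "V"), primary_call(x, "D"),
                  primary_call(x, "J"))
    orph <- apply(prim, 1L, function(p) any(strip_allele(p) %in% orphon_genes))
    x <- drop_rule(x, orph, "orphon")
  }
  x <- drop_rule(x, is.na(x$cdr3_aa) | nchar(x$cdr3_aa) <= 4L, "cdr3_length")
  if (nrow(x)) {
    mult <- tapply(x$duplicate_count, x$cdr3_aa, sum)
    x <- drop_rule(x, as.vector(mult[x$cdr3_aa]) == 1L, "singleton")
  }
  if (nrow(x)) {
    mult <- tapply(x$duplicate_count, x$cdr3_aa, sum)
    first <- !duplicated(x$cdr3_aa)
    kept <- x[first, , drop = FALSE]
    kept$duplicate_count <- as.integer(mult[kept$cdr3_aa])
    removed[["dedup"]] <- nrow(x) - nrow(kept)
    x <- kept
  }
  report <- structure(list(input_count = n_in, removed_per_rule = removed,
                           output_count = nrow(x),
                           unique_cdr3_count = length(unique(x$cdr3_aa))),
                      class = "filter_report")
  attr(x, "cdr3_convention") <- attr(records, "cdr3_convention")
  list(records = x, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d -> %d records (%d unique CDR3s)\n",
              x$input_count, x$output_count, x$unique_cdr3_count))
  print(x$removed_per_rule)
  invisible(x)
}

#' Per-gene alignment counts before and after preprocessing
#'
#' Counts primary calls of one gene type in the raw (`before`) and filtered
#' (`after`) tables and reports the fraction lost to preprocessing per gene
#' and overall (pooled).
#'
#' @param before,after rearrangement tibbles; `after` must be a subset of
#'   `before` by `sequence_id`.
#' @param gene_type `"V"`, `"D"` or `"J"`.
#' @return tibble with columns `gene`, `annotated_count`, `retained_count`,
#'   `lost_fraction`; genes never annotated are omitted, and an `"overall"`
#'   row pools all genes.
#' @export
alignment_counts <- function(before, after, gene_type = c("V", "D", "J")) {
  gene_type <- match.arg(gene_type)
  if (!all(after$sequence_id %in% before$sequence_id)) {
    stop("`after` contains sequence_ids absent from `before`", call. = FALSE)
  }
  count_calls <- function(x) {
    calls <- primary_call(x, gene_type)
    calls <- calls[calls != "no call"]
    table(calls)
  }
  b <- count_calls(before); a <- count_calls(after)
  genes <- names(b)
  annotated <- as.integer(b)
  retained <- as.integer(a[genes]); retained[is.na(retained)] <- 0L
  out <- tibble::tibble(gene = genes, annotated_count = annotated,
                        retained_count = retained,
                        lost_fraction = 1 - retained / annotated)
  overall <- tibble::tibble(gene = "overall",
                            annotated_count = sum(annotated),
                            retained_count = sum(retained),
                            lost_fraction = 1 - sum(retained) / sum(annotated))
  dplyr::bind_rows(out, overall)
}
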