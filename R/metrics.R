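# Accuracy and overlap metrics: mishit frequencies against ground truth,
# per-subgroup breakdowns, confusion matrices, multi-tool CDR3 overlap
# partitions, Top-N CDR3 selection and the processing-speed formula.

#' Primary gene call of each record
#'
#' The primary call is the first gene assigned when multiple assignments are
#' present; records without a call of the requested type yield `"no call"`.
#'
#' @param records rearrangement tibble (calls comma-separated, first
#'   primary).
#' @param gene_type `"V"`, `"D"` or `"J"`.
#' @param synonyms optional [build_synonym_map()] applied to the result.
#' @return character vector of gene/allele names or `"no call"`.
#' @export
primary_call <- function(records, gene_type = c("V", "D", "J"),
                         synonyms = NULL) {
  gene_type <- match.arg(gene_type)
  col <- c(V = "v_call", D = "d_call", J = "j_call")[[gene_type]]
  x <- records[[col]]
  first <- sub(",.*$", "", x)
  first <- trimws(first)
  out <- ifelse(is.na(first) | first == "", "no call", first)
  miss <- out == "no call"
  out[!miss] <- apply_synonyms(out[!miss], synonyms)
  out
}

# Join annotations to truth and return canonical primary/true gene vectors
# at gene level. Errors on annotation ids absent from the truth.
align_to_truth <- function(annotations, truth, gene_type, synonyms) {
  idx <- match(annotations$sequence_id, truth$sequence_id)
  if (anyNA(idx)) {
    stop("annotation sequence_id(s) absent from ground truth, e.g. ",
         annotations$sequence_id[which(is.na(idx))[1L]], call. = FALSE)
  }
  true_col <- c(V = "true_v_gene", D = "true_d_gene",
                J = "true_j_gene")[[gene_type]]
  assigned <- primary_call(annotations, gene_type, synonyms = synonyms)
  assigned <- ifelse(assigned == "no call", assigned, strip_allele(assigned))
  assigned <- ifelse(assigned == "no call", assigned,
                     apply_synonyms(assigned, synonyms))
  truth_gene <- apply_synonyms(strip_allele(truth[[true_col]][idx]), synonyms)
  list(assigned = assigned, truth = truth_gene)
}

#' Cumulative mishit frequency of one gene type
#'
#' A hit is the assignment of a read to its known originating germline gene,
#' a mishit the assignment to any other gene; comparison is at gene level
#' after synonym renaming, and the denominator `N` counts only records with
#' a call of the given type (frequency `K/N`, `NA` when `N = 0`).
#'
#' @param annotations harmonized rearrangement tibble whose `sequence_id`s
#'   all occur in `truth`.
#' @param truth ground-truth tibble ([generate_repertoire()]).
#' @param gene_type `"V"`, `"D"` or `"J"`.
#' @param synonyms optional [build_synonym_map()].
#' @return tibble with one row: `gene_type`, `K` (mishits), `N` (records
#'   with a call), `frequency`.
#' @export
mishit_frequency <- function(annotations, truth, gene_type = c("V", "D", "J"),
                             synonyms = NULL) {
  gene_type <- match.arg(gene_type)
  al <- align_to_truth(annotations, truth, gene_type, synonyms)
  has_call <- al$assigned != "no call"
  N <- sum(has_call)
  K <- sum(has_call & al$assigned != al$truth)
  tibble::tibble(gene_type = gene_type, K = K, N = N,
                 frequency = if (N > 0) K / N else NA_real_)
}

#' Per-subgroup mishit frequencies
#'
#' Rows are keyed by the *true* gene's subgroup; `W` counts mishits among
#' reads whose true gene belongs to the subgroup, `X` the reads of that
#' subgroup carrying a call, so summing `W` (`X`) over subgroups recovers
#' the cumulative `K` (`N`). Subgroups with `X = 0` are omitted.
#'
#' @inheritParams mishit_frequency
#' @return tibble with columns `subgroup`, `W`, `X`, `frequency`.
#' @export
subgroup_mishit_frequencies <- function(annotations, truth,
                                        gene_type = c("V", "D", "J"),
                                        synonyms = NULL) {
  gene_type <- match.arg(gene_type)
  al <- align_to_truth(annotations, truth, gene_type, synonyms)
  has_call <- al$assigned != "no call"
  subgroup <- parse_gene_name(al$truth)$subgroup_name
  mis <- has_call & al$assigned != al$truth
  X <- tapply(has_call, subgroup, sum)
  W <- tapply(mis, subgroup, sum)
  out <- tibble::tibble(subgroup = names(X), W = as.integer(W),
                        X = as.integer(X))
  out <- out[out$X > 0L, , drop = FALSE]
  out$frequency <- out$W / out$X
  out[order(out$subgroup), ]
}

#' Confusion matrix of true versus assigned genes
#'
#' Cell (t, a) is the fraction of reads with true gene t that received
#' assignment a; a `"no call"` column absorbs reads without a call, so each
#' row sums to one.
#'
#' @inheritParams mishit_frequency
#' @return numeric matrix (rows = true genes, columns = assigned genes plus
#'   `"no call"`), each row summing to 1.
#' @export
confusion_matrix <- function(annotations, truth, gene_type = c("V", "D", "J"),
                             synonyms = NULL) {
  gene_type <- match.arg(gene_type)
  al <- align_to_truth(annotations, truth, gene_type, synonyms)
  tab <- table(true = al$truth, assigned = al$assigned)
  m <- unclass(tab / rowSums(tab))
  # keep "no call" last when present
  if ("no call" %in% colnames(m)) {
    m <- m[, c(setdiff(colnames(m), "no call"), "no call"), drop = FALSE]
  }
  m
}

#' Partition unique CDR3 sets of several tools into overlap regions
#'
#' Exact-string set partition: every non-empty subset of tools is a region
#' holding the CDR3s found by exactly those tools. Per-tool percentages
#' divide each region count by that tool's total unique CDR3 count (the
#' reporting rule of the benchmark), so each tool's percentages over the
#' regions containing it sum to 100.
#'
#' @param cdr3_sets named list (>= 2 entries) of unique-CDR3 character
#'   vectors, one per tool.
#' @param stage optional stage label (`"annotated"`, `"preprocessed"`,
#'   `"topN"`, ...) carried in the result.
#' @return object of class `overlap_partition`: the underlying
#'   `membership_table` plus `percentages`, a tibble of (tool, region,
#'   count, pct).
#' @export
cdr3_overlap <- function(cdr3_sets, stage = "annotated") {
  if (length(cdr3_sets) < 2L) {
    stop("need at least two tools for overlap analysis", call. = FALSE)
  }
  if (is.null(names(cdr3_sets)) || any(names(cdr3_sets) == "")) {
    stop("cdr3_sets must be a named list", call. = FALSE)
  }
  mt <- membership_table(lapply(cdr3_sets, unique), level = "cdr3")
  labels <- names(cdr3_sets)
  pct_rows <- lapply(labels, function(tool) {
    in_region <- vapply(strsplit(mt$regions$region, "&", fixed = TRUE),
                        function(r) tool %in% r, logical(1))
    reg <- mt$regions[in_region, , drop = FALSE]
    total <- mt$totals[[tool]]
    pct <- if (total > 0) 100 * reg$count / total else rep(NA_real_, nrow(reg))
    tibble::tibble(tool = tool, region = reg$region, count = reg$count,
                   pct = pct)
  })
  structure(list(stage = stage, totals = mt$totals, regions = mt$regions,
                 union_size = mt$union_size, shared_all = mt$shared_all,
                 percentages = dplyr::bind_rows(pct_rows)),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("<overlap_partition> stage=%s, union=%d, shared by all=%d\n",
              x$stage, x$union_size, x$shared_all))
  print(x$percentages)
  invisible(x)
}

#' Top-N most frequent unique CDR3s
#'
#' Frequencies are record multiplicities weighted by `duplicate_count`
#' (records must be preprocessed *except* deduplication, which would erase
#' the frequencies); ties are broken lexicographically. If fewer than `n`
#' distinct CDR3s exist, all are returned.
#'
#' @param records rearrangement tibble with `cdr3_aa` (and optionally
#'   `duplicate_count`).
#' @param n number of CDR3s to keep (>= 1).
#' @return character vector of CDR3 strings, most frequent first.
#' @export
top_n_cdr3 <- function(records, n = 100L) {
  n <- assert_count(n, "n", min = 1L)
  cdr3 <- records$cdr3_aa[!is.na(records$cdr3_aa)]
  dup <- if ("duplicate_count" %in% names(records)) {
    d <- records$duplicate_count[!is.na(records$cdr3_aa)]
    ifelse(is.na(d), 1L, as.integer(d))
  } else rep(1L, length(cdr3))
  if (!length(cdr3)) return(character())
  freq <- tapply(dup, cdr3, sum)
  ord <- order(-as.integer(freq), names(freq))
  head(names(freq)[ord], n)
}

#' CDR3 discrepancy percentages over a fixed input size
#'
#' Expresses counts of discrepant reads (e.g. reads whose CDR3 from one tool
#' has no counterpart in another, split by cause) as percentages of the
#' total input, rounded to the benchmark's reporting precision.
#'
#' @param counts named integer vector of discrepant-read counts.
#' @param n_input total number of input reads (> 0).
#' @param digits decimal places for reporting (default 2).
#' @return tibble with columns `category`, `count`, `pct`.
#' @export
discrepancy_percentages <- function(counts, n_input, digits = 2L) {
  if (n_input <= 0) stop("n_input must be positive", call. = FALSE)
  if (any(counts < 0) || any(counts > n_input)) {
    stop("counts must lie in [0, n_input]", call. = FALSE)
  }
  tibble::tibble(category = names(counts),
                 count = unname(as.integer(counts)),
                 pct = unname(round(100 * counts / n_input, digits)))
}

#' Processing speed of an annotation run
#'
#' Speed is sequences processed per minute per job:
#' `speed = n_sequences / (minutes * jobs)`.
#'
#' @param n_sequences sequences processed (> 0).
#' @param minutes wall-clock minutes (> 0).
#' @param jobs number of jobs/cores (> 0).
#' @return tibble with columns `n_sequences`, `minutes`, `jobs`, `speed`.
#' @export
processing_speed <- function(n_sequences, minutes, jobs) {
  if (any(c(n_sequences, minutes, jobs) <= 0)) {
    stop("n_sequences, minutes and jobs must all be positive", call. = FALSE)
  }
  tibble::tibble(n_sequences = n_sequences, minutes = minutes, jobs = jobs,
                 speed = n_sequences / (minutes * jobs))
}
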