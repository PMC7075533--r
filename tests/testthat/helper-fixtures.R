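# Shared fixture builders. Everything is constructed in code; no files.

# Minimal rearrangement tibble with sensible defaults, overridable per column.
make_rearrangements <- function(n = NULL, sequence_id = NULL, ...) {
  over <- list(...)
  if (is.null(n)) {
    n <- if (!is.null(sequence_id)) length(sequence_id)
    else max(c(1L, lengths(over)))
  }
  if (is.null(sequence_id)) sequence_id <- sprintf("S%06d", seq_len(n))
  out <- tibble::tibble(
    sequence_id = sequence_id,
    tool_label = "test",
    v_call = "IGHV1-1",
    d_call = "IGHD1-1",
    j_call = "IGHJ1-1",
    junction_aa = "CARDTAVW",
    cdr3_aa = "ARDTAV",
    productive = TRUE,
    stop_codon = FALSE,
    vj_in_frame = TRUE,
    locus = "IGH",
    duplicate_count = 1L)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# Reference set built directly from gene names (one *01 allele per gene,
# arbitrary distinct sequences unless supplied).
make_reference_from_genes <- function(genes, label = "fx",
                                      nt_sequence = NULL) {
  parsed <- airrbench::parse_gene_name(genes)
  if (is.null(nt_sequence)) {
    nt_sequence <- sprintf("ATG%s", vapply(seq_along(genes), function(i) {
      paste(rep(c("ACA", "GGA", "CTT")[(i %% 3) + 1], 3L + (i %% 5)),
            collapse = "")
    }, character(1)))
    nt_sequence <- paste0(nt_sequence, sprintf("%03d", seq_along(genes)))
  }
  airrbench::reference_set(tibble::tibble(
    allele_name = paste0(genes, "*01"),
    gene_name = genes,
    subgroup_name = parsed$subgroup_name,
    gene_type = parsed$gene_type,
    nt_sequence = nt_sequence,
    functionality = "F",
    orphon = FALSE), label = label)
}

# Ground-truth tibble built by hand.
make_truth <- function(n, v = "IGHV1-1", d = "IGHD1-1", j = "IGHJ1-1",
                       cdr3 = NULL) {
  if (is.null(cdr3)) cdr3 <- sprintf("ARDT%02dV", seq_len(n))
  tibble::tibble(
    sequence_id = sprintf("S%06d", seq_len(n)),
    lineage_id = sprintf("L%05d", seq_len(n)),
    true_v_gene = rep_len(v, n), true_d_gene = rep_len(d, n),
    true_j_gene = rep_len(j, n),
    nt_sequence = "ATG", junction_aa = paste0("C", cdr3, "W"),
    cdr3_aa = cdr3, productive = TRUE)
}

# Three germline gene-name sets whose V region structure matches the
# published comparison: per-tool V totals 55/104/97, 44 V genes in all
# three, V union 137; pooled with D and J the union is 183 with 73 shared.
make_benchmark_germline_sets <- function() {
  vg <- function(i) sprintf("IGHV%d-%d", (i %% 7) + 1, i)
  dg <- function(i) sprintf("IGHD%d-%d", (i %% 6) + 1, i)
  jg <- function(i) sprintf("IGHJ%d-%d", 1, i)
  v_all <- vg(1:44)                      # in all three tools
  v_ab <- vg(45:51)                      # igsim & igblast only (7)
  v_bc <- vg(52:75)                      # igblast & mixcr only (24)
  v_a <- vg(76:79); v_b <- vg(80:108); v_c <- vg(109:137)  # 4 / 29 / 29
  d_all <- dg(1:25); d_a <- dg(26:29); d_b <- dg(30:33); d_c <- dg(34:37)
  j_all <- jg(1:4); j_b <- jg(5:6); j_c <- jg(7:9)
  sets <- list(
    igsim = c(v_all, v_ab, v_a, d_all, d_a, j_all),
    igblast = c(v_all, v_ab, v_bc, v_b, d_all, d_b, j_all, j_b),
    mixcr = c(v_all, v_bc, v_c, d_all, d_c, j_all, j_c))
  lapply(names(sets), function(l) make_reference_from_genes(sets[[l]], l)) |>
    stats::setNames(names(sets))
}

# Change log matching the published ten-year per-type breakdown
# (9 gene removals, 37 gene additions, 98 allele additions, 54 sequence
# changes, 23 metadata changes; 221 changes in total).
make_benchmark_change_log <- function() {
  counts <- c(gene_removal = 9L, gene_addition = 37L, allele_addition = 98L,
              sequence_change = 54L, metadata_change = 23L)
  types <- rep(names(counts), counts)
  dates <- as.Date("2010-07-28") + round(seq(0, 3120, length.out = 221))
  airrbench::change_log(tibble::tibble(
    release_date = dates, change_type = types,
    target = sprintf("IGHV1-%d", seq_along(types))))
}

# Random CDR3-like strings (unique), for network property tests.
random_cdr3s <- function(n, min_len = 4, max_len = 9, alphabet = c("A", "R", "D")) {
  out <- character(0)
  while (length(out) < n) {
    len <- sample(min_len:max_len, n, replace = TRUE)
    new <- vapply(len, function(l) {
      paste(sample(alphabet, l, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

# Brute-force network oracle: all-pairs edit distance via utils::adist.
brute_force_links <- function(cdr3s) {
  if (length(cdr3s) < 2L) {
    return(tibble::tibble(from = character(), to = character()))
  }
  d <- utils::adist(cdr3s, cdr3s)
  idx <- which(d <= 1 & upper.tri(d), arr.ind = TRUE)
  a <- cdr3s[idx[, 1]]; b <- cdr3s[idx[, 2]]
  sw <- a > b; tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
  out <- unique(tibble::tibble(from = a, to = b))
  out[order(out$from, out$to), ]
}
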