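# Emulated annotator outputs: ground truth plus configurable error.
#
# An annotator profile injects gene mishits (uniform redraws among the other
# genes of the same type, or targeted confusion pairs), naming granularity
# (gene vs allele), CDR3 boundary convention (anchored junction vs core
# CDR3), dropped reads and productive-flag flips, so that downstream metric
# code sees outputs with known, recoverable error structure.

#' Annotator error profile
#'
#' @param tool_label label of the emulated tool.
#' @param mishit_rate_v,mishit_rate_d,mishit_rate_j per-read probability that
#'   the assigned gene of that type differs from truth (uniform redraw among
#'   the other genes of the type).
#' @param confusion_pairs optional list of targeted confusions, each a list
#'   `(true =, assigned =, p =)`; for reads whose true gene matches, the
#'   targeted confusion replaces the uniform redraw.
#' @param granularity `"gene"` reports bare gene names; `"allele"` appends
#'   the first allele designation.
#' @param cdr3_convention `"anchored"` reports the junction (leading C,
#'   trailing W) in the CDR3 field, as some tools do; `"core"` reports the
#'   CDR3 proper.
#' @param drop_rate probability a read yields no annotation row.
#' @param unproductive_flip_rate probability the productive flag is inverted.
#' @param seed integer seed.
#' @return list of class `annotator_profile`.
#' @export
annotator_profile <- function(tool_label,
                              mishit_rate_v = 0, mishit_rate_d = 0,
                              mishit_rate_j = 0, confusion_pairs = list(),
                              granularity = c("gene", "allele"),
                              cdr3_convention = c("core", "anchored"),
                              drop_rate = 0, unproductive_flip_rate = 0,
                              seed = 1L) {
  granularity <- match.arg(granularity)
  cdr3_convention <- match.arg(cdr3_convention)
  for (p in confusion_pairs) {
    stopifnot(all(c("true", "assigned", "p") %in% names(p)))
    assert_prob(p$p, "confusion pair probability")
  }
  structure(list(
    tool_label = tool_label,
    mishit_rate_v = assert_prob(mishit_rate_v, "mishit_rate_v"),
    mishit_rate_d = assert_prob(mishit_rate_d, "mishit_rate_d"),
    mishit_rate_j = assert_prob(mishit_rate_j, "mishit_rate_j"),
    confusion_pairs = confusion_pairs,
    granularity = granularity,
    cdr3_convention = cdr3_convention,
    drop_rate = assert_prob(drop_rate, "drop_rate"),
    unproductive_flip_rate = assert_prob(unproductive_flip_rate,
                                         "unproductive_flip_rate"),
    seed = as.integer(seed)), class = "annotator_profile")
}

#' Emulate one tool's annotation of a ground-truth repertoire
#'
#' Every non-dropped read yields one rearrangement row. Gene assignments
#' equal the truth except with the profile's mishit probability (or a
#' matching confusion pair), in which case a different gene of the same type
#' is drawn uniformly; with a single gene of a type no mishit is possible
#' and the truth is kept. Deterministic given `profile$seed`.
#'
#' @param truth a [generate_repertoire()] result.
#' @param profile an [annotator_profile()].
#' @param reference the [reference_set()] the truth was simulated from.
#' @return rearrangement tibble (AIRR-style columns, see
#'   [read_rearrangements()]).
#' @export
emulate_annotator <- function(truth, profile, reference) {
  stopifnot(inherits(profile, "annotator_profile"),
            inherits(reference, "reference_set"))
  al <- reference$alleles
  genes_of <- lapply(split(al$gene_name, al$gene_type), unique)
  first_allele <- function(gene) {
    vapply(gene, function(g) al$allele_name[match(g, al$gene_name)],
           character(1), USE.NAMES = FALSE)
  }
  check <- function(truth_genes, type) {
    missing <- setdiff(unique(truth_genes), genes_of[[type]])
    if (length(missing)) {
      stop(sprintf("true %s gene(s) not in reference: %s", type,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  check(truth$true_v_gene, "V"); check(truth$true_d_gene, "D")
  check(truth$true_j_gene, "J")

  n <- nrow(truth)
  conf <- profile$confusion_pairs
  withr::with_seed(profile$seed, {
    keep <- stats::runif(n) >= profile$drop_rate
    assign_gene <- function(true_gene, type, rate) {
      pool <- genes_of[[type]]
      out <- true_gene
      u <- stats::runif(n)
      handled <- rep(FALSE, n)
      for (cp in conf) {
        idx <- which(true_gene == cp$true & !handled)
        if (!length(idx)) next
        hit <- idx[u[idx] < cp$p]
        out[hit] <- cp$assigned
        handled[idx] <- TRUE
      }
      if (length(pool) > 1L) {
        mis <- which(!handled & u < rate)
        if (length(mis)) {
          out[mis] <- vapply(true_gene[mis], function(g) {
            others <- pool[pool != g]
            others[sample.int(length(others), 1L)]
          }, character(1), USE.NAMES = FALSE)
        }
      }
      out
    }
    v <- assign_gene(truth$true_v_gene, "V", profile$mishit_rate_v)
    d <- assign_gene(truth$true_d_gene, "D", profile$mishit_rate_d)
    jj <- assign_gene(truth$true_j_gene, "J", profile$mishit_rate_j)
    if (profile$granularity == "allele") {
      v <- first_allele(v); d <- first_allele(d); jj <- first_allele(jj)
    }
    flip <- stats::runif(n) < profile$unproductive_flip_rate
    productive <- xor(truth$productive, flip)
    out <- tibble::tibble(
      sequence_id = truth$sequence_id,
      tool_label = profile$tool_label,
      v_call = v, d_call = d, j_call = jj,
      junction_aa = truth$junction_aa,
      cdr3_aa = if (profile$cdr3_convention == "anchored")
        truth$junction_aa else truth$cdr3_aa,
      productive = productive,
      stop_codon = FALSE,
      vj_in_frame = productive,
      locus = "IGH",
      duplicate_count = 1L)
    out <- out[keep, , drop = FALSE]
    attr(out, "cdr3_convention") <- profile$cdr3_convention
    out
  })
}
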