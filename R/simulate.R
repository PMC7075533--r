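# Ground-truth repertoire simulation.
#
# Emulates a simulator-style repertoire: a pool of base antibody sequences,
# each built from a random V/D/J recombination with an in-frame junction
# (conserved Cys from V, conserved Trp from J), plus mutated sequences that
# descend from the bases through substitution-only lineage trees, mimicking
# substitution-dominated somatic hypermutation. "Diverse" compositions
# spread mutants uniformly over bases (many small clusters); "polarized"
# compositions allocate them by a power law (a few large clonal expansions).

#' Simulation configuration
#'
#' The two named presets mirror the benchmark's study compositions: the
#' diverse preset uses a 1:2 base:mutated ratio, the polarized preset 1:5.
#'
#' @param n_base number of base antibody sequences (>= 1).
#' @param n_mutated number of mutated sequences (>= 0).
#' @param composition `"diverse"` (uniform mutant allocation) or
#'   `"polarized"` (power-law allocation, exponent 1.5).
#' @param mutation_rate expected nucleotide substitutions per mutation event
#'   (Poisson, floored at one substitution).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_base, n_mutated,
                              composition = c("diverse", "polarized"),
                              mutation_rate = 5, seed = 1L) {
  composition <- match.arg(composition)
  n_base <- assert_count(n_base, "n_base", min = 1L)
  n_mutated <- assert_count(n_mutated, "n_mutated", min = 0L)
  if (mutation_rate < 0) stop("mutation_rate must be >= 0", call. = FALSE)
  structure(list(n_base = n_base, n_mutated = n_mutated,
                 composition = composition,
                 mutation_rate = as.numeric(mutation_rate),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Preset simulation configurations
#'
#' `diverse_config()` fixes the 1:2 base:mutated ratio of the diverse study
#' composition, `polarized_config()` the 1:5 polarized ratio, at a
#' configurable scale.
#'
#' @param n_base number of base sequences.
#' @param seed integer seed.
#' @param mutation_rate see [simulation_config()].
#' @return a [simulation_config()].
#' @export
diverse_config <- function(n_base = 1000L, seed = 1L, mutation_rate = 5) {
  simulation_config(n_base, 2L * n_base, "diverse",
                    mutation_rate = mutation_rate, seed = seed)
}

#' @rdname diverse_config
#' @export
polarized_config <- function(n_base = 200L, seed = 1L, mutation_rate = 5) {
  simulation_config(n_base, 5L * n_base, "polarized",
                    mutation_rate = mutation_rate, seed = seed)
}

#' Simulate a ground-truth repertoire
#'
#' Returns one record per sequence: `n_base` independent V(D)J recombinants
#' and `n_mutated` descendants. Each mutated record belongs to the lineage
#' of one base record (chosen uniformly for diverse compositions, by a
#' power-law weight with exponent 1.5 for polarized ones) and is derived
#' from a uniformly chosen earlier member of that lineage by `>= 1`
#' nucleotide substitutions; junction anchor codons are conserved and
#' substitutions creating in-frame stop codons are rejected, so every record
#' is productive. The junction is `C` + CDR3 + `W` by construction, with the
#' true D gene sequence embedded in the CDR3.
#'
#' @param reference a [reference_set()] with at least one V, D and J gene.
#' @param config a [simulation_config()].
#' @return tibble of class `ground_truth` with columns `sequence_id`,
#'   `lineage_id`, `true_v_gene`, `true_d_gene`, `true_j_gene`,
#'   `nt_sequence`, `junction_aa`, `cdr3_aa`, `productive`.
#' @export
generate_repertoire <- function(reference, config) {
  stopifnot(inherits(reference, "reference_set"),
            inherits(config, "simulation_config"))
  al <- reference$alleles
  genes <- split(al, al$gene_type)
  for (t in c("V", "D", "J")) {
    if (is.null(genes[[t]]) || nrow(genes[[t]]) == 0L) {
      stop(sprintf("reference contains no %s genes", t), call. = FALSE)
    }
  }
  # one representative (*01) allele per gene
  first_allele <- function(g) g[!duplicated(g$gene_name), , drop = FALSE]
  v <- first_allele(genes$V); d <- first_allele(genes$D)
  j <- first_allele(genes$J)

  n_base <- config$n_base; n_mut <- config$n_mutated
  withr::with_seed(config$seed, {
    vi <- sample.int(nrow(v), n_base, replace = TRUE)
    di <- sample.int(nrow(d), n_base, replace = TRUE)
    ji <- sample.int(nrow(j), n_base, replace = TRUE)
    bases <- vector("list", n_base)
    for (i in seq_len(n_base)) {
      v_nt <- v$nt_sequence[vi[i]]
      d_nt <- d$nt_sequence[di[i]]
      j_nt <- j$nt_sequence[ji[i]]
      d_aa <- translate_nt(d_nt)
      f1 <- random_aa(sample(2:5, 1L)); f2 <- random_aa(sample(2:5, 1L))
      cdr3_aa <- paste0(f1, d_aa, f2)
      mid_nt <- paste0(backtranslate_aa(f1), d_nt, backtranslate_aa(f2))
      nt <- paste0(v_nt, mid_nt, j_nt)
      bases[[i]] <- list(nt = nt,
                         cdr3_start = nchar(v_nt) + 1L,
                         cdr3_len = 3L * nchar(cdr3_aa),
                         cdr3_aa = cdr3_aa,
                         v = v$gene_name[vi[i]], d = d$gene_name[di[i]],
                         jg = j$gene_name[ji[i]])
    }
    # allocate mutants over bases
    if (n_mut > 0L) {
      weights <- if (config$composition == "polarized") {
        seq_len(n_base)^-1.5
      } else {
        rep(1, n_base)
      }
      alloc <- as.integer(stats::rmultinom(1L, n_mut, weights))
    } else {
      alloc <- integer(n_base)
    }

    rows <- vector("list", n_base + n_mut)
    k <- 0L
    for (i in seq_len(n_base)) {
      b <- bases[[i]]
      k <- k + 1L
      rows[[k]] <- list(lineage = i, nt = b$nt, cdr3_aa = b$cdr3_aa,
                        v = b$v, d = b$d, jg = b$jg)
      if (alloc[i] == 0L) next
      protect <- c(b$cdr3_start - (3:1), b$cdr3_start + b$cdr3_len + (0:2))
      lineage_nt <- b$nt           # member sequences, base first
      lineage_cdr3 <- b$cdr3_aa
      for (m in seq_len(alloc[i])) {
        parent <- sample.int(length(lineage_nt), 1L)
        repeat {
          n_sub <- max(1L, stats::rpois(1L, config$mutation_rate))
          child <- mutate_nt(lineage_nt[parent], n_sub, protect = protect)
          cdr3_nt <- substr(child, b$cdr3_start,
                            b$cdr3_start + b$cdr3_len - 1L)
          aa <- translate_nt(cdr3_nt)
          if (!grepl("*", aa, fixed = TRUE) && child != b$nt &&
              !grepl("*", translate_nt(child), fixed = TRUE)) break
        }
        lineage_nt <- c(lineage_nt, child)
        lineage_cdr3 <- c(lineage_cdr3, aa)
        k <- k + 1L
        rows[[k]] <- list(lineage = i, nt = child, cdr3_aa = aa,
                          v = b$v, d = b$d, jg = b$jg)
      }
    }
    out <- tibble::tibble(
      sequence_id = sprintf("S%06d", seq_along(rows)),
      lineage_id = sprintf("L%05d", vapply(rows, `[[`, integer(1), "lineage")),
      true_v_gene = vapply(rows, `[[`, character(1), "v"),
      true_d_gene = vapply(rows, `[[`, character(1), "d"),
      true_j_gene = vapply(rows, `[[`, character(1), "jg"),
      nt_sequence = vapply(rows, `[[`, character(1), "nt"),
      cdr3_aa = vapply(rows, `[[`, character(1), "cdr3_aa"),
      productive = TRUE)
    out$junction_aa <- paste0("C", out$cdr3_aa, "W")
    out <- out[, c("sequence_id", "lineage_id", "true_v_gene", "true_d_gene",
                   "true_j_gene", "nt_sequence", "junction_aa", "cdr3_aa",
                   "productive")]
    class(out) <- c("ground_truth", class(out))
    out
  })
}

#' Express a ground-truth repertoire as an AIRR-style rearrangement table
#'
#' The true genes become the calls, so the result is the output of a
#' hypothetical perfect annotator; useful for preprocessing and network
#' analysis of the truth itself.
#'
#' @param truth a [generate_repertoire()] result.
#' @param tool_label label recorded for the pseudo-tool.
#' @return rearrangement tibble (see [read_rearrangements()] for columns).
#' @export
as_rearrangements <- function(truth, tool_label = "truth") {
  tibble::tibble(
    sequence_id = truth$sequence_id,
    tool_label = tool_label,
    v_call = truth$true_v_gene,
    d_call = truth$true_d_gene,
    j_call = truth$true_j_gene,
    junction_aa = truth$junction_aa,
    cdr3_aa = truth$cdr3_aa,
    productive = truth$productive,
    stop_codon = FALSE,
    vj_in_frame = TRUE,
    locus = "IGH",
    duplicate_count = 1L)
}

#' Read / write ground-truth tables as TSV
#'
#' @param truth a `ground_truth` tibble.
#' @param path TSV file.
#' @return the truth tibble for the reader; `path` invisibly for the writer.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character(), productive = readr::col_logical()))
  class(out) <- c("ground_truth", class(out))
  out
}
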