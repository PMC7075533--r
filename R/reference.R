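# Germline reference sets: construction, FASTA serialization, parsing.
#
# A ReferenceSet is a light S3 container: a label, a release date and a
# tibble of alleles with the IMGT-style naming hierarchy
# (subgroup IGHV1 > gene IGHV1-18 > allele IGHV1-18*01).

#' Construct a germline reference set
#'
#' @param alleles tibble with columns `allele_name`, `gene_name`,
#'   `subgroup_name`, `gene_type` (`"V"`, `"D"` or `"J"`), `nt_sequence`,
#'   `functionality` (`"F"`, `"ORF"` or `"P"`) and `orphon` (logical).
#' @param label human-readable name of the set (e.g. a tool label).
#' @param release_date `Date` the set was released.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(alleles, label = "reference",
                          release_date = as.Date("2019-02-10")) {
  required <- c("allele_name", "gene_name", "subgroup_name", "gene_type",
                "nt_sequence", "functionality", "orphon")
  missing <- setdiff(required, names(alleles))
  if (length(missing)) {
    stop("alleles table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(alleles$allele_name)) {
    stop("allele names must be unique within a reference set", call. = FALSE)
  }
  structure(list(label = label, release_date = as.Date(release_date),
                 alleles = tibble::as_tibble(alleles)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  tab <- table(factor(x$alleles$gene_type, levels = c("V", "D", "J")))
  cat(sprintf("<reference_set> %s (%s): %d alleles (%d V / %d D / %d J), %d genes\n",
              x$label, format(x$release_date), nrow(x$alleles),
              tab[["V"]], tab[["D"]], tab[["J"]],
              length(unique(x$alleles$gene_name))))
  invisible(x)
}

#' Generate a synthetic germline reference set
#'
#' Builds a reference of random stop-free coding sequences with IMGT-style
#' names. V genes end in a conserved cysteine codon (`TGT`) and J genes begin
#' with a conserved tryptophan codon (`TGG`) so that junction extraction is
#' well defined downstream. Each gene carries 1--3 alleles; non-`*01` alleles
#' differ from the first by one or two substitutions. `n_synonyms` pairs of
#' distinct V gene names are given byte-identical allele sequences, emulating
#' the duplicate gene/allele names real references contain.
#'
#' @param n_v,n_d,n_j number of V, D and J genes (`n_v >= 1`, `n_j >= 1`
#'   for downstream repertoire simulation).
#' @param n_synonyms number of synonymous V gene pairs
#'   (`2 * n_synonyms <= n_v`).
#' @param seed integer seed; the result is a pure function of the arguments.
#' @param label set label.
#' @return a [reference_set()].
#' @export
generate_reference_set <- function(n_v, n_d, n_j, n_synonyms = 0L, seed = 1L,
                                   label = "synthetic") {
  n_v <- assert_count(n_v, "n_v"); n_d <- assert_count(n_d, "n_d")
  n_j <- assert_count(n_j, "n_j")
  n_synonyms <- assert_count(n_synonyms, "n_synonyms")
  if (n_v < 1L || n_j < 1L) {
    stop("a reference needs at least one V and one J gene", call. = FALSE)
  }
  if (2L * n_synonyms > n_v) {
    stop("need 2 * n_synonyms <= n_v to form disjoint synonym pairs",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    gene_rows <- function(type, n, n_subgroups, make_seq) {
      if (n == 0L) return(NULL)
      sg_idx <- ((seq_len(n) - 1L) %% n_subgroups) + 1L
      num <- stats::ave(seq_len(n), sg_idx, FUN = seq_along)
      gene <- sprintf("IGH%s%d-%d", type, sg_idx, num)
      lapply(seq_len(n), function(i) {
        base_nt <- make_seq()
        # keep the junction anchor codons invariant across alleles
        protect <- switch(type,
                          V = (nchar(base_nt) - 2L):nchar(base_nt),
                          J = 1:3,
                          integer(0))
        n_alleles <- sample.int(3L, 1L)
        nts <- character(n_alleles)
        nts[1L] <- base_nt
        if (n_alleles > 1L) for (a in 2:n_alleles) {
          nts[a] <- mutate_nt(base_nt, sample.int(2L, 1L), protect = protect)
        }
        tibble::tibble(
          allele_name = sprintf("%s*%02d", gene[i], seq_len(n_alleles)),
          gene_name = gene[i],
          subgroup_name = sprintf("IGH%s%d", type, sg_idx[i]),
          gene_type = type,
          nt_sequence = nts,
          functionality = "F",
          orphon = FALSE)
      })
    }
    v_seq <- function() paste0(random_coding_nt(97L), "TGT")
    d_seq <- function() random_coding_nt(sample(4:7, 1L))
    j_seq <- function() paste0("TGG", random_coding_nt(15L))
    v_rows <- gene_rows("V", n_v, min(n_v, 7L), v_seq)
    # synonym pairs: the top half gene copies its sequences into a partner
    if (n_synonyms > 0L) for (k in seq_len(n_synonyms)) {
      donor <- v_rows[[k]]
      r <- n_v - k + 1L
      twin <- donor
      twin$gene_name <- v_rows[[r]]$gene_name[1L]
      twin$subgroup_name <- v_rows[[r]]$subgroup_name[1L]
      twin$allele_name <- sprintf("%s*%02d", twin$gene_name, seq_len(nrow(twin)))
      v_rows[[r]] <- twin
    }
    alleles <- dplyr::bind_rows(c(v_rows,
                                  gene_rows("D", n_d, min(max(n_d, 1L), 7L), d_seq),
                                  gene_rows("J", n_j, 1L, j_seq)))
    reference_set(alleles, label = label)
  })
}

# Substitute n_sub random positions of a DNA string with different bases,
# avoiding `protect` positions. Uses the caller's RNG state.
mutate_nt <- function(nt, n_sub, protect = integer(0)) {
  chars <- strsplit(nt, "")[[1]]
  free <- setdiff(seq_along(chars), protect)
  pos <- free[sample.int(length(free), min(n_sub, length(free)))]
  for (p in pos) {
    chars[p] <- sample(setdiff(NT, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Write a reference set as FASTA with pipe-delimited headers
#'
#' Headers follow the IMGT GENE-DB style dialect
#' `>accession|allele_name|species|functionality`.
#'
#' @param ref a [reference_set()].
#' @param path output file.
#' @param species species field for the header.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, species = "Homo sapiens") {
  stopifnot(inherits(ref, "reference_set"))
  headers <- sprintf("SYN%05d|%s|%s|%s", seq_len(nrow(ref$alleles)),
                     ref$alleles$allele_name, species,
                     ref$alleles$functionality)
  seqs <- Biostrings::DNAStringSet(ref$alleles$nt_sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a germline reference FASTA
#'
#' Expects the pipe-delimited header dialect
#' `>accession|allele_name|species|functionality`. Orphon genes are flagged
#' from the name (a `/OR` infix or a trailing `D` on the gene name, per IMGT
#' orphon nomenclature).
#'
#' @param path FASTA file.
#' @param label label for the resulting set (defaults to the file name).
#' @return a [reference_set()]; an empty file yields an empty set with a
#'   warning.
#' @export
read_reference_fasta <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty reference FASTA: ", path, call. = FALSE)
    empty <- tibble::tibble(allele_name = character(), gene_name = character(),
                            subgroup_name = character(), gene_type = character(),
                            nt_sequence = character(), functionality = character(),
                            orphon = logical())
    return(reference_set(empty, label = label))
  }
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed FASTA header (expected 4 pipe-delimited fields): '%s'",
                 names(seqs)[bad[1L]]), call. = FALSE)
  }
  allele <- vapply(fields, `[[`, character(1), 2L)
  fun <- vapply(fields, `[[`, character(1), 4L)
  parsed <- parse_gene_name(allele)
  alleles <- tibble::tibble(
    allele_name = allele,
    gene_name = parsed$gene_name,
    subgroup_name = parsed$subgroup_name,
    gene_type = parsed$gene_type,
    nt_sequence = unname(as.character(seqs)),
    functionality = fun,
    orphon = grepl("/OR", parsed$gene_name) | grepl("D$", parsed$gene_name))
  reference_set(alleles, label = label)
}

#' Map synonymous gene or allele names to a canonical name
#'
#' Names whose nucleotide sequences are identical are grouped, and every
#' member maps to the lexicographically smallest name of its group; this is
#' the renaming step that prevents false mishits when distinct names carry
#' the same sequence. At the `gene` level two genes are synonymous when their
#' full (sorted) allele sequence sets are identical.
#'
#' @param ref a [reference_set()].
#' @param level `"gene"` or `"allele"`.
#' @return named character vector mapping each name to its canonical name
#'   (class `synonym_map`); idempotent by construction.
#' @export
build_synonym_map <- function(ref, level = c("gene", "allele")) {
  level <- match.arg(level)
  al <- ref$alleles
  if (level == "allele") {
    keys <- al$nt_sequence
    names_in <- al$allele_name
  } else {
    sets <- vapply(split(al$nt_sequence, al$gene_name),
                   function(s) paste(sort(s), collapse = ";"), character(1))
    keys <- unname(sets)
    names_in <- names(sets)
  }
  canonical <- stats::ave(names_in, keys, FUN = function(g) rep(min(g), length(g)))
  map <- stats::setNames(canonical, names_in)
  class(map) <- "synonym_map"
  map
}

#' Apply a synonym map to a vector of names
#'
#' Names absent from the map (or `NA`) pass through unchanged; allele
#' suffixes are preserved when the map is gene-level and the input carries
#' alleles of a mapped gene.
#'
#' @param x character vector of gene/allele names.
#' @param map a [build_synonym_map()] result, or `NULL` for a no-op.
#' @return canonicalized character vector.
#' @export
apply_synonyms <- function(x, map) {
  if (is.null(map)) return(x)
  m <- unclass(map)
  hit <- !is.na(x) & x %in% names(m)
  x[hit] <- unname(m[x[hit]])
  # gene-level map applied to allele names: canonicalize the gene part
  gene <- strip_allele(x)
  has_allele <- !is.na(x) & grepl("\\*", x)
  ghit <- has_allele & gene %in% names(m)
  if (any(ghit)) {
    suffix <- sub("^[^*]*", "", x[ghit])
    x[ghit] <- paste0(unname(m[gene[ghit]]), suffix)
  }
  x
}
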