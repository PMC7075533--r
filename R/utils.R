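# Shared helpers: genetic-code lookups, name parsing, validation.

NT <- c("A", "C", "G", "T")

# Standard genetic code as a named character vector, codon -> amino acid.
genetic_code <- function() {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  gc
}

# Codons per amino acid, stop codons excluded.
codons_by_aa <- function() {
  gc <- genetic_code()
  gc <- gc[gc != "*"]
  split(names(gc), gc)
}

#' Translate in-frame DNA strings to amino acids
#'
#' Vectorised standard-genetic-code translation; stop codons become `*`.
#' Used internally by the repertoire simulator, where reads are in frame by
#' construction.
#'
#' @param nt character vector of DNA strings whose lengths are multiples of 3.
#' @return character vector of amino-acid strings.
#' @keywords internal
translate_nt <- function(nt) {
  gc <- genetic_code()
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    stopifnot(n %% 3L == 0L)
    codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    paste(gc[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Back-translate an amino-acid string, sampling uniformly among synonymous
# codons. Relies on the calling function's RNG state.
backtranslate_aa <- function(aa) {
  tab <- codons_by_aa()
  if (nchar(aa) == 0L) return("")
  res <- vapply(strsplit(aa, "")[[1]], function(a) {
    choices <- tab[[a]]
    choices[sample.int(length(choices), 1L)]
  }, character(1))
  paste(res, collapse = "")
}

# Random stop-free coding DNA of n_codons codons.
random_coding_nt <- function(n_codons) {
  tab <- unlist(codons_by_aa(), use.names = FALSE)
  paste(tab[sample.int(length(tab), n_codons, replace = TRUE)], collapse = "")
}

# Amino-acid alphabet without the stop symbol.
AA_ALPHABET <- sort(unique(as.character(Biostrings::GENETIC_CODE)[
  as.character(Biostrings::GENETIC_CODE) != "*"]))

random_aa <- function(n) {
  paste(AA_ALPHABET[sample.int(length(AA_ALPHABET), n, replace = TRUE)],
        collapse = "")
}

#' Parse immunoglobulin gene names into their naming hierarchy
#'
#' Splits names such as `"IGHV1-18*01"` into subgroup (`IGHV1`), gene
#' (`IGHV1-18`) and allele components. Names without an allele suffix are
#' returned with `allele_name = NA`.
#'
#' @param x character vector of gene or allele names.
#' @return tibble with columns `allele_name`, `gene_name`, `subgroup_name`,
#'   `gene_type`.
#' @export
parse_gene_name <- function(x) {
  gene <- sub("\\*.*$", "", x)
  allele <- ifelse(grepl("\\*", x), x, NA_character_)
  subgroup <- regmatches(gene, regexpr("^IGH[VDJ][0-9]+", gene))
  subgroup <- ifelse(lengths(regmatches(gene, gregexpr("^IGH[VDJ][0-9]+", gene))) > 0,
                     sub("^(IGH[VDJ][0-9]+).*$", "\\1", gene), NA_character_)
  type <- substr(gene, 4L, 4L)
  type[!type %in% c("V", "D", "J")] <- NA_character_
  tibble::tibble(allele_name = allele, gene_name = gene,
                 subgroup_name = subgroup, gene_type = type)
}

# Strip allele suffixes ("IGHV1-18*01" -> "IGHV1-18").
strip_allele <- function(x) sub("\\*.*$", "", x)

# Format percentages the way the benchmark reports them (one decimal).
format_pct <- function(x) round(x, 1)

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

CHANGE_TYPES <- c("gene_removal", "gene_addition", "allele_addition",
                  "sequence_change", "metadata_change")
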