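#!/usr/bin/env Rscript
# Stage 1 — simulate the study inputs.
#
# Builds a synthetic germline reference (30 V / 10 D / 5 J genes, two
# synonymous V pairs) and two ground-truth repertoires: a diverse
# composition (1:2 base:mutated, many small clonal clusters) and a
# polarized one (1:5, a few large expansions), scaled to desk size.

suppressMessages(library(airrbench))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930L %% 1000L

ref <- generate_reference_set(n_v = 30, n_d = 10, n_j = 5, n_synonyms = 2,
                              seed = seed)
write_reference_fasta(ref, file.path(out, "reference.fasta"))
print(ref)

diverse <- generate_repertoire(ref, diverse_config(n_base = 1000, seed = seed))
polarized <- generate_repertoire(ref, polarized_config(n_base = 200,
                                                       seed = seed))
write_ground_truth(diverse, file.path(out, "truth_diverse.tsv"))
write_ground_truth(polarized, file.path(out, "truth_polarized.tsv"))

for (nm in c("diverse", "polarized")) {
  truth <- get(nm)
  sizes <- table(truth$lineage_id)
  cat(sprintf("%-9s: %d reads, %d lineages, mean cluster %.1f, max cluster %d\n",
              nm, nrow(truth), length(sizes), mean(sizes), max(sizes)))
}
cat("wrote", out, "\n")
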