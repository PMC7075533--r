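#!/usr/bin/env Rscript
# Stage 5 — unique CDR3 overlap between tools.
#
# Partitions each composition's unique CDR3 sets into exclusive regions at
# three stages: raw annotated output, preprocessed output, and the Top 100
# most frequent preprocessed CDR3s. Percentages are per tool: region count
# over that tool's total unique CDR3 count.

suppressMessages(library(airrbench))

data_dir <- "results/data"; ann_dir <- "results/annotations"
out <- "results/overlap"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ref <- read_reference_fasta(file.path(data_dir, "reference.fasta"))
synonyms <- build_synonym_map(ref, "gene")
tools <- c("toolA", "toolB", "toolC")
conventions <- c(toolA = "core", toolB = "anchored", toolC = "core")

for (comp in c("diverse", "polarized")) {
  sets_ann <- list(); sets_pre <- list(); sets_top <- list()
  for (label in tools) {
    raw <- read_rearrangements(file.path(ann_dir,
                                         sprintf("%s_%s.tsv", comp, label)),
                               tool_label = label)
    h <- harmonize(raw, conventions[[label]], synonyms = synonyms)
    filtered <- preprocess_filter(h)$records
    sets_ann[[label]] <- unique(stats::na.omit(h$cdr3_aa))
    sets_pre[[label]] <- filtered$cdr3_aa
    sets_top[[label]] <- top_n_cdr3(filtered, 100)
  }
  for (stage in c("annotated", "preprocessed", "top100")) {
    sets <- switch(stage, annotated = sets_ann, preprocessed = sets_pre,
                   top100 = sets_top)
    ov <- cdr3_overlap(sets, stage = stage)
    readr::write_tsv(ov$percentages,
                     file.path(out, sprintf("%s_%s.tsv", comp, stage)))
    all_label <- paste(tools, collapse = "&")
    shared <- ov$percentages[ov$percentages$region == all_label, ]
    cat(sprintf("%-9s %-12s: union %5d; shared-by-all %% per tool: %s\n",
                comp, stage, ov$union_size,
                paste(sprintf("%s %.1f", shared$tool, shared$pct),
                      collapse = ", ")))
  }
}
cat("wrote", out, "\n")
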