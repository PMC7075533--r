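# Synthetic-data generators: reference sets, repertoires, emulated
# annotators, change logs.

test_that("generate_reference_set honours counts, synonyms and preconditions", {
  ref <- generate_reference_set(5, 2, 3, n_synonyms = 1, seed = 1)
  al <- ref$alleles
  expect_equal(length(unique(al$gene_name[al$gene_type == "V"])), 5L)
  expect_equal(length(unique(al$gene_name[al$gene_type == "D"])), 2L)
  expect_equal(length(unique(al$gene_name[al$gene_type == "J"])), 3L)
  # exactly one pair of distinct V gene names shares identical sequences
  seq_sets <- vapply(split(al$nt_sequence[al$gene_type == "V"],
                           al$gene_name[al$gene_type == "V"]),
                     function(s) paste(sort(s), collapse = ";"), character(1))
  expect_equal(sum(duplicated(seq_sets)), 1L)
  # allele naming hierarchy invariants
  expect_true(all(grepl("^IGH[VDJ][0-9]+-[0-9]+\\*[0-9]{2}$", al$allele_name)))
  expect_true(all(startsWith(al$gene_name, al$subgroup_name)))
  expect_true(all(nchar(al$nt_sequence) > 0))
  expect_error(generate_reference_set(0, 0, 1, seed = 1), "at least one V")
  expect_error(generate_reference_set(-1, 2, 3), "n_v")
  expect_error(generate_reference_set(4, 1, 1, n_synonyms = 3), "synonym")
})

test_that("reference FASTA serialization is deterministic and round-trips", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.fasta"); p2 <- file.path(dir, "b.fasta")
  write_reference_fasta(generate_reference_set(5, 2, 3, 1, seed = 9), p1)
  write_reference_fasta(generate_reference_set(5, 2, 3, 1, seed = 9), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_reference_fasta(p1)
  orig <- generate_reference_set(5, 2, 3, 1, seed = 9)
  expect_equal(back$alleles$allele_name, orig$alleles$allele_name)
  expect_equal(back$alleles$nt_sequence, orig$alleles$nt_sequence)
  expect_equal(back$alleles$gene_type, orig$alleles$gene_type)
})

test_that("generate_repertoire conserves counts and lineage structure", {
  ref <- generate_reference_set(8, 4, 3, seed = 2)
  cfg <- simulation_config(100, 200, "diverse", seed = 3)
  rep1 <- generate_repertoire(ref, cfg)
  expect_equal(nrow(rep1), 300L)
  expect_identical(rep1, generate_repertoire(ref, cfg))  # seed determinism

  # degenerate input: no mutants, all lineages distinct
  rep0 <- generate_repertoire(ref, simulation_config(50, 0, "diverse", seed = 4))
  expect_equal(nrow(rep0), 50L)
  expect_false(anyDuplicated(rep0$lineage_id) > 0)

  # every true gene resolvable; junction anchors; mutants differ from base
  al <- ref$alleles
  expect_true(all(rep1$true_v_gene %in% al$gene_name[al$gene_type == "V"]))
  expect_true(all(rep1$true_d_gene %in% al$gene_name[al$gene_type == "D"]))
  expect_true(all(rep1$true_j_gene %in% al$gene_name[al$gene_type == "J"]))
  expect_identical(rep1$junction_aa, paste0("C", rep1$cdr3_aa, "W"))
  base <- rep1[!duplicated(rep1$lineage_id), ]
  mut <- rep1[duplicated(rep1$lineage_id), ]
  base_nt <- stats::setNames(base$nt_sequence, base$lineage_id)
  expect_true(all(mut$nt_sequence != base_nt[mut$lineage_id]))
  # substitution-only model: mutant length equals its base length
  expect_true(all(nchar(mut$nt_sequence) == nchar(base_nt[mut$lineage_id])))
  expect_error(generate_repertoire(
    make_reference_from_genes(c("IGHV1-1", "IGHJ1-1")), cfg), "no D genes")
})

test_that("diverse preset yields mean lineage size n_total / n_base", {
  ref <- generate_reference_set(10, 4, 3, seed = 5)
  rep <- generate_repertoire(ref, diverse_config(n_base = 1000, seed = 6))
  sizes <- table(rep$lineage_id)
  expect_equal(mean(sizes), 3)            # (1000 + 2000) / 1000
  expect_equal(length(sizes), 1000L)
})

test_that("polarized allocation is heavier-tailed than diverse", {
  ref <- generate_reference_set(10, 4, 3, seed = 5)
  div <- generate_repertoire(ref, simulation_config(200, 1000, "diverse", seed = 7))
  pol <- generate_repertoire(ref, simulation_config(200, 1000, "polarized", seed = 7))
  expect_gt(max(table(pol$lineage_id)), max(table(div$lineage_id)))
})

test_that("emulate_annotator identity and forced-complement cases", {
  ref <- generate_reference_set(6, 3, 2, seed = 11)
  truth <- generate_repertoire(ref, simulation_config(60, 60, seed = 11))
  perfect <- emulate_annotator(truth,
                               annotator_profile("perfect", seed = 1), ref)
  expect_equal(nrow(perfect), nrow(truth))
  expect_identical(perfect$v_call, truth$true_v_gene)
  expect_identical(perfect$d_call, truth$true_d_gene)
  expect_identical(perfect$j_call, truth$true_j_gene)

  always <- emulate_annotator(truth,
    annotator_profile("bad", mishit_rate_v = 1, seed = 2), ref)
  expect_true(all(always$v_call != truth$true_v_gene))

  # determinism contract
  p <- annotator_profile("t", mishit_rate_v = 0.3, drop_rate = 0.1, seed = 5)
  expect_identical(emulate_annotator(truth, p, ref),
                   emulate_annotator(truth, p, ref))

  # unknown true gene is a data error
  bad_truth <- truth
  bad_truth$true_v_gene[1] <- "IGHV9-99"
  expect_error(emulate_annotator(bad_truth, p, ref), "IGHV9-99")
})

test_that("injected mishit rates are recovered within 3 binomial SDs", {
  ref <- generate_reference_set(12, 5, 4, seed = 21)
  truth <- generate_repertoire(ref, simulation_config(2500, 2500, seed = 21))
  for (p in c(0, 0.1, 0.5, 1)) {
    ann <- emulate_annotator(truth,
      annotator_profile("t", mishit_rate_v = p, seed = 31 + round(100 * p)),
      ref)
    observed <- mean(ann$v_call != truth$true_v_gene)
    tol <- 3 * sqrt(p * (1 - p) / nrow(ann))
    expect_lte(abs(observed - p), max(tol, 1e-12))
  }
})

test_that("annotator conventions round-trip: anchored = C + core + W", {
  ref <- generate_reference_set(5, 3, 2, seed = 41)
  truth <- generate_repertoire(ref, simulation_config(40, 40, seed = 41))
  core <- emulate_annotator(truth,
    annotator_profile("c", cdr3_convention = "core", seed = 3), ref)
  anch <- emulate_annotator(truth,
    annotator_profile("a", cdr3_convention = "anchored", seed = 3), ref)
  expect_identical(anch$cdr3_aa, paste0("C", core$cdr3_aa, "W"))

  allele <- emulate_annotator(truth,
    annotator_profile("al", granularity = "allele", seed = 3), ref)
  expect_true(all(grepl("\\*[0-9]{2}$", allele$v_call)))
  expect_identical(sub("\\*.*$", "", allele$v_call), truth$true_v_gene)

  dropped <- emulate_annotator(truth,
    annotator_profile("d", drop_rate = 0.5, seed = 3), ref)
  expect_lt(nrow(dropped), nrow(truth))
})

test_that("generate_change_log respects rates, dates and determinism", {
  empty <- generate_change_log(3, rates = c(allele_addition = 0), seed = 1)
  expect_equal(nrow(empty$events), 0L)
  expect_equal(length(empty$release_dates), 3L)

  only_add <- generate_change_log(2, rates = c(gene_addition = 3), seed = 8)
  expect_true(all(only_add$events$change_type == "gene_addition"))

  a <- generate_change_log(6, rates = c(allele_addition = 2, gene_removal = 1),
                           seed = 13)
  expect_identical(a$events,
                   generate_change_log(6, rates = c(allele_addition = 2,
                                                    gene_removal = 1),
                                       seed = 13)$events)
  expect_true(!is.unsorted(a$events$release_date))
  expect_equal(as.numeric(diff(a$release_dates), units = "days"),
               rep(91, 5))   # 13 weeks
})
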