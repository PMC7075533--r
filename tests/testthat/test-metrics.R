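# Accuracy and overlap metrics.

test_that("primary_call takes the first listed gene and handles no-calls", {
  rec <- make_rearrangements(
    n = 3,
    v_call = c("IGHV3-53,IGHV3-66", "IGHV1-1", NA),
    j_call = c(NA, "", "IGHJ1-1"))
  expect_equal(primary_call(rec, "V"),
               c("IGHV3-53", "IGHV1-1", "no call"))
  expect_equal(primary_call(rec, "J"), c("no call", "no call", "IGHJ1-1"))

  # synonym canonicalization turns a synonym of the truth into the truth
  ref <- make_reference_from_genes(c("IGHV3-30", "IGHV9-99"),
                                   nt_sequence = c("AAA", "AAA"))
  syn <- build_synonym_map(ref, "gene")
  rec2 <- make_rearrangements(v_call = "IGHV9-99")
  expect_equal(primary_call(rec2, "V", synonyms = syn), "IGHV3-30")
})

test_that("mishit_frequency computes K/N at gene level", {
  truth <- make_truth(5, v = c("IGHV1-1", "IGHV1-1", "IGHV2-2", "IGHV2-2",
                               "IGHV2-2"))
  ann <- make_rearrangements(
    sequence_id = truth$sequence_id,
    v_call = c("IGHV1-1", "IGHV2-2", "IGHV2-2", "IGHV2-2", "IGHV2-2"))
  mf <- mishit_frequency(ann, truth, "V")
  expect_equal(mf$K, 1L)
  expect_equal(mf$N, 5L)
  expect_equal(mf$frequency, 0.2)

  perfect <- make_rearrangements(sequence_id = truth$sequence_id,
                                 v_call = truth$true_v_gene)
  expect_equal(mishit_frequency(perfect, truth, "V")$frequency, 0)

  # no-call reads are excluded from the denominator
  ann$v_call[1] <- NA
  mf2 <- mishit_frequency(ann, truth, "V")
  expect_equal(mf2$N, 4L)

  none <- ann; none$v_call <- NA
  expect_true(is.na(mishit_frequency(none, truth, "V")$frequency))

  rogue <- make_rearrangements(sequence_id = "ZZZ")
  expect_error(mishit_frequency(rogue, truth, "V"), "absent")

  # allele-granularity annotations are compared at the gene level
  allele_ann <- make_rearrangements(sequence_id = truth$sequence_id,
                                    v_call = paste0(truth$true_v_gene, "*01"))
  expect_equal(mishit_frequency(allele_ann, truth, "V")$frequency, 0)
})

test_that("emulated mishit rates are recovered by the metric (binomial oracle)", {
  ref <- generate_reference_set(10, 4, 3, seed = 51)
  truth <- generate_repertoire(ref, simulation_config(1500, 1500, seed = 51))
  syn <- build_synonym_map(ref, "gene")
  for (p in c(0, 0.05, 0.3)) {
    ann <- emulate_annotator(truth,
      annotator_profile("t", mishit_rate_v = p, seed = 61 + round(100 * p)),
      ref)
    mf <- mishit_frequency(harmonize(ann, "core", synonyms = syn),
                           truth, "V", synonyms = syn)
    tol <- 3 * sqrt(p * (1 - p) / mf$N)
    expect_lte(abs(mf$frequency - p), max(tol, 1e-12))
  }
})

test_that("subgroup rows partition the cumulative mishit counts", {
  truth <- make_truth(8, v = rep(c("IGHV3-1", "IGHV3-2", "IGHV1-1", "IGHV1-2"),
                                 each = 2))
  ann <- make_rearrangements(
    sequence_id = truth$sequence_id,
    v_call = c("IGHV3-1", "IGHV9-9", "IGHV3-2", "IGHV3-2",
               truth$true_v_gene[5:8]))
  rows <- subgroup_mishit_frequencies(ann, truth, "V")
  total <- mishit_frequency(ann, truth, "V")
  expect_equal(sum(rows$W), total$K)
  expect_equal(sum(rows$X), total$N)
  expect_equal(rows$frequency[rows$subgroup == "IGHV3"], 0.25)
  expect_equal(rows$frequency[rows$subgroup == "IGHV1"], 0)
})

test_that("confusion matrix rows are conditional assignment distributions", {
  truth <- make_truth(4, v = "IGHV1-1")
  ann <- make_rearrangements(
    sequence_id = truth$sequence_id,
    v_call = c("IGHV1-1", "IGHV1-1", "IGHV1-1", "IGHV2-2"))
  m <- confusion_matrix(ann, truth, "V")
  expect_equal(m["IGHV1-1", "IGHV1-1"], 0.75)
  expect_equal(m["IGHV1-1", "IGHV2-2"], 0.25)
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)))

  # perfect annotator -> identity matrix
  truth2 <- make_truth(6, v = rep(c("IGHV1-1", "IGHV2-2", "IGHV3-3"), 2))
  perfect <- make_rearrangements(sequence_id = truth2$sequence_id,
                                 v_call = truth2$true_v_gene)
  m2 <- confusion_matrix(perfect, truth2, "V")
  expect_equal(unname(m2), diag(3))
})

test_that("a configured confusion pair is recovered at its probability", {
  genes <- c("IGHV3-66", "IGHV3-53", "IGHV1-1", "IGHD1-1", "IGHJ1-1")
  ref <- make_reference_from_genes(genes)
  truth <- make_truth(2000, v = "IGHV3-66")
  prof <- annotator_profile("mixcr-like",
    confusion_pairs = list(list(true = "IGHV3-66", assigned = "IGHV3-53",
                                p = 0.49)), seed = 77)
  ann <- emulate_annotator(truth, prof, ref)
  m <- confusion_matrix(ann, truth, "V")
  tol <- 3 * sqrt(0.49 * 0.51 / 2000)
  expect_lte(abs(m["IGHV3-66", "IGHV3-53"] - 0.49), tol)
})

test_that("K/N equals one minus trace-weighted confusion accuracy", {
  withr::with_seed(123, {
    for (i in 1:5) {
      genes_v <- sprintf("IGHV%d-1", 1:4)
      truth <- make_truth(300, v = sample(genes_v, 300, replace = TRUE))
      ann <- make_rearrangements(
        sequence_id = truth$sequence_id,
        v_call = ifelse(runif(300) < 0.3,
                        sample(genes_v, 300, replace = TRUE),
                        truth$true_v_gene))
      mf <- mishit_frequency(ann, truth, "V")
      m <- confusion_matrix(ann, truth, "V")
      counts <- table(truth$true_v_gene)
      acc <- sum(vapply(rownames(m), function(g) {
        if (g %in% colnames(m)) m[g, g] * counts[[g]] else 0
      }, numeric(1))) / sum(counts)
      expect_equal(mf$frequency, 1 - acc, tolerance = 1e-12)
    }
  })
})

test_that("cdr3_overlap partitions sets and percentages sum to 100", {
  ov <- cdr3_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  reg <- stats::setNames(ov$regions$count, ov$regions$region)
  expect_equal(unname(reg[c("A", "B", "A&B")]), c(1, 1, 2))
  pa <- ov$percentages[ov$percentages$tool == "A", ]
  expect_equal(pa$pct[pa$region == "A&B"], 200 / 3, tolerance = 1e-9)
  expect_equal(pa$pct[pa$region == "A"], 100 / 3, tolerance = 1e-9)

  ident <- cdr3_overlap(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$percentages$pct[ident$percentages$region == "A&B"],
               c(100, 100))

  disj <- cdr3_overlap(list(A = "x", B = "y"))
  expect_equal(disj$shared_all, 0L)

  # per-tool percentages sum to 100 on random sets
  withr::with_seed(5, {
    for (i in 1:10) {
      sets <- lapply(1:3, function(j) {
        sample(sprintf("C%02d", 1:30), sample(5:25, 1))
      })
      names(sets) <- c("A", "B", "C")
      ov <- cdr3_overlap(sets)
      sums <- tapply(ov$percentages$pct, ov$percentages$tool, sum)
      expect_true(all(abs(sums - 100) < 0.1))
    }
  })
  expect_error(cdr3_overlap(list(A = "x")), "two tools")
})

test_that("top_n_cdr3 ranks by weighted frequency with lexicographic ties", {
  rec <- make_rearrangements(
    n = 12,
    cdr3_aa = c(rep("XRRRR", 5), rep("YAAAA", 3), rep("YBBBB", 3), "WWWWW"))
  expect_equal(top_n_cdr3(rec, 2), c("XRRRR", "YAAAA"))   # YAAAA < YBBBB
  expect_equal(top_n_cdr3(rec, 99),
               c("XRRRR", "YAAAA", "YBBBB", "WWWWW"))
  expect_equal(top_n_cdr3(rec, 1), "XRRRR")

  # duplicate_count weighting dominates raw row counts
  rec2 <- make_rearrangements(n = 3, cdr3_aa = c("AAAAA", "BBBBB", "BBBBB"),
                              duplicate_count = c(10L, 1L, 1L))
  expect_equal(top_n_cdr3(rec2, 1), "AAAAA")
})

test_that("discrepancy percentages reproduce count/total arithmetic", {
  out <- discrepancy_percentages(c(no_overlap = 51791), 759505)
  expect_equal(out$pct, 6.82)
  expect_error(discrepancy_percentages(c(x = 10), 0), "positive")
  expect_error(discrepancy_percentages(c(x = 10), 5), "counts")
})

test_that("processing_speed follows the sequences/(minutes*jobs) formula", {
  expect_equal(processing_speed(1000, 10, 2)$speed, 50)
  expect_equal(processing_speed(1000, 10, 1)$speed, 100)
  expect_error(processing_speed(1000, 10, 0), "positive")
})
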