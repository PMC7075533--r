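# Germline comparison: FASTA parsing, membership partitions, change
# tabulation, interval statistics, synonym maps.

test_that("read_reference_fasta parses the pipe-delimited header dialect", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ref.fasta")
  writeLines(c(">X1|IGHV1-18*01|Homo sapiens|F", "CAGGT",
               ">X2|IGHJ4-1*02|Homo sapiens|ORF", "TGGAA",
               ">X3|IGHV1-69D*01|Homo sapiens|F", "CCCGG"), p)
  ref <- read_reference_fasta(p)
  al <- ref$alleles
  expect_equal(al$allele_name[1], "IGHV1-18*01")
  expect_equal(al$gene_name[1], "IGHV1-18")
  expect_equal(al$subgroup_name[1], "IGHV1")
  expect_equal(al$gene_type, c("V", "J", "V"))
  expect_equal(al$functionality, c("F", "ORF", "F"))
  expect_equal(al$nt_sequence[1], "CAGGT")
  expect_equal(al$orphon, c(FALSE, FALSE, TRUE))  # trailing-D orphon name

  empty <- file.path(dir, "empty.fasta")
  file.create(empty)
  expect_warning(e <- read_reference_fasta(empty), "empty")
  expect_equal(nrow(e$alleles), 0L)

  bad <- file.path(dir, "bad.fasta")
  writeLines(c(">justaname", "ACGT"), bad)
  expect_error(read_reference_fasta(bad), "malformed.*justaname")
})

test_that("intersect_references performs exact set algebra", {
  sets <- list(A = make_reference_from_genes(c("IGHV1-1", "IGHV1-2", "IGHV1-3")),
               B = make_reference_from_genes(c("IGHV1-2", "IGHV1-3", "IGHV1-4")),
               C = make_reference_from_genes("IGHV1-3"))
  mt <- intersect_references(sets, level = "gene")
  expect_equal(mt$shared_all, 1L)
  expect_equal(mt$union_size, 4L)
  expect_equal(mt$shared_pct, 25)
  regions <- stats::setNames(mt$regions$count, mt$regions$region)
  expect_equal(unname(regions[c("A", "B", "A&B", "A&B&C")]), c(1, 1, 1, 1))

  same <- intersect_references(stats::setNames(list(sets$A, sets$A),
                                               c("A", "B")), level = "gene")
  expect_equal(same$shared_pct, 100)
  expect_true(all(same$regions$count[same$regions$n_sets == 1] == 0))

  expect_error(intersect_references(sets["A"], "gene"), "at least two")
})

test_that("membership regions always sum to the union (subset-enumeration oracle)", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      k <- sample(2:4, 1)
      items <- lapply(seq_len(k), function(i) {
        sample(sprintf("IGHV1-%d", 1:15), sample(3:12, 1))
      })
      names(items) <- LETTERS[seq_len(k)]
      mt <- airrbench:::membership_table(items)
      universe <- unique(unlist(items))
      expect_equal(sum(mt$regions$count), length(universe))
      # oracle: enumerate every subset and count items exclusive to it
      for (r in seq_len(nrow(mt$regions))) {
        lbls <- strsplit(mt$regions$region[r], "&", fixed = TRUE)[[1]]
        inside <- Reduce(intersect, items[lbls])
        outside <- unique(unlist(items[setdiff(names(items), lbls)]))
        expect_equal(mt$regions$count[r], length(setdiff(inside, outside)))
      }
      # per-set total = sum of regions containing that label
      for (lbl in names(items)) {
        contains <- vapply(strsplit(mt$regions$region, "&", fixed = TRUE),
                           function(x) lbl %in% x, logical(1))
        expect_equal(sum(mt$regions$count[contains]), mt$totals[[lbl]])
      }
    }
  })
})

test_that("tabulate_changes counts per type and is additive over windows", {
  log <- change_log(tibble::tibble(
    release_date = as.Date("2015-01-01") + c(0, 0, 30, 30, 60),
    change_type = c("gene_removal", "gene_removal", "gene_addition",
                    "gene_addition", "gene_addition"),
    target = sprintf("g%d", 1:5)))
  s <- tabulate_changes(log)
  expect_equal(unname(s$per_type[c("gene_removal", "gene_addition")]), c(2L, 3L))
  expect_equal(s$total, 5L)
  expect_equal(sum(colSums(s$per_release[-1])), s$total)

  none <- tabulate_changes(log, from_date = "2020-01-01", to_date = "2020-06-01")
  expect_equal(none$total, 0L)
  expect_true(all(none$per_type == 0L))

  first <- tabulate_changes(log, to_date = "2015-01-31")
  second <- tabulate_changes(log, from_date = "2015-02-01")
  expect_equal(first$per_type + second$per_type, s$per_type)
  expect_error(tabulate_changes(log, from_date = "2016-01-01",
                                to_date = "2015-01-01"), "from_date")
})

test_that("update_interval_stats uses fractional weeks and nearest-rank p90", {
  dates <- as.Date("2015-01-01") + cumsum(c(0, 91, 91))   # 13-week gaps
  log <- change_log(tibble::tibble(
    release_date = rep(dates, each = 4),
    change_type = "allele_addition",
    target = sprintf("g%d", 1:12)))
  st <- update_interval_stats(log)
  expect_equal(st$mean_interval_weeks, 13)
  expect_equal(st$mean_changes_per_update, 4)

  # intervals 1..10 weeks -> nearest-rank p90 is the 9th order statistic
  dates10 <- as.Date("2015-01-01") + cumsum(c(0, (1:10) * 7))
  log10 <- change_log(tibble::tibble(release_date = dates10,
                                     change_type = "metadata_change",
                                     target = "g"),
                      release_dates = dates10)
  expect_equal(update_interval_stats(log10)$p90_interval_weeks, 9)

  single <- change_log(tibble::tibble(release_date = as.Date("2015-01-01"),
                                      change_type = "gene_addition",
                                      target = "g"))
  expect_error(update_interval_stats(single), "two distinct")
})

test_that("build_synonym_map groups identical sequences under the smallest name", {
  genes <- c("IGHV3-30", "IGHV9-99", "IGHV1-1")
  ref <- make_reference_from_genes(genes,
                                   nt_sequence = c("AAA", "AAA", "CCC"))
  map <- build_synonym_map(ref, level = "gene")
  expect_equal(unname(unclass(map)[c("IGHV3-30", "IGHV9-99", "IGHV1-1")]),
               c("IGHV3-30", "IGHV3-30", "IGHV1-1"))
  # idempotence: applying the map twice equals applying once
  once <- apply_synonyms(genes, map)
  expect_identical(apply_synonyms(once, map), once)

  # no duplicates -> identity map
  id_map <- build_synonym_map(make_reference_from_genes(genes), "gene")
  expect_identical(unname(unclass(id_map)), names(unclass(id_map)))
  expect_identical(apply_synonyms(genes, id_map), genes)

  # three-way duplicate group maps to the single smallest name
  ref3 <- make_reference_from_genes(c("IGHV5-5", "IGHV2-2", "IGHV7-7"),
                                    nt_sequence = rep("GGG", 3))
  map3 <- build_synonym_map(ref3, "gene")
  expect_true(all(unclass(map3) == "IGHV2-2"))
})

test_that("change logs round-trip through TSV", {
  dir <- withr::local_tempdir()
  log <- generate_change_log(4, rates = c(allele_addition = 3,
                                          sequence_change = 1), seed = 3)
  p <- file.path(dir, "log.tsv")
  write_change_log(log, p)
  back <- read_change_log(p)
  expect_equal(back$events, log$events)
})
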