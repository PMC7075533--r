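# End-to-end benchmark orchestration.
#
# A benchmark config names the tools (existing AIRR TSV files or synthetic
# annotator profiles), the germline reference, optional ground truth, the
# stages to run and an output directory. Synthetic-profile tools are
# materialized to AIRR TSV on disk first, so real exports and emulated
# outputs flow through identical code paths.

BENCHMARK_STAGES <- c("preprocess", "mishits", "overlap", "network", "speed")

#' Assemble a benchmark configuration
#'
#' @param tools named list; each element is either a path to an AIRR
#'   rearrangement TSV or an [annotator_profile()].
#' @param reference path to a reference FASTA, or a [reference_set()].
#' @param truth path to a ground-truth TSV, or a `ground_truth` tibble;
#'   required for the mishit stage and for synthetic-profile tools.
#' @param stages subset of preprocess, mishits, overlap, network, speed.
#' @param out_dir output directory (created if needed).
#' @param top_n Top-N CDR3 cut-off for the overlap stage.
#' @param seed integer master seed.
#' @param speed optional tibble/data.frame with columns `tool`,
#'   `n_sequences`, `minutes`, `jobs` for the speed stage.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(tools, reference, truth = NULL,
                             stages = c("preprocess", "mishits", "overlap",
                                        "network"),
                             out_dir = tempfile("airrbench"), top_n = 100L,
                             seed = 1L, speed = NULL) {
  stages <- match.arg(stages, BENCHMARK_STAGES, several.ok = TRUE)
  if (is.null(names(tools)) || any(names(tools) == "")) {
    stop("tools must be a named list", call. = FALSE)
  }
  if (length(tools) < 2L && length(intersect(stages, c("overlap", "network")))) {
    stop("overlap and network stages need at least two tools", call. = FALSE)
  }
  structure(list(tools = tools, reference = reference, truth = truth,
                 stages = stages, out_dir = out_dir,
                 top_n = assert_count(top_n, "top_n", min = 1L),
                 seed = as.integer(seed), speed = speed),
            class = "benchmark_config")
}

#' Read a benchmark configuration from JSON
#'
#' Tool entries with a `path` field reference AIRR TSV files; entries with a
#' `profile` field are synthetic annotator profiles (fields as in
#' [annotator_profile()]).
#'
#' @param path JSON file.
#' @return a [benchmark_config()].
#' @export
read_benchmark_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  tools <- lapply(cfg$tools, function(t) {
    if (!is.null(t$path)) return(t$path)
    p <- t$profile
    do.call(annotator_profile, c(list(tool_label = t$label), p))
  })
  names(tools) <- vapply(cfg$tools, `[[`, character(1), "label")
  benchmark_config(tools = tools, reference = cfg$reference,
                   truth = cfg$truth,
                   stages = cfg$stages %||% c("preprocess", "mishits",
                                              "overlap", "network"),
                   out_dir = cfg$out_dir %||% tempfile("airrbench"),
                   top_n = cfg$top_n %||% 100L, seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full benchmark
#'
#' Stages run in dependency order (harmonize/preprocess feed overlap and
#' network; mishits needs ground truth). The run is a pure function of the
#' configuration, including all seeds. Per-stage record counts are logged
#' with `message()`.
#'
#' @param config a [benchmark_config()].
#' @return object of class `benchmark_report` with per-stage tables.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  stages <- config$stages
  needs_truth <- "mishits" %in% stages ||
    any(vapply(config$tools, inherits, logical(1), "annotator_profile"))
  if (needs_truth && is.null(config$truth)) {
    stop("configuration error: ground truth is required for the mishit ",
         "stage and for synthetic annotator profiles", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  reference <- if (inherits(config$reference, "reference_set"))
    config$reference else read_reference_fasta(config$reference)
  truth <- if (is.null(config$truth)) NULL
  else if (inherits(config$truth, "data.frame")) config$truth
  else read_ground_truth(config$truth)
  synonyms <- build_synonym_map(reference, level = "gene")
  orphons <- unique(reference$alleles$gene_name[reference$alleles$orphon])

  # materialize every tool to disk, then read all back identically
  ann_dir <- file.path(config$out_dir, "annotations")
  dir.create(ann_dir, showWarnings = FALSE)
  conventions <- list()
  paths <- list()
  for (label in names(config$tools)) {
    t <- config$tools[[label]]
    if (inherits(t, "annotator_profile")) {
      tab <- emulate_annotator(truth, t, reference)
      p <- file.path(ann_dir, paste0(label, ".tsv"))
      write_rearrangements(tab, p)
      conventions[[label]] <- t$cdr3_convention
      paths[[label]] <- p
    } else {
      if (!file.exists(t)) stop("unreadable input file: ", t, call. = FALSE)
      conventions[[label]] <- "core"
      paths[[label]] <- t
    }
  }
  raw <- lapply(names(paths), function(label) {
    x <- read_rearrangements(paths[[label]], tool_label = label)
    message(sprintf("[%s] read %d records", label, nrow(x)))
    harmonize(x, cdr3_convention = conventions[[label]],
              synonyms = synonyms, granularity = "gene")
  })
  names(raw) <- names(paths)

  report <- list(config_stages = stages, skipped = list(),
                 meta = list(seed = config$seed, tools = names(raw),
                             top_n = config$top_n))

  filtered <- NULL
  if (any(c("preprocess", "overlap", "network") %in% stages)) {
    filtered <- lapply(names(raw), function(label) {
      res <- preprocess_filter(raw[[label]], orphon_genes = orphons)
      message(sprintf("[%s] preprocess: %d -> %d records", label,
                      res$report$input_count, res$report$output_count))
      res
    })
    names(filtered) <- names(raw)
    report$filter_reports <- lapply(filtered, `[[`, "report")
  }

  if ("mishits" %in% stages) {
    report$mishits <- lapply(names(raw), function(label) {
      dplyr::bind_rows(lapply(c("V", "D", "J"), function(g) {
        mishit_frequency(raw[[label]], truth, g, synonyms = synonyms)
      }))
    })
    names(report$mishits) <- names(raw)
  }

  if ("overlap" %in% stages) {
    sets_ann <- lapply(raw, function(x) unique(stats::na.omit(x$cdr3_aa)))
    sets_pre <- lapply(filtered, function(f) f$records$cdr3_aa)
    # Top-N wants frequencies: rerun the filter without its dedup step by
    # reusing the pre-dedup multiplicities carried in duplicate_count
    sets_top <- lapply(filtered, function(f) {
      top_n_cdr3(f$records, n = config$top_n)
    })
    report$overlap <- list(
      annotated = cdr3_overlap(sets_ann, stage = "annotated"),
      preprocessed = cdr3_overlap(sets_pre, stage = "preprocessed"),
      topN = cdr3_overlap(sets_top, stage = "topN"))
  }

  if ("network" %in% stages) {
    nets <- lapply(filtered, function(f) build_network(f$records$cdr3_aa))
    labels <- names(nets)
    subsets <- list()
    for (k in 2:length(labels)) {
      for (cmb in utils::combn(labels, k, simplify = FALSE)) {
        shared <- Reduce(intersect, lapply(cmb, function(l) nets[[l]]$nodes))
        subsets[[paste(cmb, collapse = "&")]] <- shared
      }
    }
    # degrees are measured in each subset's member networks only
    report$network <- list(
      networks = lapply(nets, function(n)
        list(n_nodes = length(n$nodes), n_links = nrow(n$links),
             average_degree = n$average_degree,
             classification = classify_diversity(n))),
      subnetwork_degrees = subnetwork_degree_matrix(nets, subsets),
      correlations = local({
        res <- list()
        for (cmb in utils::combn(labels, 2L, simplify = FALSE)) {
          shared <- intersect(nets[[cmb[1]]]$nodes, nets[[cmb[2]]]$nodes)
          key <- paste(cmb, collapse = "&")
          if (length(shared) >= 3L) {
            res[[key]] <- degree_correlations(
              nets[[cmb[1]]]$degree[shared], nets[[cmb[2]]]$degree[shared])
          }
        }
        res
      }))
  }

  if ("speed" %in% stages) {
    if (is.null(config$speed)) {
      report$skipped$speed <- "no timing records in configuration"
    } else {
      sp <- config$speed
      report$speed <- dplyr::bind_rows(lapply(seq_len(nrow(sp)), function(i) {
        tibble::tibble(tool = sp$tool[i],
                       processing_speed(sp$n_sequences[i], sp$minutes[i],
                                        sp$jobs[i]))
      }))
    }
  }

  for (s in setdiff(BENCHMARK_STAGES, stages)) {
    report$skipped[[s]] <- "stage not requested"
  }
  class(report) <- "benchmark_report"
  report
}

#' Write a benchmark report to disk
#'
#' One TSV per result table plus a JSON summary; rewriting into the same
#' directory is an idempotent overwrite.
#'
#' @param report a [run_benchmark()] result.
#' @param directory output directory (created if needed).
#' @return tibble manifest of written files (also written as
#'   `manifest.tsv`).
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(tab, name) {
    p <- file.path(directory, name)
    readr::write_tsv(tab, p)
    files <<- c(files, name)
  }
  if (!is.null(report$filter_reports)) {
    put(dplyr::bind_rows(lapply(names(report$filter_reports), function(l) {
      r <- report$filter_reports[[l]]
      tibble::tibble(tool = l, rule = c("input", names(r$removed_per_rule),
                                        "output", "unique_cdr3"),
                     count = c(r$input_count, unname(r$removed_per_rule),
                               r$output_count, r$unique_cdr3_count))
    })), "filter_report.tsv")
  }
  if (!is.null(report$mishits)) {
    put(dplyr::bind_rows(lapply(names(report$mishits), function(l) {
      tibble::tibble(tool = l, report$mishits[[l]])
    })), "mishit_summary.tsv")
  }
  if (!is.null(report$overlap)) {
    for (stage in names(report$overlap)) {
      put(report$overlap[[stage]]$percentages,
          sprintf("overlap_%s.tsv", stage))
    }
  }
  if (!is.null(report$network)) {
    put(dplyr::bind_rows(lapply(names(report$network$networks), function(l) {
      tibble::tibble(tool = l, tibble::as_tibble(report$network$networks[[l]]))
    })), "network_summary.tsv")
    m <- report$network$subnetwork_degrees
    put(tibble::tibble(network = rownames(m),
                       tibble::as_tibble(as.data.frame(m))),
        "subnetwork_degrees.tsv")
    if (length(report$network$correlations)) {
      put(dplyr::bind_rows(lapply(names(report$network$correlations),
                                  function(l) {
        cr <- report$network$correlations[[l]]
        tibble::tibble(pair = l, r = cr$r, tau = cr$tau, n = cr$n)
      })), "correlations.tsv")
    }
  }
  if (!is.null(report$speed)) put(report$speed, "speed.tsv")

  summary <- list(stages = report$config_stages, meta = report$meta,
                  skipped = report$skipped, tables = files)
  jsonlite::write_json(summary, file.path(directory, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, "summary.json")
  manifest <- tibble::tibble(file = files)
  readr::write_tsv(manifest, file.path(directory, "manifest.tsv"))
  manifest
}
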