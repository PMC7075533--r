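# Germline database comparison: membership partitions across reference sets
# at four naming levels, and change-history tabulation over releases.

#' Intersect reference sets at a chosen naming level
#'
#' Compares two or more germline sets as exact-string item sets at the
#' subgroup, gene, allele or nucleotide-sequence level (the nt level counts
#' identical sequence strings), and partitions the union into exclusive
#' regions -- one per non-empty subset of set labels, as in an UpSet plot.
#' The shared-by-all percentage is the size of the all-sets region over the
#' union, rounded to integer percent.
#'
#' @param sets list of [reference_set()] objects (at least two), optionally
#'   named; unnamed entries take their set labels.
#' @param level one of `"subgroup"`, `"gene"`, `"allele"`, `"nt_sequence"`.
#' @param gene_type_filter optional `"V"`, `"D"` or `"J"` to restrict the
#'   comparison to one gene class.
#' @return object of class `membership_table` with fields `level`, `totals`
#'   (named per-set item counts), `regions` (tibble of region/count),
#'   `union_size`, `shared_all` and `shared_pct`.
#' @export
intersect_references <- function(sets,
                                 level = c("subgroup", "gene", "allele",
                                           "nt_sequence"),
                                 gene_type_filter = NULL) {
  level <- match.arg(level)
  if (length(sets) < 2L) {
    stop("need at least two reference sets to intersect", call. = FALSE)
  }
  labels <- names(sets)
  if (is.null(labels)) labels <- rep("", length(sets))
  labels <- ifelse(labels == "",
                   vapply(sets, function(s) s$label, character(1)), labels)
  if (anyDuplicated(labels)) stop("set labels must be unique", call. = FALSE)
  items <- lapply(sets, function(s) {
    al <- s$alleles
    if (!is.null(gene_type_filter)) al <- al[al$gene_type %in% gene_type_filter, ]
    unique(switch(level,
                  subgroup = al$subgroup_name,
                  gene = al$gene_name,
                  allele = al$allele_name,
                  nt_sequence = al$nt_sequence))
  })
  names(items) <- labels
  membership_table(items, level = level)
}

# Core set-partition computation over a named list of item vectors.
membership_table <- function(items, level = "gene") {
  labels <- names(items)
  universe <- unique(unlist(items, use.names = FALSE))
  memb <- vapply(items, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL, labels))
  # every non-empty subset of labels, smallest first
  subsets <- unlist(lapply(seq_along(labels), function(k) {
    combn(labels, k, simplify = FALSE)
  }), recursive = FALSE)
  region_of <- apply(memb, 1L, function(r) paste(labels[r], collapse = "&"))
  region_labels <- vapply(subsets, paste, character(1), collapse = "&")
  counts <- as.integer(table(factor(region_of, levels = region_labels)))
  regions <- tibble::tibble(region = region_labels,
                            n_sets = lengths(subsets),
                            count = counts)
  totals <- vapply(items, function(s) length(unique(s)), integer(1))
  shared_all <- counts[length(counts)]
  union_size <- length(universe)
  structure(list(level = level, totals = totals, regions = regions,
                 union_size = union_size, shared_all = shared_all,
                 shared_pct = if (union_size > 0)
                   round(100 * shared_all / union_size) else NA_real_),
            class = "membership_table")
}

#' @export
print.membership_table <- function(x, ...) {
  cat(sprintf("<membership_table> level=%s, union=%d, shared by all=%d (%s%%)\n",
              x$level, x$union_size, x$shared_all, x$shared_pct))
  print(x$regions)
  invisible(x)
}

#' Construct a germline change log
#'
#' @param events tibble with columns `release_date` (`Date`), `change_type`
#'   (one of the five tracked categories: gene removal/addition, allele
#'   addition, sequence change, metadata change) and `target`.
#' @param release_dates optional vector of all release dates, including
#'   releases that introduced no change; defaults to the distinct event
#'   dates.
#' @return object of class `change_log`, events sorted by date.
#' @export
change_log <- function(events, release_dates = NULL) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("release_date", "change_type", "target") %in% names(events)))
  bad <- setdiff(unique(events$change_type), CHANGE_TYPES)
  if (length(bad)) {
    stop("unknown change_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  events$release_date <- as.Date(events$release_date)
  events <- events[order(events$release_date), , drop = FALSE]
  if (is.null(release_dates)) release_dates <- unique(events$release_date)
  release_dates <- sort(as.Date(release_dates))
  structure(list(events = events, release_dates = release_dates),
            class = "change_log")
}

#' Generate a synthetic germline change log
#'
#' Releases are spaced `interval_weeks` apart from `start_date`; per-release
#' counts of each change type are Poisson draws around the given rates.
#'
#' @param n_releases number of releases (>= 1).
#' @param rates named numeric vector of expected per-release counts for the
#'   five change types (missing types default to 0).
#' @param start_date first release date.
#' @param interval_weeks spacing between releases, in weeks.
#' @param seed integer seed.
#' @return a [change_log()].
#' @export
generate_change_log <- function(n_releases, rates = c(allele_addition = 2),
                                start_date = as.Date("2010-07-28"),
                                interval_weeks = 13, seed = 1L) {
  n_releases <- assert_count(n_releases, "n_releases", min = 1L)
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  full_rates <- stats::setNames(numeric(length(CHANGE_TYPES)), CHANGE_TYPES)
  full_rates[names(rates)] <- rates
  dates <- as.Date(start_date) + round((seq_len(n_releases) - 1L) *
                                         interval_weeks * 7)
  withr::with_seed(seed, {
    ev <- lapply(seq_len(n_releases), function(i) {
      counts <- stats::rpois(length(full_rates), full_rates)
      if (sum(counts) == 0L) return(NULL)
      tibble::tibble(release_date = dates[i],
                     change_type = rep(CHANGE_TYPES, counts),
                     target = sprintf("IGHV%d-%d", sample.int(7, sum(counts),
                                                              replace = TRUE),
                                      sample.int(99, sum(counts),
                                                 replace = TRUE)))
    })
    events <- dplyr::bind_rows(ev)
    if (nrow(events) == 0L) {
      events <- tibble::tibble(release_date = as.Date(character()),
                               change_type = character(), target = character())
    }
    change_log(events, release_dates = dates)
  })
}

#' Tabulate germline changes over a date window
#'
#' Counts change events with release date inside the inclusive window, per
#' change type and in total, plus per-release increments.
#'
#' @param log a [change_log()].
#' @param from_date,to_date optional window bounds (inclusive).
#' @return object of class `change_summary`: `per_type` (named counts over
#'   the five types), `total`, and `per_release` (tibble of per-date
#'   increments).
#' @export
tabulate_changes <- function(log, from_date = NULL, to_date = NULL) {
  stopifnot(inherits(log, "change_log"))
  ev <- log$events
  if (!is.null(from_date) && !is.null(to_date) &&
      as.Date(from_date) > as.Date(to_date)) {
    stop("from_date must be <= to_date", call. = FALSE)
  }
  if (!is.null(from_date)) ev <- ev[ev$release_date >= as.Date(from_date), ]
  if (!is.null(to_date)) ev <- ev[ev$release_date <= as.Date(to_date), ]
  per_type <- vapply(CHANGE_TYPES, function(t) sum(ev$change_type == t),
                     integer(1))
  if (nrow(ev) == 0L) {
    per_release <- tibble::tibble(release_date = as.Date(character()))
    for (t in CHANGE_TYPES) per_release[[t]] <- integer()
  } else {
    tab <- table(as.character(ev$release_date),
                 factor(ev$change_type, levels = CHANGE_TYPES))
    per_release <- tibble::tibble(release_date = as.Date(rownames(tab)))
    for (t in CHANGE_TYPES) per_release[[t]] <- as.integer(tab[, t])
  }
  structure(list(per_type = per_type, total = sum(per_type),
                 per_release = per_release),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("<change_summary> total=%d\n", x$total))
  print(x$per_type)
  invisible(x)
}

#' Release interval and change-load statistics
#'
#' Intervals are successive release-date gaps in fractional weeks (days/7);
#' changes per update counts events at each release (releases without events
#' count zero). Percentiles use the nearest-rank definition, with no
#' interpolation.
#'
#' @param log a [change_log()] with at least two distinct release dates.
#' @return list of class `interval_stats`: `mean_interval_weeks`,
#'   `mean_changes_per_update`, `p90_interval_weeks`,
#'   `p90_changes_per_update`.
#' @export
update_interval_stats <- function(log) {
  stopifnot(inherits(log, "change_log"))
  dates <- sort(unique(log$release_dates))
  if (length(dates) < 2L) {
    stop("need at least two distinct release dates", call. = FALSE)
  }
  intervals <- as.numeric(diff(dates), units = "days") / 7
  changes <- vapply(dates, function(d) sum(log$events$release_date == d),
                    integer(1))
  nearest_rank <- function(x, p) {
    x <- sort(x)
    x[ceiling(p * length(x))]
  }
  structure(list(mean_interval_weeks = mean(intervals),
                 mean_changes_per_update = mean(changes),
                 p90_interval_weeks = nearest_rank(intervals, 0.9),
                 p90_changes_per_update = nearest_rank(changes, 0.9)),
            class = "interval_stats")
}

#' Read / write change logs as TSV
#'
#' Columns: `release_date` (ISO 8601), `change_type`, `target`.
#'
#' @param path TSV file.
#' @param log a [change_log()].
#' @return [change_log()] for the reader; `path` invisibly for the writer.
#' @export
read_change_log <- function(path) {
  ev <- readr::read_tsv(path, col_types = readr::cols(
    release_date = readr::col_date(), change_type = readr::col_character(),
    target = readr::col_character()))
  change_log(ev)
}

#' @rdname read_change_log
#' @export
write_change_log <- function(log, path) {
  stopifnot(inherits(log, "change_log"))
  readr::write_tsv(log$events, path)
  invisible(path)
}
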