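# CDR3 similarity networks.
#
# Nodes are unique CDR3 amino-acid strings; links connect pairs at
# Levenshtein distance <= 1 (one substitution, insertion or deletion).
# Identical strings are one node, so links always join distinct strings.
# Edge enumeration uses masked-position hashing within length buckets
# (pairs with length difference > 1 can never link), which is exactly
# equivalent to the all-pairs edit-distance computation.

#' Are two distinct strings within Levenshtein distance one?
#'
#' Unit-cost substitution/insertion/deletion edit distance, with early
#' exits: identical strings return `FALSE` (one node, not a link) and a
#' length difference above one returns `FALSE` without computing anything.
#'
#' @param a,b non-empty strings.
#' @return `TRUE` iff `a != b` and their edit distance is <= 1.
#' @export
levenshtein_leq1 <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      nchar(a) == 0L || nchar(b) == 0L) {
    stop("a and b must be single non-empty strings", call. = FALSE)
  }
  if (a == b) return(FALSE)
  na <- nchar(a); nb <- nchar(b)
  if (abs(na - nb) > 1L) return(FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (na == nb) {
    return(sum(ca != cb) == 1L)
  }
  # length difference one: b (say) must equal a with one character deleted
  if (na < nb) { tmp <- ca; ca <- cb; cb <- tmp }      # ca is the longer
  i <- 1L
  while (i <= length(cb) && ca[i] == cb[i]) i <- i + 1L
  all(ca[-i] == cb)
}

#' Build a CDR3 similarity network
#'
#' @param cdr3s character vector of unique, non-empty CDR3 strings.
#' @return object of class `cdr3_network`: `nodes`, `links` (tibble of
#'   `from`/`to`, `from < to`), `degree` (named integer vector) and
#'   `average_degree` (`2 * |links| / |nodes|`, 0 for an empty network).
#' @export
build_network <- function(cdr3s) {
  if (anyDuplicated(cdr3s)) {
    stop("CDR3 node set must not contain duplicates", call. = FALSE)
  }
  if (any(is.na(cdr3s) | nchar(cdr3s) == 0L)) {
    stop("CDR3 nodes must be non-empty strings", call. = FALSE)
  }
  n <- length(cdr3s)
  pairs_from <- character(0); pairs_to <- character(0)
  add_pairs <- function(a, b) {
    sw <- a > b
    tmp <- a[sw]; a[sw] <- b[sw]; b[sw] <- tmp
    pairs_from <<- c(pairs_from, a); pairs_to <<- c(pairs_to, b)
  }
  if (n > 1L) {
    len <- nchar(cdr3s)
    by_len <- split(cdr3s, len)
    lens <- as.integer(names(by_len))
    for (L in lens) {
      grp <- by_len[[as.character(L)]]
      # substitution links: strings equal after masking one position
      if (length(grp) > 1L) {
        for (p in seq_len(L)) {
          key <- paste0(substr(grp, 1L, p - 1L), "\r",
                        substr(grp, p + 1L, L))
          dupkey <- key[duplicated(key)]
          if (!length(dupkey)) next
          for (kk in unique(dupkey)) {
            members <- grp[key == kk]
            cmb <- combn(members, 2L)
            add_pairs(cmb[1L, ], cmb[2L, ])
          }
        }
      }
      # indel links against the next-shorter bucket
      shorter <- by_len[[as.character(L - 1L)]]
      if (!is.null(shorter) && L >= 2L) {
        for (p in seq_len(L)) {
          del <- paste0(substr(grp, 1L, p - 1L), substr(grp, p + 1L, L))
          hit <- del %in% shorter
          if (any(hit)) add_pairs(grp[hit], del[hit])
        }
      }
    }
  }
  links <- unique(tibble::tibble(from = pairs_from, to = pairs_to))
  links <- links[order(links$from, links$to), , drop = FALSE]
  degree <- stats::setNames(integer(n), cdr3s)
  if (nrow(links)) {
    tab <- table(c(links$from, links$to))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(nodes = cdr3s, links = links, degree = degree,
                 average_degree = if (n > 0) 2 * nrow(links) / n else 0),
            class = "cdr3_network")
}

#' @export
print.cdr3_network <- function(x, ...) {
  cat(sprintf("<cdr3_network> %d nodes, %d links, average degree %.3f\n",
              length(x$nodes), nrow(x$links), x$average_degree))
  invisible(x)
}

#' Classify repertoire diversity from network topology
#'
#' Diverse repertoires (many small clonal clusters) give average degree
#' below 0.5; polarized repertoires (few large expansions) above 0.5;
#' exactly 0.5 is reported as `"boundary"`.
#'
#' @param network a non-empty [build_network()] result.
#' @return `"diverse"`, `"boundary"` or `"polarized"`.
#' @export
classify_diversity <- function(network) {
  stopifnot(inherits(network, "cdr3_network"))
  if (length(network$nodes) == 0L) {
    stop("cannot classify an empty network", call. = FALSE)
  }
  if (network$average_degree < 0.5) "diverse"
  else if (network$average_degree > 0.5) "polarized"
  else "boundary"
}

#' Average degree of shared-CDR3 sub-networks in each parent network
#'
#' Rows are parent networks (the tool whose links are used) and columns are
#' shared-CDR3 subsets (tool pair/triple overlaps). A cell is the mean
#' degree of the subset's nodes *measured in the row's full network* --
#' links to nodes outside the subset count -- so the same sub-network can
#' have different average degree in different parent networks. Set
#' `induced = TRUE` to instead count only links internal to the subset
#' (induced-subgraph degrees).
#'
#' @param networks named list of [build_network()] objects.
#' @param subsets named list of CDR3 character vectors; every subset must be
#'   contained in every row network's nodes.
#' @param induced measure induced-subgraph degrees instead of parent-network
#'   degrees.
#' @return numeric matrix, rows = networks, columns = subsets.
#' @export
shared_subnetwork_degrees <- function(networks, subsets, induced = FALSE) {
  stopifnot(length(networks) >= 1L, length(subsets) >= 1L)
  out <- matrix(NA_real_, length(networks), length(subsets),
                dimnames = list(names(networks), names(subsets)))
  for (r in names(networks)) {
    net <- networks[[r]]
    for (s in names(subsets)) {
      nodes <- subsets[[s]]
      missing <- setdiff(nodes, net$nodes)
      if (length(missing)) {
        stop(sprintf("subset '%s' node '%s' is absent from network '%s'",
                     s, missing[1L], r), call. = FALSE)
      }
      if (induced) {
        keep <- net$links$from %in% nodes & net$links$to %in% nodes
        ln <- net$links[keep, , drop = FALSE]
        deg <- stats::setNames(integer(length(nodes)), nodes)
        if (nrow(ln)) {
          tab <- table(c(ln$from, ln$to))
          deg[names(tab)] <- as.integer(tab)
        }
        out[r, s] <- mean(deg)
      } else {
        out[r, s] <- mean(net$degree[nodes])
      }
    }
  }
  out
}

#' Pearson and Kendall correlation of paired degree vectors
#'
#' Compares the degrees of the same shared CDR3s measured in two networks.
#' Kendall's tau uses the tie-corrected tau-b, appropriate for heavily tied
#' degree vectors. Constant vectors make both coefficients undefined; the
#' result is then `NA` with a reason.
#'
#' @param degrees_a,degrees_b numeric vectors of equal length >= 3, aligned
#'   by CDR3.
#' @return list of class `correlation_result`: `r`, `tau`, `n`, `reason`
#'   (`NA` unless undefined).
#' @export
degree_correlations <- function(degrees_a, degrees_b) {
  if (length(degrees_a) != length(degrees_b)) {
    stop("degree vectors must have equal length", call. = FALSE)
  }
  n <- length(degrees_a)
  if (n < 3L) stop("need at least three paired degrees", call. = FALSE)
  if (stats::sd(degrees_a) == 0 || stats::sd(degrees_b) == 0) {
    return(structure(list(r = NA_real_, tau = NA_real_, n = n,
                          reason = "constant degree vector"),
                     class = "correlation_result"))
  }
  structure(list(r = stats::cor(degrees_a, degrees_b, method = "pearson"),
                 tau = stats::cor(degrees_a, degrees_b, method = "kendall"),
                 n = n, reason = NA_character_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat(sprintf("<correlation_result> undefined (%s), n=%d\n", x$reason, x$n))
  } else {
    cat(sprintf("<correlation_result> r=%.3f, tau=%.3f, n=%d\n",
                x$r, x$tau, x$n))
  }
  invisible(x)
}

#' Export a network as an edge-list TSV
#'
#' @param network a [build_network()] object.
#' @param path output file; isolated nodes are listed with an empty `to`.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  iso <- setdiff(network$nodes, c(network$links$from, network$links$to))
  edges <- dplyr::bind_rows(
    network$links,
    tibble::tibble(from = iso, to = rep(NA_character_, length(iso))))
  readr::write_tsv(edges, path)
  invisible(path)
}

#' Membership-aware sub-network degree matrix
#'
#' Assembles the row-by-column matrix of [shared_subnetwork_degrees()] for
#' tool-overlap subsets named like `"A&B"`, measuring each subset only in
#' the networks of its member tools (a pair's shared CDR3s need not exist in
#' a third tool's network); non-member cells are `NA`.
#'
#' @param networks named list of [build_network()] objects.
#' @param subsets named list of shared CDR3 sets, names `&`-joined member
#'   tool labels.
#' @param induced see [shared_subnetwork_degrees()].
#' @return numeric matrix, rows = networks, columns = subsets, `NA` where
#'   the row tool is not a member of the column subset.
#' @export
subnetwork_degree_matrix <- function(networks, subsets, induced = FALSE) {
  out <- matrix(NA_real_, length(networks), length(subsets),
                dimnames = list(names(networks), names(subsets)))
  for (s in names(subsets)) {
    members <- intersect(strsplit(s, "&", fixed = TRUE)[[1]], names(networks))
    if (!length(members)) next
    m <- shared_subnetwork_degrees(networks[members], subsets[s],
                                   induced = induced)
    out[members, s] <- m[, 1]
  }
  out
}
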