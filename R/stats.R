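#' One-mode projection of a bipartite network
#'
#' Projects the bipartite network onto one node class: two drivers are
#' connected by the regime shifts they jointly cause, two regime shifts by
#' the drivers they share. Edge weight is the shared-neighbour count.
#'
#' @param network a [bipartite_network] or 0/1 incidence matrix.
#' @param side which class to project onto: `"driver"` (columns) or
#'   `"shift"` (rows).
#' @return an object of class `one_mode_projection`: list with `weights`
#'   (symmetric integer matrix, zero diagonal), `side`, and `node_names`.
#' @export
project_one_mode <- function(network, side = c("driver", "shift")) {
  side <- match.arg(side)
  m <- as_incidence(network)
  if (length(m) == 0 || sum(m) == 0) stop("cannot project an empty network")
  w <- if (side == "driver") crossprod(m) else tcrossprod(m)
  diag(w) <- 0L
  storage.mode(w) <- "integer"
  structure(list(weights = w, side = side, node_names = rownames(w)),
            class = "one_mode_projection")
}

#' @export
print.one_mode_projection <- function(x, ...) {
  cat(sprintf("one_mode_projection (%s side): %d nodes, %d weighted edges\n",
              x$side, nrow(x$weights), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Mean degree of a one-mode projection
#'
#' Average number of neighbours per node in the binarized projection, i.e.
#' how many other drivers (or shifts) a node co-occurs with at least once.
#'
#' @param projection a [project_one_mode] result.
#' @return a single number.
#' @export
mean_degree <- function(projection) {
  w <- projection$weights
  mean(rowSums(w > 0))
}

#' Co-occurrence index of a bipartite network
#'
#' Counts open triangles: two same-class nodes attached to a common
#' opposite-class node, one co-occurrence event. For the driver side, every
#' regime shift with degree k contributes choose(k, 2) driver pairs.
#'
#' Three normalizations are returned. `index` divides the count by the number
#' of node pairs on the chosen side (mean co-occurrences per pair);
#' `per_connected_pair` divides by the number of pairs that co-occur at least
#' once. The latter varies across degree-preserving randomizations (the raw
#' count and per-pair index are fully determined by the degree sequences, so
#' only `per_connected_pair` is informative against fixed-margin nulls).
#'
#' @inheritParams project_one_mode
#' @return list with `index`, `open_triangle_count`, `per_connected_pair`,
#'   `connected_pairs`, `n_pairs`.
#' @export
co_occurrence_index <- function(network, side = c("driver", "shift")) {
  side <- match.arg(side)
  m <- as_incidence(network)
  n_side <- if (side == "driver") ncol(m) else nrow(m)
  if (n_side < 2)
    stop("co-occurrence index undefined for fewer than 2 nodes")
  opp_deg <- if (side == "driver") rowSums(m) else colSums(m)
  count <- sum(choose(opp_deg, 2))
  w <- if (side == "driver") crossprod(m) else tcrossprod(m)
  diag(w) <- 0
  connected <- sum(w[upper.tri(w)] > 0)
  list(index = count / choose(n_side, 2),
       open_triangle_count = as.integer(count),
       per_connected_pair = if (connected > 0) count / connected else NA_real_,
       connected_pairs = as.integer(connected),
       n_pairs = choose(n_side, 2))
}

#' Bipartite clustering coefficient (four-cycle closure)
#'
#' Ratio of closed four-link paths (squares, the bipartite analogue of a
#' closed triangle) to open three-link paths. Each square contains four of
#' the counted three-paths, so `cc = 4 * squares / three_paths`; `cc` is 1
#' for complete bipartite graphs and undefined (NA) when no three-path
#' exists. Subgraphs are counted unlabelled and non-induced.
#'
#' @inheritParams project_one_mode
#' @return list with `cc`, `squares`, `three_paths`. When `three_paths` is 0,
#'   `cc` is `NA` and carries `attr(, "undefined") = TRUE`.
#' @export
bipartite_clustering_coefficient <- function(network) {
  m <- as_incidence(network)
  rd <- rowSums(m)
  cd <- colSums(m)
  s <- tcrossprod(m)
  squares <- sum(choose(s[upper.tri(s)], 2))
  three_paths <- sum(m * outer(rd - 1, cd - 1))
  cc <- if (three_paths > 0) 4 * squares / three_paths else {
    x <- NA_real_; attr(x, "undefined") <- TRUE; x
  }
  list(cc = cc, squares = as.integer(squares),
       three_paths = as.integer(three_paths))
}

#' NODF nestedness
#'
#' Nestedness by overlap and decreasing fill: for each node pair on one side,
#' the paired overlap is the percentage of the smaller-degree node's links
#' shared with the strictly larger-degree node, and 0 when degrees are equal.
#' Row-pair, column-pair, and pooled averages are returned on the usual
#' 0-100 scale, together with each node's mean overlap across the pairs it
#' participates in (used e.g. to order nodes by nestedness).
#'
#' @inheritParams project_one_mode
#' @return list with `nodf_total`, `nodf_rows`, `nodf_cols`, and
#'   `per_node_contribution` (named vector over rows then columns).
#' @export
nodf_nestedness <- function(network) {
  m <- as_incidence(network)
  if (sum(m) == 0) stop("cannot compute NODF of an empty network")
  side_terms <- function(a) {
    # a: incidence with the side of interest as rows
    deg <- rowSums(a)
    n <- nrow(a)
    if (n < 2)
      return(list(mean = 0, pairs = 0, contrib = stats::setNames(rep(NA_real_, n),
                                                                 rownames(a))))
    ov <- tcrossprod(a)
    dmin <- outer(deg, deg, pmin)
    deq <- outer(deg, deg, "==")
    val <- matrix(0, n, n)
    ok <- !deq & dmin > 0
    val[ok] <- 100 * ov[ok] / dmin[ok]
    diag(val) <- NA
    contrib <- rowMeans(val, na.rm = TRUE)
    names(contrib) <- rownames(a)
    ut <- val[upper.tri(val)]
    list(mean = mean(ut), pairs = length(ut), contrib = contrib)
  }
  r <- side_terms(m)
  c <- side_terms(t(m))
  total <- (r$mean * r$pairs + c$mean * c$pairs) / (r$pairs + c$pairs)
  list(nodf_total = total, nodf_rows = r$mean, nodf_cols = c$mean,
       per_node_contribution = c(r$contrib, c$contrib))
}

#' Summaries of driver generality and idiosyncrasy
#'
#' Identifies idiosyncratic drivers (degree 1, unique to a single regime
#' shift) and the half-coverage set: the smallest prefix of drivers, sorted
#' by decreasing degree with ties broken alphabetically, whose summed degree
#' strictly exceeds half of all links. Percentages use integer truncation,
#' matching the "~%" convention of narrative summaries (e.g. 14 of 57 -> 24).
#'
#' @inheritParams project_one_mode
#' @return list with `n_drivers`, `n_shifts`, `n_links`,
#'   `idiosyncratic` (names), `idiosyncratic_pct`, `half_coverage` (names),
#'   `half_coverage_pct`, `driver_degree` (named, sorted decreasing),
#'   `shift_degree` (named), `shift_degree_range` with argmin/argmax.
#' @export
driver_summary <- function(network) {
  m <- as_incidence(network)
  dd <- colSums(m)
  sd_ <- rowSums(m)
  n_links <- sum(m)
  ord <- order(-dd, colnames(m))
  dd_sorted <- dd[ord]
  cum <- cumsum(dd_sorted)
  k <- which(cum > n_links / 2)[1]
  idio <- names(dd)[dd == 1]
  list(n_drivers = ncol(m), n_shifts = nrow(m), n_links = n_links,
       idiosyncratic = sort(idio),
       idiosyncratic_pct = as.integer(length(idio) / ncol(m) * 100),
       half_coverage = names(dd_sorted)[seq_len(k)],
       half_coverage_pct = as.integer(k / ncol(m) * 100),
       driver_degree = dd_sorted,
       shift_degree = sd_,
       shift_degree_range = list(
         min = min(sd_), min_shift = names(which.min(sd_)),
         max = max(sd_), max_shift = names(which.max(sd_))))
}

#' Node pairs sharing at least a threshold number of neighbours
#'
#' E.g. the driver pairs jointly causing 10 or more regime shifts, or the
#' regime shift pairs with 8 drivers in common.
#'
#' @inheritParams project_one_mode
#' @param threshold minimum shared-neighbour count (>= 1).
#' @return data frame with columns `node1`, `node2`, `shared`, sorted by
#'   decreasing count then lexically.
#' @export
shared_driver_pairs <- function(network, side = c("driver", "shift"),
                                threshold = 1L) {
  side <- match.arg(side)
  stopifnot(threshold >= 1)
  proj <- project_one_mode(network, side)
  w <- proj$weights
  idx <- which(upper.tri(w) & w >= threshold, arr.ind = TRUE)
  out <- data.frame(node1 = rownames(w)[idx[, 1]],
                    node2 = colnames(w)[idx[, 2]],
                    shared = w[idx], stringsAsFactors = FALSE)
  # symmetric pairs: report in lexical order within the pair
  swap <- out$node1 > out$node2
  tmp <- out$node1[swap]; out$node1[swap] <- out$node2[swap]
  out$node2[swap] <- tmp
  out[order(-out$shared, out$node1, out$node2), , drop = FALSE]
}

#' All headline statistics of a bipartite network
#'
#' Convenience wrapper computing the statistics compared against null models:
#' projection mean degrees, co-occurrence indices, bipartite clustering
#' coefficient, and NODF.
#'
#' @inheritParams project_one_mode
#' @return named list of statistics (see [compare_to_null] for how they are
#'   used against a null ensemble).
#' @export
network_summary <- function(network) {
  m <- as_incidence(network)
  cooc_d <- co_occurrence_index(m, "driver")
  cooc_s <- co_occurrence_index(m, "shift")
  cl <- bipartite_clustering_coefficient(m)
  nodf <- nodf_nestedness(m)
  list(mean_degree_driver = mean_degree(project_one_mode(m, "driver")),
       mean_degree_shift = mean_degree(project_one_mode(m, "shift")),
       cooc_index_driver = cooc_d$index,
       cooc_index_shift = cooc_s$index,
       cooc_per_connected_driver = cooc_d$per_connected_pair,
       cooc_per_connected_shift = cooc_s$per_connected_pair,
       clustering_coefficient = cl$cc,
       nodf_total = nodf$nodf_total)
}
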