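#' Drivers per regime shift by global-change category
#'
#' Multiplies the incidence matrix by the driver-category membership matrix,
#' giving the number of drivers of each regime shift that fall into each
#' detailed (15) or broad (5) global-change category. Because each driver
#' belongs to exactly one detailed category, the counts in each row sum to
#' the shift's degree.
#'
#' @param network a [bipartite_network].
#' @param scheme a category scheme as returned in
#'   [generate_rsdb_like]`()$scheme`: needs `membership` (driver x detailed
#'   0/1 matrix, rows named by driver) and `detailed_to_broad` (named
#'   character vector).
#' @param level `"detailed"` or `"broad"`.
#' @return integer matrix, shifts x categories.
#' @export
category_counts <- function(network, scheme, level = c("detailed", "broad")) {
  level <- match.arg(level)
  m <- as_incidence(network)
  memb <- scheme$membership
  missing <- setdiff(colnames(m), rownames(memb))
  if (length(missing))
    stop("drivers missing from category scheme: ",
         paste(missing, collapse = ", "))
  if (!all(rowSums(memb) == 1))
    stop("category membership rows must each sum to exactly 1")
  memb <- memb[colnames(m), , drop = FALSE]
  counts <- m %*% memb
  if (level == "broad") {
    broad <- scheme$detailed_to_broad[colnames(counts)]
    agg <- matrix(0L, length(broad), length(unique(broad)),
                  dimnames = list(colnames(counts), unique(broad)))
    agg[cbind(seq_along(broad), match(broad, unique(broad)))] <- 1L
    counts <- counts %*% agg
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Proportion of each regime shift's drivers by management scale
#'
#' For each regime shift, the share of its drivers that can be managed at
#' local, regional/national, and international scales; rows sum to one.
#' Rows are ordered by the shifts' ecosystem type (when available in
#' `attrs`) and then by name, the ordering used for managerial-opportunity
#' bar charts.
#'
#' @param network a [bipartite_network].
#' @param attrs attribute data frame with columns `node_name` and
#'   `management_scale` for every driver (rows with `side == "driver"` are
#'   used when a `side` column is present), and optionally `ecosystem_type`
#'   for shifts.
#' @return numeric matrix, shifts x 3 scales, rows summing to 1.
#' @export
management_scale_proportions <- function(network, attrs) {
  m <- as_incidence(network)
  scales <- c("local", "regional_national", "international")
  da <- attrs
  if ("side" %in% names(da)) da <- da[da$side == "driver", , drop = FALSE]
  lab <- stats::setNames(da$management_scale, da$node_name)[colnames(m)]
  bad <- colnames(m)[is.na(lab) | !(lab %in% scales)]
  if (length(bad))
    stop("drivers without a valid management scale: ",
         paste(bad, collapse = ", "))
  ind <- matrix(0L, ncol(m), 3, dimnames = list(colnames(m), scales))
  ind[cbind(seq_len(ncol(m)), match(lab, scales))] <- 1L
  counts <- m %*% ind
  props <- counts / rowSums(counts)
  ord <- order_shifts_by_ecosystem(rownames(props), attrs)
  props[ord, , drop = FALSE]
}

order_shifts_by_ecosystem <- function(shift_names, attrs) {
  eco <- rep(NA_character_, length(shift_names))
  if (!is.null(attrs) && all(c("node_name") %in% names(attrs))) {
    sa <- attrs
    if ("side" %in% names(sa)) sa <- sa[sa$side == "shift", , drop = FALSE]
    ecocol <- intersect(c("ecosystem_type", "ecosystem"), names(sa))
    if (length(ecocol))
      eco <- sa[[ecocol[1]]][match(shift_names, sa$node_name)]
  }
  order(eco, shift_names, na.last = TRUE)
}

#' Global distribution of drivers across management scales
#'
#' Share of all classified drivers per management scale, as exact fractions
#' and truncated integer percentages, plus the combined share manageable at
#' local or regional/national scales (the complement being drivers that can
#' only be managed internationally).
#'
#' @param attrs attribute data frame with `node_name` and `management_scale`
#'   (driver rows used when a `side` column is present).
#' @return list with `n_drivers`, `fraction` (named, sums to 1), `pct`
#'   (named truncated integer percents), `subnational_fraction`,
#'   `subnational_pct` (local + regional/national combined).
#' @export
global_scale_shares <- function(attrs) {
  scales <- c("local", "regional_national", "international")
  da <- attrs
  if ("side" %in% names(da)) da <- da[da$side == "driver", , drop = FALSE]
  lab <- da$management_scale[!is.na(da$management_scale)]
  if (!length(lab)) stop("no classified drivers")
  if (!all(lab %in% scales))
    stop("unknown management scale: ",
         paste(setdiff(lab, scales), collapse = ", "))
  tab <- table(factor(lab, levels = scales))
  frac <- as.numeric(tab) / length(lab)
  names(frac) <- scales
  sub <- frac["local"] + frac["regional_national"]
  list(n_drivers = length(lab), fraction = frac,
       pct = stats::setNames(as.integer(frac * 100), scales),
       subnational_fraction = unname(sub),
       subnational_pct = as.integer(sub * 100))
}

#' Permutation test for attribute homophily on a weighted projection
#'
#' Tests whether co-occurring nodes share an attribute more than expected:
#' the observed statistic is the share of total projection weight that falls
#' on same-label pairs, and the null distribution is obtained by permuting
#' the labels over the nodes. One-sided (greater), with the add-one p-value
#' convention, so p is never zero and is uniform under the null. This is the
#' package's replacement for model-based homophily (node-match) terms.
#'
#' @param projection a [project_one_mode] result.
#' @param labels character vector of node labels, either named by node or in
#'   projection node order. At least two distinct labels are required.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return list of class `homophily_result`: `observed_within_share`,
#'   `permutation_p`, `n_perm`, `null_mean`, `direction`, `label_name`.
#' @export
attribute_homophily_test <- function(projection, labels, n_perm = 999,
                                     seed = NULL) {
  stopifnot(inherits(projection, "one_mode_projection"), n_perm >= 99)
  if (!is.null(seed)) set.seed(seed)
  w <- projection$weights
  if (!is.null(names(labels))) labels <- labels[rownames(w)]
  if (length(labels) != nrow(w) || anyNA(labels))
    stop("labels must cover every projection node")
  if (length(unique(labels)) < 2)
    stop("homophily test needs at least two distinct labels")
  ut <- upper.tri(w)
  total <- sum(w[ut])
  if (total == 0) stop("projection has no co-occurrence weight")
  within_share <- function(lb) {
    same <- outer(lb, lb, "==")
    sum(w[ut & same]) / total
  }
  obs <- within_share(labels)
  perm <- vapply(seq_len(n_perm),
                 function(i) within_share(sample(labels)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  structure(list(label_name = "labels",
                 observed_within_share = obs,
                 null_mean = mean(perm),
                 permutation_p = p, n_perm = n_perm,
                 direction = "greater"),
            class = "homophily_result")
}

#' @export
print.homophily_result <- function(x, ...) {
  cat(sprintf(
    "homophily: within-label weight share %.3f (null mean %.3f), p = %.4g (%d perms, one-sided)\n",
    x$observed_within_share, x$null_mean, x$permutation_p, x$n_perm))
  invisible(x)
}
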