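#' Pairwise binary distances between nodes of one side
#'
#' Distances between regime shifts given the drivers they share (or between
#' drivers given the regime shifts they cause), computed on the binary
#' neighbour sets A and B: Sorensen-Dice `1 - 2|A&B| / (|A| + |B|)` or
#' Jaccard `1 - |A&B| / |A|B|union`. Both reward shared presences rather
#' than shared absences, which suits co-occurrence data.
#'
#' @param network a [bipartite_network].
#' @param side `"shift"` or `"driver"`.
#' @param metric `"sorensen_dice"` or `"jaccard"`.
#' @return a `dist_matrix`: list with `distances` (symmetric matrix in
#'   `[0, 1]`, zero diagonal), `metric_name`, `node_names`.
#' @export
pairwise_distance <- function(network, side = c("shift", "driver"),
                              metric = c("sorensen_dice", "jaccard")) {
  side <- match.arg(side)
  metric <- match.arg(metric)
  m <- as_incidence(network)
  a <- if (side == "shift") m else t(m)
  deg <- rowSums(a)
  if (any(deg == 0))
    stop("nodes with empty neighbour sets: ",
         paste(rownames(a)[deg == 0], collapse = ", "))
  inter <- tcrossprod(a)
  d <- if (metric == "sorensen_dice")
    1 - 2 * inter / outer(deg, deg, "+")
  else
    1 - inter / (outer(deg, deg, "+") - inter)
  diag(d) <- 0
  structure(list(distances = d, metric_name = metric,
                 node_names = rownames(a)),
            class = "dist_matrix")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the
#' size-weighted mean of all cross-pair distances. Tied candidate merges are
#' broken deterministically: each cluster is represented by its
#' lexicographically smallest leaf name, and among tied pairs the lexically
#' smallest (representative, representative) pair merges first. Distance
#' ties are common for binary metrics on small networks, so without a
#' documented rule the tree would depend on input order.
#'
#' @param dist a `dist_matrix` (from [pairwise_distance] or
#'   [categorical_block_distance]) or a plain symmetric matrix/`dist`.
#' @return object of class `upgma_dendrogram`: list with `hclust` (a
#'   [stats::hclust]-compatible tree usable with [stats::cophenetic] and
#'   [ape::as.phylo]), `merge_heights`, and `leaf_names`.
#' @export
upgma_cluster <- function(dist) {
  d <- as_dist_matrix(dist)
  if (anyNA(d)) stop("distance matrix contains NA")
  n <- nrow(d)
  if (n < 2) stop("need at least two nodes to cluster")
  labels <- rownames(d)
  # clusters indexed 1..(2n-1); leaves first, merges appended
  size <- c(rep(1L, n), integer(n - 1))
  rep_name <- c(labels, character(n - 1))
  code <- c(-seq_len(n), seq_len(n - 1))  # hclust merge codes
  D <- matrix(Inf, 2 * n - 1, 2 * n - 1)
  D[seq_len(n), seq_len(n)] <- d
  diag(D) <- Inf
  active <- c(rep(TRUE, n), rep(FALSE, n - 1))
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    act <- which(active)
    sub <- D[act, act, drop = FALSE]
    h <- min(sub)
    ties <- which(sub == h, arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    pair_rep <- apply(ties, 1, function(ij) {
      r <- sort(c(rep_name[act[ij[1]]], rep_name[act[ij[2]]]))
      paste(r, collapse = "\r")
    })
    best <- ties[order(pair_rep)[1], ]
    i <- act[best[1]]; j <- act[best[2]]
    new <- n + k
    merge[k, ] <- sort(c(code[i], code[j]))
    height[k] <- h
    size[new] <- size[i] + size[j]
    rep_name[new] <- min(rep_name[i], rep_name[j])
    for (o in act) if (o != i && o != j)
      D[new, o] <- D[o, new] <-
        (size[i] * D[i, o] + size[j] * D[j, o]) / size[new]
    active[c(i, j)] <- FALSE
    active[new] <- TRUE
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_leaf_order(merge),
                       labels = labels, method = "average",
                       call = match.call(),
                       dist.method = attr(dist, "metric_name")),
                  class = "hclust")
  structure(list(hclust = hc, merge_heights = height,
                 leaf_names = labels),
            class = "upgma_dendrogram")
}

# left-to-right leaf order by traversing the merge matrix
hclust_leaf_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

as_dist_matrix <- function(x) {
  if (inherits(x, "dist_matrix")) return(x$distances)
  if (inherits(x, "dist")) return(as.matrix(x))
  if (is.matrix(x)) {
    if (is.null(rownames(x)))
      dimnames(x) <- list(paste0("n", seq_len(nrow(x))),
                          paste0("n", seq_len(nrow(x))))
    return(x)
  }
  stop("expected a dist_matrix, dist, or matrix")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram on %d leaves, merge heights %.3g .. %.3g\n",
              length(x$leaf_names), min(x$merge_heights),
              max(x$merge_heights)))
  invisible(x)
}

#' Serialize a dendrogram to newick
#'
#' @param dendrogram a [upgma_cluster] result.
#' @param path optional file to write to.
#' @return the newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  phy <- ape::as.phylo(dendrogram$hclust)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Classical (metric) multidimensional scaling
#'
#' Principal-coordinates embedding: squared distances are double-centred and
#' eigendecomposed; the top axes with nonnegative eigenvalues are kept,
#' ordered by decreasing eigenvalue, with coordinates centred at zero.
#' Negative eigenvalues (non-Euclidean residue of the distance) are reported
#' but never used.
#'
#' @param dist a `dist_matrix`, `dist`, or symmetric matrix.
#' @param k number of axes requested; silently truncated (with a warning) to
#'   the number of positive eigenvalues.
#' @return object of class `ordination`: `coordinates` (node x axis),
#'   `eigenvalues` (all of them, decreasing), `proportion_explained` (over
#'   positive eigenvalues).
#' @export
classical_mds <- function(dist, k = 2) {
  d <- as_dist_matrix(dist)
  stopifnot(k >= 1)
  n <- nrow(d)
  res <- stats::cmdscale(stats::as.dist(d), k = min(k, n - 1), eig = TRUE)
  eig <- res$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > n_pos) {
    warning(sprintf("only %d positive-eigenvalue axes available; truncating",
                    n_pos))
    k <- n_pos
  }
  coords <- res$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained =
                   pmax(eig, 0)[seq_len(k)] / sum(pmax(eig, 0))),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("ordination: %d nodes, %d axes (%.1f%% of positive inertia)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$proportion_explained)))
  invisible(x)
}

#' Fit explanatory variables onto an ordination (vector fitting)
#'
#' For each variable, the centred and scaled values are regressed on the
#' ordination coordinates; the squared multiple correlation measures how
#' much of the variable's variation the ordination captures, the normalized
#' coefficient vector gives the direction of increase, and significance is
#' assessed by permuting the variable's values (add-one convention,
#' one-sided on r-squared). Binary variables are treated as numeric 0/1.
#'
#' @param ord an [classical_mds] result.
#' @param variables data frame or matrix of numeric/binary variables, rows
#'   aligned with (or named by) the ordination nodes.
#' @param n_perm permutations per variable (>= 99).
#' @param seed optional integer seed.
#' @param alpha threshold used for the `significant` flag (default 0.05).
#' @return data frame with one row per non-constant variable: `variable`,
#'   `r_squared`, one `dir_*` column per axis (unit vector), `permutation_p`,
#'   `significant`. Constant variables are skipped with a message.
#' @export
fit_variables <- function(ord, variables, n_perm = 999, seed = NULL,
                          alpha = 0.05) {
  stopifnot(inherits(ord, "ordination"), n_perm >= 99)
  if (!is.null(seed)) set.seed(seed)
  x <- ord$coordinates
  v <- as.data.frame(variables)
  if (!is.null(rownames(v)) && all(rownames(x) %in% rownames(v)))
    v <- v[rownames(x), , drop = FALSE]
  if (nrow(v) != nrow(x))
    stop("variables not aligned with ordination nodes")
  xc <- scale(x, center = TRUE, scale = FALSE)
  fit_one <- function(y) {
    yc <- y - mean(y)
    b <- solve(crossprod(xc), crossprod(xc, yc))
    r2 <- drop(crossprod(xc %*% b)) / drop(crossprod(yc))
    list(r2 = r2, dir = drop(b) / sqrt(sum(b^2)))
  }
  rows <- list()
  for (nm in names(v)) {
    y <- as.numeric(v[[nm]])
    if (anyNA(y) || stats::sd(y) == 0) {
      message("skipping constant or incomplete variable: ", nm)
      next
    }
    obs <- fit_one(y)
    perm_r2 <- vapply(seq_len(n_perm),
                      function(i) fit_one(sample(y))$r2, numeric(1))
    p <- (1 + sum(perm_r2 >= obs$r2)) / (n_perm + 1)
    row <- data.frame(variable = nm, r_squared = obs$r2,
                      permutation_p = p, significant = p < alpha,
                      stringsAsFactors = FALSE)
    for (a in seq_along(obs$dir))
      row[[paste0("dir_", colnames(x)[a])]] <- obs$dir[a]
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sorensen-Dice distances over blocks of binary categorical variables
#'
#' The categorical variables describing the regime shifts come in thematic
#' blocks (ecosystem processes, provisioning/regulating/cultural services,
#' drivers, land use, scales, reversibility). For each block, all-zero
#' columns are removed and the Sorensen-Dice distance is computed between
#' the shifts' binary profiles.
#'
#' @param attrs attribute data frame with `node_name` (shift rows used when
#'   a `side` column is present) and the binary variable columns.
#' @param blocks named list mapping block name to a character vector of
#'   column names in `attrs`.
#' @return named list of `dist_matrix` objects, one per block.
#' @export
categorical_block_distance <- function(attrs, blocks) {
  sa <- attrs
  if ("side" %in% names(sa)) sa <- sa[sa$side == "shift", , drop = FALSE]
  out <- list()
  for (b in names(blocks)) {
    cols <- blocks[[b]]
    missing <- setdiff(cols, names(sa))
    if (length(missing))
      stop("block ", b, " references unknown variables: ",
           paste(missing, collapse = ", "))
    prof <- as.matrix(sa[, cols, drop = FALSE])
    rownames(prof) <- sa$node_name
    if (!all(prof %in% c(0, 1)))
      stop("block ", b, " contains non-binary values")
    prof <- prof[, colSums(prof) > 0, drop = FALSE]
    if (ncol(prof) == 0)
      stop("block ", b, " has no informative (non-zero) variables")
    deg <- rowSums(prof)
    if (any(deg == 0))
      stop("block ", b, " has all-zero profiles after cleaning: ",
           paste(rownames(prof)[deg == 0], collapse = ", "))
    inter <- tcrossprod(prof)
    d <- 1 - 2 * inter / outer(deg, deg, "+")
    diag(d) <- 0
    out[[b]] <- structure(list(distances = d, metric_name = "sorensen_dice",
                               node_names = rownames(prof)),
                          class = "dist_matrix")
  }
  out
}
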