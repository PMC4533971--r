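# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use naive enumeration (set
# intersections, explicit subgraph loops, pairwise recursion) so they share
# no code path with the package implementations they check.

random_network <- function(nr, nc, p = 0.4, seed = NULL,
                           nonempty = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(as.integer(runif(nr * nc) < p), nr, nc)
    if (!nonempty || (all(rowSums(m) > 0) && all(colSums(m) > 0))) break
  }
  dimnames(m) <- list(sprintf("s%02d", seq_len(nr)),
                      sprintf("d%02d", seq_len(nc)))
  m
}

# shared-neighbour weight by explicit set intersection
oracle_projection <- function(m, side) {
  a <- if (side == "driver") t(m) else m
  n <- nrow(a)
  w <- matrix(0L, n, n, dimnames = list(rownames(a), rownames(a)))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    w[i, j] <- length(intersect(which(a[i, ] == 1), which(a[j, ] == 1)))
  w
}

# open triangles by enumerating neighbour pairs of each opposite-side node
oracle_open_triangles <- function(m, side) {
  a <- if (side == "driver") m else t(m)  # rows = opposite side
  total <- 0L
  for (i in seq_len(nrow(a))) {
    nb <- which(a[i, ] == 1)
    if (length(nb) >= 2) total <- total + nrow(t(combn(nb, 2)))
  }
  total
}

# squares and 3-link paths by explicit subgraph enumeration
oracle_squares_paths <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  squares <- 0L
  if (nr >= 2 && nc >= 2) {
    for (r in combn(seq_len(nr), 2, simplify = FALSE))
      for (cc in combn(seq_len(nc), 2, simplify = FALSE))
        if (m[r[1], cc[1]] & m[r[1], cc[2]] & m[r[2], cc[1]] & m[r[2], cc[2]])
          squares <- squares + 1L
  }
  paths <- 0L
  # middle edge (u, a); x a column neighbour of u, y a row neighbour of a
  for (u in seq_len(nr)) for (a in seq_len(nc)) if (m[u, a] == 1)
    for (x in seq_len(nc)) if (x != a && m[u, x] == 1)
      for (y in seq_len(nr)) if (y != u && m[y, a] == 1)
        paths <- paths + 1L
  list(squares = squares, three_paths = paths)
}

# NODF by explicit double loop over ordered pairs
oracle_nodf <- function(m) {
  pair_terms <- function(a) {
    n <- nrow(a)
    if (n < 2) return(numeric(0))
    deg <- rowSums(a)
    out <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (deg[i] == deg[j] || min(deg[i], deg[j]) == 0) {
        out <- c(out, 0)
      } else {
        shared <- sum(a[i, ] == 1 & a[j, ] == 1)
        out <- c(out, 100 * shared / min(deg[i], deg[j]))
      }
    }
    out
  }
  r <- pair_terms(m); cc <- pair_terms(t(m))
  list(rows = if (length(r)) mean(r) else 0,
       cols = if (length(cc)) mean(cc) else 0,
       total = mean(c(r, cc)))
}

# naive UPGMA returning the cophenetic matrix; same documented lexical
# tie rule as the implementation (smallest leaf name represents a cluster),
# realized independently
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  dd <- matrix(NA_real_, n + (n - 1), n + (n - 1))
  dd[seq_len(n), seq_len(n)] <- d
  coph <- matrix(0, n, n)
  nxt <- n + 1
  leaf_names <- rownames(d)
  cluster_rep <- function(i) min(leaf_names[members[[i]]])
  repeat {
    act <- which(active[seq_len(nxt - 1)])
    if (length(act) < 2) break
    best <- c(Inf, NA, NA)
    best_key <- NULL
    for (i in act) for (j in act) if (i < j && dd[i, j] <= best[1]) {
      key <- paste(sort(c(cluster_rep(i), cluster_rep(j))),
                   collapse = "\r")
      if (dd[i, j] < best[1] || (dd[i, j] == best[1] && key < best_key)) {
        best <- c(dd[i, j], i, j)
        best_key <- key
      }
    }
    i <- best[2]; j <- best[3]; h <- best[1]
    mi <- members[[i]]; mj <- members[[j]]
    for (x in mi) for (y in mj) { coph[x, y] <- h; coph[y, x] <- h }
    members[[nxt]] <- c(mi, mj)
    for (k in act) if (k != i && k != j) {
      ni <- length(mi); nj <- length(mj)
      dd[nxt, k] <- dd[k, nxt] <- (ni * dd[min(i, k), max(i, k)] +
                                   nj * dd[min(j, k), max(j, k)]) / (ni + nj)
    }
    active[c(i, j)] <- FALSE
    active[nxt] <- TRUE
    nxt <- nxt + 1
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# all 0/1 matrices with the given margins, keyed by their cell string
enumerate_margin_class <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  out <- list()
  recurse <- function(i, m, cols_left) {
    if (i > nr) {
      if (all(cols_left == 0)) out[[length(out) + 1]] <<- m
      return(invisible(NULL))
    }
    for (pick in combn(seq_len(nc), row_sums[i], simplify = FALSE)) {
      if (all(cols_left[pick] >= 1)) {
        m2 <- m; m2[i, pick] <- 1L
        cl <- cols_left; cl[pick] <- cl[pick] - 1L
        recurse(i + 1, m2, cl)
      }
    }
  }
  recurse(1, matrix(0L, nr, nc), as.integer(col_sums))
  out
}

matrix_key <- function(m) paste(m, collapse = "")

# small labelled network from an explicit edge list
toy_network <- function(edges) {
  df <- data.frame(shift = vapply(edges, `[`, "", 1),
                   driver = vapply(edges, `[`, "", 2),
                   stringsAsFactors = FALSE)
  edge_file <- tempfile(fileext = ".csv")
  write.csv(df, edge_file, row.names = FALSE, quote = FALSE)
  on.exit(unlink(edge_file))
  read_bipartite_edge_list(edge_file)
}
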