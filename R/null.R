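#' Gale-Ryser feasibility of a bipartite degree sequence
#'
#' Checks whether any 0/1 matrix exists with the given row and column sums.
#'
#' @param row_sums,col_sums nonnegative integer vectors.
#' @return `TRUE` or `FALSE`.
#' @export
feasible_margins <- function(row_sums, col_sums) {
  if (any(row_sums < 0) || any(col_sums < 0)) return(FALSE)
  if (sum(row_sums) != sum(col_sums)) return(FALSE)
  if (any(row_sums > length(col_sums)) || any(col_sums > length(row_sums)))
    return(FALSE)
  r <- sort(row_sums, decreasing = TRUE)
  lhs <- cumsum(r)
  rhs <- vapply(seq_along(r),
                function(k) sum(pmin(col_sums, k)), numeric(1))
  all(lhs <= rhs)
}

#' Sample a binary matrix with the observed margins
#'
#' Draws a 0/1 matrix with exactly the row and column sums of the observed
#' network: the null hypothesis that links are reshuffled while each node
#' keeps its number of links. Two samplers are provided. `"curveball"`
#' (default) restarts from the observed matrix and applies random trade
#' steps, an MCMC scheme whose stationary distribution is uniform over the
#' margin class. `"sis"` builds the matrix column by column (sequential
#' importance sampling) and attaches a log importance weight
#' (`attr(, "log_weight")`, the negative log proposal density); unweighted
#' summaries over SIS samples are approximate unless reweighted.
#'
#' @param network a [bipartite_network] or incidence matrix.
#' @param method `"curveball"` or `"sis"`.
#' @param n_trades number of curveball trade steps; default
#'   `5 * min(dim)` trades per sample.
#' @return a [bipartite_network] with identical margins; for `"sis"` the
#'   incidence carries a `log_weight` attribute.
#' @export
sample_fixed_margins <- function(network, method = c("curveball", "sis"),
                                 n_trades = NULL) {
  method <- match.arg(method)
  m <- as_incidence(network)
  if (sum(m) == 0) stop("cannot randomize an empty network")
  if (method == "curveball") {
    if (is.null(n_trades)) n_trades <- 5L * min(dim(m))
    out <- curveball_trades(m, as.integer(n_trades))
    dimnames(out) <- dimnames(m)
    lw <- 0
  } else {
    res <- sis_sample(rowSums(m), colSums(m))
    out <- res$matrix
    dimnames(out) <- dimnames(m)
    lw <- res$log_weight
  }
  net <- bipartite_network(out, report_empty = FALSE)
  attr(net, "log_weight") <- lw
  net
}

# Sequential importance sampler for 0/1 matrices with fixed margins.
# Columns are filled in decreasing-column-sum order; within a column, rows
# are visited in decreasing residual order and receive a 1 with a drafting
# probability proportional to residual row demand, restricted to choices
# that keep the remaining problem Gale-Ryser feasible (greedy realizability:
# placing remaining 1s on the largest residual rows is feasibility-optimal).
# Every matrix in the margin class has positive support; the log importance
# weight is minus the log of the (unique) decision-path probability.
sis_sample <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  if (!feasible_margins(row_sums, col_sums))
    stop("infeasible margins (Gale-Ryser violation)")
  col_order <- order(-col_sums, seq_len(nc))
  a <- matrix(0L, nr, nc)
  r <- as.integer(row_sums)
  logq <- 0
  rest_feasible <- function(r_resid, cols_left) {
    feasible_margins(r_resid, cols_left)
  }
  for (jj in seq_len(nc)) {
    j <- col_order[jj]
    k <- as.integer(col_sums[j])
    cols_left <- col_sums[col_order[-seq_len(jj)]]
    if (k == 0) next
    # feasibility of completing this column given a partial assignment:
    # place the remaining k 1s greedily on the largest residual rows
    col_ok <- function(r_now, avail, k_now) {
      if (k_now == 0) return(rest_feasible(r_now, cols_left))
      av <- avail[r_now[avail] > 0]
      if (length(av) < k_now) return(FALSE)
      top <- av[order(-r_now[av])][seq_len(k_now)]
      r2 <- r_now
      r2[top] <- r2[top] - 1L
      rest_feasible(r2, cols_left)
    }
    row_order <- order(-r, seq_len(nr))
    avail <- row_order
    for (pos in seq_along(row_order)) {
      if (k == 0) break
      i <- row_order[pos]
      rest <- avail[avail != i]
      can_take <- r[i] > 0 && {
        r2 <- r; r2[i] <- r2[i] - 1L
        col_ok(r2, rest, k - 1L)
      }
      can_skip <- col_ok(r, rest, k)
      if (!can_take && !can_skip)
        stop("internal error: sis sampler reached an infeasible state")
      if (can_take && can_skip) {
        p <- k * r[i] / sum(r[avail])
        p <- min(max(p, 1e-12), 1 - 1e-12)
        take <- runif(1) < p
        logq <- logq + log(if (take) p else 1 - p)
      } else take <- can_take
      if (take) {
        a[i, j] <- 1L
        r[i] <- r[i] - 1L
        k <- k - 1L
      }
      avail <- rest
    }
  }
  stopifnot(all(rowSums(a) == row_sums), all(colSums(a) == col_sums))
  list(matrix = a, log_weight = -logq)
}

#' Null ensemble of network statistics under fixed margins
#'
#' Draws `n_samples` degree-preserving randomizations of the network and
#' computes the headline statistics of [network_summary] on each: the
#' Monte-Carlo reference distribution against which the observed network is
#' judged.
#'
#' @inheritParams sample_fixed_margins
#' @param n_samples number of null networks (>= 2). Study-scale analyses use
#'   10000; tests use a few hundred.
#' @return object of class `null_ensemble`: list with `statistics` (data
#'   frame, one row per sample), `method`, `n_trades`, `n_samples`,
#'   `log_weights`.
#' @export
build_null_ensemble <- function(network, n_samples = 10000,
                                method = c("curveball", "sis"),
                                n_trades = NULL) {
  method <- match.arg(method)
  stopifnot(n_samples >= 2)
  m <- as_incidence(network)
  rs <- rowSums(m); cs <- colSums(m)
  stats_list <- vector("list", n_samples)
  lw <- numeric(n_samples)
  for (b in seq_len(n_samples)) {
    samp <- sample_fixed_margins(m, method = method, n_trades = n_trades)
    sm <- as.matrix(samp)
    if (any(rowSums(sm) != rs) || any(colSums(sm) != cs))
      stop("sampler violated the margin contract")
    lw[b] <- attr(samp, "log_weight")
    stats_list[[b]] <- as.data.frame(network_summary(sm))
  }
  structure(list(statistics = do.call(rbind, stats_list),
                 method = method,
                 n_trades = if (is.null(n_trades)) 5L * min(dim(m)) else n_trades,
                 n_samples = n_samples, log_weights = lw),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d fixed-margin samples (%s)\n",
              x$n_samples, x$method))
  print(summary(x$statistics))
  invisible(x)
}

#' Compare observed statistics to a null ensemble
#'
#' For each statistic: standardized effect size
#' `ses_z = (observed - null mean) / null sd`, an empirical p-value with the
#' add-one convention `(1 + #{samples at least as extreme}) / (n + 1)`
#' (never exactly zero), and the p-value of a one-sample t-test of the null
#' sample against the observed value.
#'
#' @param observed a [network_summary] result (or any named list of numbers
#'   whose names appear in the ensemble table).
#' @param ensemble a [build_null_ensemble] result.
#' @param statistics which statistics to compare; defaults to all columns
#'   shared between `observed` and the ensemble.
#' @param alternative `"auto"` (tail chosen by the sign of observed minus
#'   null mean, as reported in `direction`), `"greater"`, or `"less"`. Fixed
#'   tails make the empirical p exactly uniform under the null; the folded
#'   auto tail does not.
#' @return data frame with one row per statistic: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `ses_z`, `empirical_p`, `t_p`, `direction`.
#'   `ses_z` is `NA` when the null sd is 0.
#' @export
compare_to_null <- function(observed, ensemble, statistics = NULL,
                            alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- ensemble$statistics
  if (is.null(statistics))
    statistics <- intersect(names(observed), names(tab))
  rows <- lapply(statistics, function(s) {
    x <- tab[[s]]
    x <- x[is.finite(x)]
    obs <- observed[[s]]
    mu <- mean(x); sdv <- stats::sd(x)
    dir <- switch(alternative,
                  auto = if (obs >= mu) "greater" else "less",
                  alternative)
    n_extreme <- if (dir == "greater") sum(x >= obs) else sum(x <= obs)
    p_emp <- (1 + n_extreme) / (length(x) + 1)
    t_p <- if (sdv > 0) stats::t.test(x, mu = obs)$p.value else NA_real_
    data.frame(statistic = s, observed = obs, null_mean = mu, null_sd = sdv,
               ses_z = if (sdv > 0) (obs - mu) / sdv else NA_real_,
               empirical_p = p_emp, t_p = t_p, direction = dir,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
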