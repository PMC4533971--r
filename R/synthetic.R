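#' Configuration of the synthetic network generator
#'
#' Defaults emulate the scale of the regime shifts database analysed by the
#' package: 25 generic regime shift types, 57 drivers, a mean of 11.2
#' drivers per shift, 14 idiosyncratic (degree-1) drivers, a strongly nested
#' incidence structure, and management-scale homophily among co-occurring
#' drivers.
#'
#' @param n_shifts,n_drivers node counts per side.
#' @param target_mean_shift_degree expected number of drivers per shift.
#' @param nestedness_strength nonnegative; 0 plants no degree order, larger
#'   values concentrate links of specialist nodes onto generalist partners
#'   (see [generate_nested_bipartite]).
#' @param homophily_strength probability in `[0, 1]` that a driver copies a
#'   management-scale label from a co-occurring driver rather than drawing
#'   uniformly.
#' @param n_idiosyncratic exact number of degree-1 driver columns to plant.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_shifts = 25, n_drivers = 57,
                             target_mean_shift_degree = 11.2,
                             nestedness_strength = 5,
                             homophily_strength = 0.8,
                             n_idiosyncratic = 14, seed = NULL) {
  stopifnot(n_shifts >= 2, n_drivers >= 2,
            n_idiosyncratic >= 0, n_idiosyncratic <= n_drivers,
            nestedness_strength >= 0,
            homophily_strength >= 0, homophily_strength <= 1,
            target_mean_shift_degree > 0,
            target_mean_shift_degree <= n_drivers)
  structure(list(n_shifts = n_shifts, n_drivers = n_drivers,
                 target_mean_shift_degree = target_mean_shift_degree,
                 nestedness_strength = nestedness_strength,
                 homophily_strength = homophily_strength,
                 n_idiosyncratic = n_idiosyncratic, seed = seed),
            class = "synthetic_config")
}

# Link-probability surface: logistic in the scaled rank product. The
# intercept is calibrated by root finding so the expected mean shift degree
# hits the target for any nestedness strength.
nested_link_probs <- function(n_shifts, n_drivers, target, strength) {
  u <- (seq_len(n_shifts) - 0.5) / n_shifts
  v <- (seq_len(n_drivers) - 0.5) / n_drivers
  uv <- outer(u, v)
  f <- function(a) mean(stats::plogis(a - strength * uv)) * n_drivers - target
  a <- stats::uniroot(f, c(-60, 60), tol = 1e-10)$root
  stats::plogis(a - strength * uv)
}

# Number of shift/driver groups behind the planted co-occurrence structure;
# mirrors the three broad system classes of the emulated database.
N_GROUPS <- 3L

#' Generate a bipartite network with planted nestedness
#'
#' Shift degrees are drawn from a link-probability surface logistic in the
#' product of the (scaled) row and column rank indices -- early-rank rows
#' and columns are generalists, late ranks specialists -- with the intercept
#' calibrated so the expected mean shift degree matches the target for any
#' nestedness strength. Link selection then plants the co-occurrence
#' structure of the emulated database: shifts and drivers are divided
#' round-robin into three groups, and each shift draws its links without
#' replacement with weights `(surface * affinity)^sharpness`, where the
#' affinity multiplier `1 + 1.4 * strength` favours drivers of the shift's
#' own group and the sharpness exponent `1 + 0.4 * strength` concentrates
#' choices on the heaviest weights. The result is a shared core of
#' generalist drivers plus group-specific nested driver pools: specialist
#' link sets sit inside generalist ones (nestedness beyond the margins)
#' while shifts of a group share driver sets (elevated four-cycle clustering
#' and co-occurrence concentrated onto fewer driver pairs, the signature a
#' purely independent-cell surface cannot produce relative to
#' degree-preserving nulls). At strength 0 both knobs are inactive and the
#' procedure reduces to independent uniform filling with no planted order.
#' Empty rows/columns are repaired, exactly `n_idiosyncratic` driver columns
#' are pruned to degree 1 (keeping one of their existing links), every other
#' column is kept at degree >= 2, and links are topped up (outside
#' idiosyncratic columns) towards the target count.
#'
#' @param config a [synthetic_config]. When `config$seed` is non-`NULL` the
#'   RNG is seeded, making the draw reproducible.
#' @return a [bipartite_network] with shifts `rs01, rs02, ...` and drivers
#'   `dr01, dr02, ...`.
#' @export
generate_nested_bipartite <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_shifts; nd <- config$n_drivers
  s <- config$nestedness_strength
  p <- nested_link_probs(ns, nd, config$target_mean_shift_degree, s)
  gr_row <- (seq_len(ns) - 1L) %% N_GROUPS
  gr_col <- (seq_len(nd) - 1L) %% N_GROUPS
  affinity <- 1 + 1.4 * s * outer(gr_row, gr_col, "==")
  w <- (p * affinity)^(1 + 0.4 * s)
  a <- matrix(0L, ns, nd,
              dimnames = list(sprintf("rs%02d", seq_len(ns)),
                              sprintf("dr%02d", seq_len(nd))))
  for (i in seq_len(ns)) {
    d_i <- max(1L, sum(runif(nd) < p[i, ]))
    a[i, sample(nd, d_i, prob = w[i, ])] <- 1L
  }
  # repair empty columns, weighted by the same selection surface
  for (j in which(colSums(a) == 0))
    a[sample.int(ns, 1, prob = w[, j]), j] <- 1L
  # plant idiosyncratic drivers: prune the lowest-degree columns to degree 1,
  # keeping one of their existing links so alignment is preserved
  n_idio <- config$n_idiosyncratic
  idio <- integer(0)
  if (n_idio > 0) {
    deg <- colSums(a)
    idio <- order(deg, runif(nd))[seq_len(n_idio)]
    for (j in idio) {
      links <- which(a[, j] == 1L)
      if (length(links) > 1) {
        keep <- links[sample.int(length(links), 1)]
        a[setdiff(links, keep), j] <- 0L
      }
    }
    # rows emptied by pruning get a link in a non-idiosyncratic column
    open <- setdiff(seq_len(nd), idio)
    for (i in which(rowSums(a) == 0))
      a[i, open[sample.int(length(open), 1, prob = w[i, open])]] <- 1L
    # remaining columns must not be accidentally idiosyncratic
    for (j in setdiff(which(colSums(a) == 1L), idio)) {
      zero <- which(a[, j] == 0L)
      a[zero[sample.int(length(zero), 1, prob = w[zero, j])], j] <- 1L
    }
  }
  # top up towards the target link count (never into idiosyncratic columns)
  target_links <- round(config$target_mean_shift_degree * ns)
  deficit <- target_links - sum(a)
  if (deficit > 0) {
    open_cols <- setdiff(seq_len(nd), idio)
    cells <- which(a[, open_cols, drop = FALSE] == 0L)
    if (length(cells)) {
      pw <- w[, open_cols, drop = FALSE][cells]
      add <- sample(cells, min(deficit, length(cells)), prob = pw)
      a[, open_cols][add] <- 1L
    }
  }
  bipartite_network(a, report_empty = FALSE)
}

#' Assign management-scale labels with planted homophily
#'
#' Labels drivers with the three management scales (`local`,
#' `regional_national`, `international`) such that co-occurring drivers tend
#' to share a scale. The planting is two-level. First a latent scale field
#' is laid over the regime shifts: working breadth-first through the shift
#' projection, each shift with probability `homophily_strength^4` copies the
#' latent scale of an already-labelled neighbouring shift sampled
#' proportionally to shared-driver weight, and otherwise draws the currently
#' least-used scale (a balancing innovation, independent of the network, so
#' the strength-0 null stays exchangeable). Each driver then, with
#' probability `homophily_strength`, adopts the majority latent scale among
#' the regime shifts it belongs to (ties sampled), and otherwise draws
#' uniformly. At strength 0 driver labels are iid uniform; at strength 1
#' there are no innovations, the latent field is constant within each
#' connected component, and every driver-projection component is label-pure.
#' Intermediate strengths produce balanced labels whose agreement
#' concentrates on strongly co-occurring driver pairs, which is what a
#' weighted within-label permutation test detects.
#'
#' @param network a [bipartite_network].
#' @param config a [synthetic_config]; uses `homophily_strength`, and seeds
#'   the RNG from `config$seed + 1` when the seed is non-`NULL`.
#' @return data frame (`node_name`, `side`, `management_scale`), one row per
#'   driver.
#' @export
plant_attribute_homophily <- function(network, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  m <- as_incidence(network)
  scales <- c("local", "regional_national", "international")
  h <- config$homophily_strength
  ws <- tcrossprod(m)
  diag(ws) <- 0
  ns <- nrow(m)
  h_latent <- h^4
  latent <- rep(NA_character_, ns)
  visited <- rep(FALSE, ns)
  balanced_draw <- function() {
    cnt <- table(factor(latent, levels = scales))
    lo <- names(cnt)[cnt == min(cnt)]
    if (length(lo) > 1) sample(lo, 1) else lo
  }
  for (start in sample.int(ns)) {
    if (visited[start]) next
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      node <- queue[1]; queue <- queue[-1]
      nb <- which(ws[node, ] > 0)
      labelled <- nb[!is.na(latent[nb])]
      if (length(labelled) && runif(1) < h_latent) {
        pick <- if (length(labelled) == 1) labelled else
          sample(labelled, 1, prob = ws[node, labelled])
        latent[node] <- latent[pick]
      } else {
        latent[node] <- balanced_draw()
      }
      new_nb <- nb[!visited[nb]]
      visited[new_nb] <- TRUE
      queue <- c(queue, new_nb)
    }
  }
  labels <- vapply(seq_len(ncol(m)), function(j) {
    if (runif(1) < h) {
      tb <- table(latent[m[, j] == 1L])
      top <- names(tb)[tb == max(tb)]
      if (length(top) > 1) sample(top, 1) else top
    } else {
      sample(scales, 1)
    }
  }, character(1))
  data.frame(node_name = colnames(m), side = "driver",
             management_scale = labels, stringsAsFactors = FALSE)
}

#' Generate a full synthetic dataset at regime-shifts-database scale
#'
#' One call producing everything the analysis pipeline consumes: a nested
#' 25 x 57 bipartite network with mean shift degree about 11.2 and exactly 14
#' idiosyncratic drivers; driver attributes (management scale with planted
#' homophily, directedness, one of 15 mutually exclusive detailed categories
#' mapped onto 5 broad ones); shift attributes (ecosystem type plus the
#' binary categorical-variable blocks used for block distances and vector
#' fitting); and the category scheme.
#'
#' @param seed integer seed.
#' @param config optional [synthetic_config] overriding the defaults.
#' @return list with `network` ([bipartite_network]), `attributes` (data
#'   frame over drivers and shifts, `side` column distinguishes them),
#'   `scheme` (list: `detailed_names`, `broad_names`, `detailed_to_broad`,
#'   `membership`), and `blocks` (named list of shift attribute column names
#'   per categorical block).
#' @export
generate_rsdb_like <- function(seed, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  config$seed <- NULL
  set.seed(seed)
  net <- generate_nested_bipartite(config)
  drivers <- driver_names(net)
  shifts <- shift_names(net)
  scale_attr <- plant_attribute_homophily(net, config)

  scheme <- rsdb_category_scheme(drivers)
  detailed <- colnames(scheme$membership)[max.col(scheme$membership)]
  degree1 <- colSums(as.matrix(net)) == 1
  directedness <- ifelse(runif(length(drivers)) < 0.5, "direct", "indirect")
  steps <- ifelse(directedness == "direct", 1L, 1L + sample(1:2, length(drivers),
                                                            replace = TRUE))
  drv <- data.frame(node_name = drivers, side = "driver",
                    management_scale = scale_attr$management_scale,
                    directedness = directedness, steps_to_feedback = steps,
                    detailed_category = detailed,
                    broad_category = scheme$detailed_to_broad[detailed],
                    idiosyncratic = unname(degree1),
                    stringsAsFactors = FALSE)

  eco <- sample(c("marine", "terrestrial", "subcontinental"),
                length(shifts), replace = TRUE)
  blocks <- list(ecosystem_processes = 5, provisioning_services = 8,
                 regulating_services = 8, cultural_services = 4,
                 drivers_block = 10, land_use = 11, scales = 8,
                 reversibility = 3)
  blk_cols <- list()
  blk_df <- list()
  for (b in names(blocks)) {
    nv <- blocks[[b]]
    cols <- sprintf("%s_%02d", b, seq_len(nv))
    blk_cols[[b]] <- cols
    vals <- matrix(as.integer(runif(length(shifts) * nv) < 0.4),
                   length(shifts), nv, dimnames = list(NULL, cols))
    # every shift expresses at least one variable per block, so block
    # distances over binary profiles are always defined
    for (i in which(rowSums(vals) == 0))
      vals[i, sample.int(nv, 1)] <- 1L
    blk_df[[b]] <- as.data.frame(vals)
  }
  shf <- cbind(data.frame(node_name = shifts, side = "shift",
                          ecosystem_type = eco, stringsAsFactors = FALSE),
               do.call(cbind, unname(blk_df)))

  attributes <- merge_attr_frames(drv, shf)
  list(network = net, attributes = attributes, scheme = scheme,
       blocks = blk_cols)
}

# 15 detailed driver categories (mutually exclusive), 3 per broad category.
rsdb_category_scheme <- function(drivers) {
  detailed_to_broad <- c(
    "deforestation & land clearing"   = "habitat modification",
    "urbanisation & infrastructure"   = "habitat modification",
    "landscape fragmentation"         = "habitat modification",
    "agriculture & cropping"          = "food production",
    "livestock & ranching"            = "food production",
    "aquaculture"                     = "food production",
    "nutrient inputs"                 = "nutrients & pollutants",
    "chemical pollutants"             = "nutrients & pollutants",
    "waste & sewage"                  = "nutrients & pollutants",
    "fishing & harvesting"            = "resource extraction",
    "logging & biomass extraction"    = "resource extraction",
    "water extraction"                = "resource extraction",
    "climatic spillovers"             = "spill-over effects",
    "oceanic spillovers"              = "spill-over effects",
    "ecological spillovers"           = "spill-over effects")
  detailed <- names(detailed_to_broad)
  assignment <- sample(detailed, length(drivers), replace = TRUE)
  membership <- matrix(0L, length(drivers), length(detailed),
                       dimnames = list(drivers, detailed))
  membership[cbind(seq_along(drivers), match(assignment, detailed))] <- 1L
  list(detailed_names = detailed,
       broad_names = unique(unname(detailed_to_broad)),
       detailed_to_broad = detailed_to_broad,
       membership = membership)
}

# bind driver and shift attribute frames, padding missing columns with NA
merge_attr_frames <- function(a, b) {
  all_cols <- union(names(a), names(b))
  for (cl in setdiff(all_cols, names(a))) a[[cl]] <- NA
  for (cl in setdiff(all_cols, names(b))) b[[cl]] <- NA
  rbind(a[all_cols], b[all_cols])
}
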