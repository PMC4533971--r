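test_that("binary distances match their set-theoretic definitions", {
  net <- toy_network(list(c("S1", "a"), c("S1", "b"), c("S2", "a"),
                          c("S2", "b"), c("S3", "c")))
  d <- pairwise_distance(net, "shift", "jaccard")$distances
  expect_equal(d["S1", "S2"], 0)
  expect_equal(d["S1", "S3"], 1)
  d2 <- pairwise_distance(net, "shift", "sorensen_dice")$distances
  expect_equal(d2["S1", "S2"], 0)
  expect_equal(d2["S1", "S3"], 1)

  fx <- load_table1_fixture(canonical = TRUE)$network
  dj <- pairwise_distance(fx, "driver", "jaccard")$distances
  ds <- pairwise_distance(fx, "driver", "sorensen_dice")$distances
  expect_equal(dj["climate change", "greenhouse gases"], 7 / 9)
  expect_equal(ds["climate change", "greenhouse gases"], 7 / 11)

  bad <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
                dimnames = list(c("A", "B"), c("x", "y")))
  expect_error(suppressWarnings(pairwise_distance(bad, "shift")), "B")
})

test_that("distances agree with vegan and are proper dissimilarities", {
  skip_if_not_installed("vegan")
  m <- random_network(8, 10, 0.45, seed = 31)
  dj <- pairwise_distance(m, "shift", "jaccard")$distances
  ds <- pairwise_distance(m, "shift", "sorensen_dice")$distances
  expect_equal(as.dist(dj),
               vegan::vegdist(m, "jaccard", binary = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.dist(ds),
               vegan::vegdist(m, "bray", binary = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
  # jaccard triangle inequality on random triples
  set.seed(32)
  for (r in 1:1000) {
    ijk <- sample(nrow(dj), 3)
    expect_lte(dj[ijk[1], ijk[2]],
               dj[ijk[1], ijk[3]] + dj[ijk[3], ijk[2]] + 1e-12)
  }
  expect_true(all(dj >= 0 & dj <= 1) && all(diag(dj) == 0))
  expect_identical(dj, t(dj))
})

test_that("average-linkage clustering follows the closed form", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma_cluster(d)
  expect_equal(sort(dend$merge_heights), c(1, 4))
  nwk <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))

  # ultrametric input is reproduced exactly
  cop <- cophenetic(dend$hclust)
  dend2 <- upgma_cluster(as.matrix(cop))
  expect_equal(as.matrix(cophenetic(dend2$hclust))[rownames(d), rownames(d)],
               as.matrix(cop)[rownames(d), rownames(d)])
  expect_error(upgma_cluster(matrix(NA_real_, 2, 2)), "NA")
})

test_that("UPGMA matches a naive implementation on random instances", {
  for (s in 1:10) {
    set.seed(600 + s)
    x <- matrix(runif(10 * 4), 10)
    rownames(x) <- paste0("n", 1:10)
    d <- as.matrix(dist(x))
    dend <- upgma_cluster(d)
    cop <- as.matrix(cophenetic(dend$hclust))
    orc <- oracle_upgma_cophenetic(d)
    expect_equal(cop[rownames(d), rownames(d)], orc, tolerance = 1e-10)
    # tie-free distances: agreement with stats::hclust average linkage
    ref <- as.matrix(cophenetic(hclust(as.dist(d), method = "average")))
    expect_equal(cop[rownames(d), rownames(d)],
                 ref[rownames(d), rownames(d)], tolerance = 1e-10)
  }
})

test_that("classical MDS recovers planted geometry", {
  # three collinear points
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("p", "q", "r"), c("p", "q", "r")))
  ord <- suppressWarnings(classical_mds(d, k = 1))
  expect_equal(sort(ord$coordinates[, 1]), c(-1, 0, 1),
               ignore_attr = TRUE)
  expect_equal(max(ord$eigenvalues), 2)

  # planted 2-D cloud: embedded distances match the originals
  set.seed(77)
  pts <- matrix(rnorm(20 * 2), 20)
  rownames(pts) <- paste0("n", 1:20)
  d2 <- as.matrix(dist(pts))
  ord2 <- classical_mds(d2, k = 2)
  expect_equal(as.matrix(dist(ord2$coordinates)), d2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(ord2$coordinates)), c(0, 0),
               tolerance = 1e-10)
  expect_equal(sum(pmax(ord2$eigenvalues, 0)),
               sum(d2[upper.tri(d2)]^2) / 20, tolerance = 1e-8)

  # duplicated points coincide
  d3 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  rownames(d3) <- colnames(d3) <- paste0("m", 1:4)
  ord3 <- suppressWarnings(classical_mds(d3, k = 2))
  expect_equal(ord3$coordinates[1, ], ord3$coordinates[2, ],
               tolerance = 1e-10)
})

test_that("vector fitting recovers aligned variables and skips constants", {
  set.seed(55)
  pts <- matrix(rnorm(25 * 2), 25)
  rownames(pts) <- paste0("n", 1:25)
  ord <- classical_mds(as.matrix(dist(pts)), k = 2)
  vars <- data.frame(aligned = ord$coordinates[, 1],
                     flat = rep(1, 25),
                     noise = rnorm(25))
  rownames(vars) <- rownames(ord$coordinates)
  expect_message(
    fit <- fit_variables(ord, vars, n_perm = 199, seed = 9),
    "constant")
  aligned <- fit[fit$variable == "aligned", ]
  expect_equal(aligned$r_squared, 1, tolerance = 1e-10)
  expect_equal(abs(aligned$dir_axis1), 1, tolerance = 1e-8)
  expect_equal(aligned$permutation_p, 1 / 200)
  expect_false("flat" %in% fit$variable)
})

test_that("vector fitting r-squared matches vegan envfit", {
  skip_if_not_installed("vegan")
  set.seed(66)
  m <- random_network(12, 15, 0.4, seed = 66)
  ord <- classical_mds(pairwise_distance(m, "shift", "sorensen_dice"), k = 2)
  vars <- data.frame(v1 = rnorm(12), v2 = as.numeric(runif(12) < 0.5))
  rownames(vars) <- rownames(ord$coordinates)
  fit <- fit_variables(ord, vars, n_perm = 99, seed = 3)
  ef <- vegan::envfit(ord$coordinates, vars, permutations = 99)
  expect_equal(fit$r_squared, unname(ef$vectors$r[fit$variable]),
               tolerance = 1e-8)
})

test_that("vector-fit permutation p is calibrated and has power", {
  set.seed(88)
  pts <- matrix(rnorm(25 * 2), 25)
  rownames(pts) <- paste0("n", 1:25)
  ord <- classical_mds(as.matrix(dist(pts)), k = 2)
  p_null <- vapply(1:50, function(r) {
    v <- data.frame(x = rnorm(25))
    rownames(v) <- rownames(ord$coordinates)
    fit_variables(ord, v, n_perm = 99)$permutation_p
  }, numeric(1))
  expect_lte(mean(p_null < 0.05), 0.16)
  # planted signal at snr 3
  ax <- scale(ord$coordinates[, 1])[, 1]
  p_alt <- vapply(1:30, function(r) {
    v <- data.frame(x = ax + rnorm(25, sd = 1 / 3))
    rownames(v) <- rownames(ord$coordinates)
    fit_variables(ord, v, n_perm = 99)$permutation_p
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.9)
})

test_that("block distances clean zero columns and validate profiles", {
  attrs <- data.frame(node_name = c("S1", "S2", "S3"), side = "shift",
                      b1 = c(1, 1, 0), b2 = c(0, 1, 1), b3 = c(0, 0, 0),
                      b4 = c(1, 1, 1))
  out <- categorical_block_distance(attrs,
                                    list(blockA = c("b1", "b2", "b3"),
                                         blockB = "b4"))
  dA <- out$blockA$distances
  expect_equal(dA["S1", "S2"], 1 - 2 * 1 / 3)  # b3 removed before computing
  expect_equal(dA["S1", "S1"], 0)
  expect_equal(out$blockB$distances["S1", "S3"], 0)

  # complementary profiles are at distance 1
  attrs2 <- data.frame(node_name = c("S1", "S2"), side = "shift",
                       x = c(1, 0), y = c(0, 1))
  d2 <- categorical_block_distance(attrs2, list(b = c("x", "y")))$b$distances
  expect_equal(d2["S1", "S2"], 1)

  expect_error(categorical_block_distance(attrs, list(b = "nope")),
               "unknown")
  attrs$b5 <- c(0, 0, 0)
  expect_error(categorical_block_distance(attrs, list(b = "b5")),
               "no informative")

  # the full study block layout is accepted end to end
  syn <- generate_rsdb_like(9)
  blocks <- categorical_block_distance(syn$attributes, syn$blocks)
  expect_identical(names(blocks), names(syn$blocks))
  for (b in blocks)
    expect_true(all(b$distances >= 0 & b$distances <= 1))
})
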