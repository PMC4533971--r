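test_that("one-mode projections count shared neighbours", {
  tri <- toy_network(list(c("S", "x"), c("S", "y"), c("S", "z")))
  w <- project_one_mode(tri, "driver")$weights
  expect_true(all(w[upper.tri(w)] == 1))
  expect_true(all(diag(w) == 0))

  fx <- load_table1_fixture(canonical = TRUE)$network
  wfx <- project_one_mode(fx, "driver")$weights
  expect_identical(wfx["climate change", "greenhouse gases"], 2L)
  expect_identical(wfx["agriculture", "sewage"], 0L)
})

test_that("projection weights match the set-intersection oracle", {
  for (s in 1:10) {
    m <- random_network(6, 7, 0.4, seed = s)
    for (side in c("driver", "shift")) {
      w <- project_one_mode(m, side)$weights
      expect_identical(unname(w), unname(oracle_projection(m, side)))
      deg <- if (side == "driver") colSums(m) else rowSums(m)
      expect_true(all(w <= outer(deg, deg, pmin) | diag(length(deg)) == 1))
    }
  }
})

test_that("projection mean degree counts positive-weight neighbours", {
  tri <- project_one_mode(
    toy_network(list(c("S", "x"), c("S", "y"), c("S", "z"))), "driver")
  expect_equal(mean_degree(tri), 2)
  dyads <- project_one_mode(
    toy_network(list(c("S1", "a"), c("S1", "b"), c("S2", "c"),
                     c("S2", "d"))), "driver")
  expect_equal(mean_degree(dyads), 1)
  lonely <- project_one_mode(
    toy_network(list(c("S1", "a"), c("S2", "b"))), "driver")
  expect_equal(mean_degree(lonely), 0)
})

test_that("co-occurrence counts open triangles", {
  one <- toy_network(list(c("S", "x"), c("S", "y"), c("S", "z")))
  res <- co_occurrence_index(one, "driver")
  expect_identical(res$open_triangle_count, 3L)
  expect_equal(res$index, 1)
  for (k in c(2, 4, 6)) {
    star <- matrix(1L, 1, k, dimnames = list("S", paste0("d", 1:k)))
    expect_identical(co_occurrence_index(star, "driver")$open_triangle_count,
                     as.integer(choose(k, 2)))
  }
  fx <- load_table1_fixture(canonical = TRUE)$network
  for (side in c("driver", "shift")) {
    res <- co_occurrence_index(fx, side)
    expect_identical(res$open_triangle_count,
                     oracle_open_triangles(as.matrix(fx), side))
    # identity: total projection weight equals the open-triangle count
    w <- project_one_mode(fx, side)$weights
    expect_identical(sum(w[upper.tri(w)]), res$open_triangle_count)
  }
  expect_error(co_occurrence_index(matrix(1L, 3, 1,
                                          dimnames = list(letters[1:3], "x")),
                                   "driver"),
               "fewer than 2")
})

test_that("bipartite clustering counts squares over three-paths", {
  k22 <- matrix(1L, 2, 2, dimnames = list(c("A", "B"), c("x", "y")))
  res <- bipartite_clustering_coefficient(k22)
  expect_identical(res$squares, 1L)
  expect_identical(res$three_paths, 4L)
  expect_equal(res$cc, 1)

  star <- matrix(1L, 3, 1, dimnames = list(c("A", "B", "C"), "x"))
  res <- bipartite_clustering_coefficient(star)
  expect_identical(res$three_paths, 0L)
  expect_true(is.na(res$cc))
  expect_true(attr(res$cc, "undefined"))

  for (s in 1:50) {
    m <- random_network(6, 6, 0.35, seed = 100 + s, nonempty = FALSE)
    res <- bipartite_clustering_coefficient(m)
    orc <- oracle_squares_paths(m)
    expect_identical(res$squares, orc$squares)
    expect_identical(res$three_paths, orc$three_paths)
    if (orc$three_paths > 0)
      expect_equal(res$cc, 4 * orc$squares / orc$three_paths)
  }
})

test_that("NODF matches the pairwise-overlap oracle and vegan", {
  stair <- matrix(c(1L, 1L, 1L, 1L, 1L, 0L, 1L, 0L, 0L), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("r", 1:3), paste0("c", 1:3)))
  expect_equal(nodf_nestedness(stair)$nodf_total, 100)
  eye <- diag(3L)
  dimnames(eye) <- list(paste0("r", 1:3), paste0("c", 1:3))
  expect_equal(nodf_nestedness(eye)$nodf_total, 0)

  for (s in 1:12) {
    m <- random_network(8, 8, 0.45, seed = 200 + s)
    res <- nodf_nestedness(m)
    orc <- oracle_nodf(m)
    expect_equal(res$nodf_rows, orc$rows)
    expect_equal(res$nodf_cols, orc$cols)
    expect_equal(res$nodf_total, orc$total)
  }
  skip_if_not_installed("vegan")
  for (s in 1:5) {
    m <- random_network(7, 9, 0.4, seed = 300 + s)
    veg <- vegan::nestednodf(m, order = TRUE)$statistic
    expect_equal(nodf_nestedness(m)$nodf_total, unname(veg["NODF"]),
                 tolerance = 1e-10)
  }
})

test_that("driver summaries follow the truncation and tie conventions", {
  # degrees 5,1,1,1: the top driver alone exceeds half of the 8 links
  m <- matrix(0L, 5, 4, dimnames = list(paste0("s", 1:5), c("b", "a", "c", "d")))
  m[, "b"] <- 1L
  m[1, "a"] <- 1L; m[2, "c"] <- 1L; m[3, "d"] <- 1L
  ds <- driver_summary(m)
  expect_identical(ds$half_coverage, "b")
  expect_identical(ds$half_coverage_pct, 25L)
  expect_setequal(ds$idiosyncratic, c("a", "c", "d"))
  expect_identical(ds$idiosyncratic_pct, 75L)

  # 57 drivers, 13 of which account for more than half the links -> 22%
  deg <- c(rep(12L, 13), rep(3L, 44))
  big <- matrix(0L, 25, 57,
                dimnames = list(sprintf("s%02d", 1:25), sprintf("d%02d", 1:57)))
  for (j in seq_along(deg)) big[seq_len(deg[j]), j] <- 1L
  ds <- driver_summary(big)
  expect_identical(length(ds$half_coverage), 13L)
  expect_identical(ds$half_coverage_pct, 22L)

  # 14 idiosyncratic of 57 -> truncated 24%
  syn <- generate_rsdb_like(1)
  ds <- driver_summary(syn$network)
  expect_identical(length(ds$idiosyncratic), 14L)
  expect_identical(ds$idiosyncratic_pct, 24L)
  expect_identical(ds$shift_degree_range$min,
                   min(rowSums(as.matrix(syn$network))))
})

test_that("shared pairs are thresholded and deterministically sorted", {
  tri <- toy_network(list(c("S", "x"), c("S", "y"), c("S", "z")))
  expect_identical(nrow(shared_driver_pairs(tri, "driver", 1)), 3L)
  expect_identical(nrow(shared_driver_pairs(tri, "driver", 2)), 0L)

  fx <- load_table1_fixture(canonical = TRUE)$network
  pr <- shared_driver_pairs(fx, "driver", 2)
  expect_true(any(pr$node1 == "climate change" &
                  pr$node2 == "greenhouse gases" & pr$shared == 2))
  expect_true(all(diff(pr$shared) <= 0))
  expect_true(all(pr$node1 < pr$node2))
})

test_that("adding a link never decreases triangles or squares", {
  for (s in 1:10) {
    m <- random_network(6, 6, 0.4, seed = 400 + s)
    zeros <- which(m == 0L)
    if (!length(zeros)) next
    m2 <- m
    m2[sample(zeros, 1)] <- 1L
    expect_gte(co_occurrence_index(m2, "driver")$open_triangle_count,
               co_occurrence_index(m, "driver")$open_triangle_count)
    expect_gte(bipartite_clustering_coefficient(m2)$squares,
               bipartite_clustering_coefficient(m)$squares)
  }
})
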