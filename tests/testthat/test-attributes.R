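make_scheme <- function(drivers, detailed, broad_of) {
  memb <- matrix(0L, length(drivers), length(detailed),
                 dimnames = list(drivers, detailed))
  assign <- sample(detailed, length(drivers), replace = TRUE)
  memb[cbind(seq_along(drivers), match(assign, detailed))] <- 1L
  list(detailed_names = detailed, broad_names = unique(unname(broad_of)),
       detailed_to_broad = broad_of, membership = memb)
}

test_that("category counts are an incidence-by-membership product", {
  net <- toy_network(list(c("S", "a"), c("S", "b"), c("S", "c"),
                          c("T", "a")))
  memb <- matrix(c(1L, 1L, 0L, 0L, 0L, 1L), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  scheme <- list(detailed_names = c("c1", "c2"), broad_names = "B",
                 detailed_to_broad = c(c1 = "B", c2 = "B"),
                 membership = memb)
  counts <- category_counts(net, scheme)
  expect_identical(unname(counts["S", ]), c(2L, 1L))
  expect_identical(unname(counts["T", ]), c(1L, 0L))
  broad <- category_counts(net, scheme, "broad")
  expect_equal(unname(broad[, "B"]), unname(rowSums(counts)),
               ignore_attr = TRUE)
})

test_that("category row sums equal bipartite shift degrees", {
  detailed <- paste0("c", 1:6)
  broad_of <- setNames(rep(c("B1", "B2"), each = 3), detailed)
  for (s in 1:10) {
    m <- random_network(6, 9, 0.4, seed = 500 + s)
    set.seed(s)
    scheme <- make_scheme(colnames(m), detailed, broad_of)
    counts <- category_counts(m, scheme)
    expect_identical(unname(rowSums(counts)), unname(rowSums(m)))
    broad <- category_counts(m, scheme, "broad")
    expect_identical(unname(rowSums(broad)), unname(rowSums(m)))
  }
  m <- random_network(4, 5, 0.5, seed = 1)
  scheme <- make_scheme(colnames(m)[-1], detailed, broad_of)
  expect_error(category_counts(m, scheme), "missing")
})

test_that("management-scale proportions are per-shift simplex rows", {
  net <- toy_network(list(c("S", "a"), c("S", "b"), c("S", "c")))
  attrs <- data.frame(node_name = c("a", "b", "c"), side = "driver",
                      management_scale = c("local", "local",
                                           "international"))
  pr <- management_scale_proportions(net, attrs)
  expect_equal(unname(pr["S", ]), c(2 / 3, 0, 1 / 3))

  attrs$management_scale <- "international"
  pr <- management_scale_proportions(net, attrs)
  expect_equal(unname(pr["S", ]), c(0, 0, 1))

  syn <- generate_rsdb_like(6)
  pr <- management_scale_proportions(syn$network, syn$attributes)
  expect_equal(unname(rowSums(pr)), rep(1, 25), tolerance = 1e-9)
  # rows grouped by ecosystem type, as in the managerial-opportunity figure
  sa <- syn$attributes[syn$attributes$side == "shift", ]
  eco <- sa$ecosystem_type[match(rownames(pr), sa$node_name)]
  expect_false(is.unsorted(eco))

  attrs2 <- data.frame(node_name = c("a", "b"), side = "driver",
                       management_scale = c("local", "local"))
  expect_error(management_scale_proportions(net, attrs2), "without a valid")
})

test_that("global scale shares use truncated percentages", {
  attrs <- data.frame(
    node_name = sprintf("d%02d", 1:57), side = "driver",
    management_scale = c(rep("local", 20), rep("regional_national", 15),
                         rep("international", 22)))
  sh <- global_scale_shares(attrs)
  expect_equal(sum(sh$fraction), 1)
  expect_identical(sh$subnational_pct, 61L)  # 35/57 = 61.4%, truncated
  expect_equal(sh$subnational_fraction, 35 / 57)

  all_local <- data.frame(node_name = "a", side = "driver",
                          management_scale = "local")
  expect_identical(global_scale_shares(all_local)$pct[["local"]], 100L)
  expect_error(global_scale_shares(
    data.frame(node_name = "a", side = "driver",
               management_scale = "galactic")), "unknown")
})

test_that("homophily test separates label-pure cliques", {
  # two shifts with disjoint driver triples: two label-pure cliques
  net <- toy_network(list(c("S1", "a"), c("S1", "b"), c("S1", "c"),
                          c("S2", "x"), c("S2", "y"), c("S2", "z")))
  proj <- project_one_mode(net, "driver")
  labels <- setNames(rep(c("L1", "L2"), each = 3),
                     c("a", "b", "c", "x", "y", "z"))
  ht <- attribute_homophily_test(proj, labels, n_perm = 999, seed = 1)
  expect_equal(ht$observed_within_share, 1)
  # exactly the permutations that re-separate the cliques are as extreme
  set.seed(1)
  n_extreme <- sum(vapply(1:999, function(i) {
    lb <- sample(labels)
    w <- proj$weights; ut <- upper.tri(w)
    sum(w[ut & outer(lb, lb, "==")]) / sum(w[ut]) >= 1
  }, logical(1)))
  expect_equal(ht$permutation_p, (1 + n_extreme) / 1000)
  expect_lt(ht$permutation_p, 0.25)

  expect_error(attribute_homophily_test(proj, setNames(rep("L", 6),
                                                       names(labels))),
               "two distinct")
})

test_that("homophily permutation p is valid under random labels", {
  syn <- generate_rsdb_like(8)
  proj <- project_one_mode(syn$network, "driver")
  set.seed(99)
  p <- vapply(1:60, function(r) {
    labels <- setNames(sample(c("L1", "L2", "L3"), 57, replace = TRUE),
                       driver_names(syn$network))
    attribute_homophily_test(proj, labels, n_perm = 99)$permutation_p
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.15)
  expect_gt(mean(p), 0.35)
})
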