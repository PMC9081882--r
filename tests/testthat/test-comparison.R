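test_that("total connectivity contrast reports both tests with pooled df", {
  r <- total_connectivity_contrast(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$df, 4)
  expect_equal(r$mean_a, r$mean_b)

  # hand-ranked Kruskal-Wallis: ranks 1..6, group means 2 and 5
  r2 <- total_connectivity_contrast(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$H, 27 / 7, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:5) {
    na <- sample(5:50, 1); nb <- sample(5:50, 1)
    r3 <- total_connectivity_contrast(rnorm(na), rnorm(nb))
    expect_equal(r3$df, na + nb - 2)
  }
  expect_error(total_connectivity_contrast(1, c(1, 2)), "length >= 2")
})

test_that("node-level contrast extracts 29 strengths per condition", {
  ca <- correlation_matrix(make_null_cohort(seed = 32, condition = "a"))
  cb <- correlation_matrix(make_null_cohort(seed = 33, condition = "b"))
  r <- node_connectivity_contrast(ca, cb, "LC-L")
  expect_equal(r$n_a, 29)
  expect_equal(r$n_b, 29)
  expect_equal(r$df, 56)
  same <- node_connectivity_contrast(ca, ca, "LC-L")
  expect_equal(same$t, 0)
  expect_error(node_connectivity_contrast(ca, cb, "XX-L"), "unknown region")
})

test_that("node contrast fails informatively when all pairs are undefined", {
  co <- make_null_cohort(seed = 34)
  co$densities[, "LC-L"] <- 10
  cm <- suppressWarnings(correlation_matrix(co))
  cb <- correlation_matrix(make_null_cohort(seed = 35))
  expect_error(node_connectivity_contrast(cm, cb, "LC-L"), "undefined")
})

test_that("hemispheric counts follow the >=1-endpoint group rule", {
  empty <- network_from_edges(empty_edge_df())
  expect_true(all(empty$intra_left == 0 & empty$intra_right == 0 &
                  empty$inter == 0))

  one <- hemispheric_counts(network_from_edges(data.frame(
    from = "Cg-L", to = "PrL-L", rho = 0.9, p = 0.01, n = 8L, sign = 1L,
    stringsAsFactors = FALSE)))
  expect_equal(one$intra_left[one$area_group == "frontal"], 1L)
  expect_equal(sum(one$intra_left) + sum(one$intra_right) + sum(one$inter), 1L)

  # a cross-group cross-hemisphere edge is counted in both groups
  two <- hemispheric_counts(network_from_edges(data.frame(
    from = "Cg-L", to = "DG-R", rho = -0.8, p = 0.02, n = 8L, sign = -1L,
    stringsAsFactors = FALSE)))
  expect_equal(two$inter[two$area_group == "frontal"], 1L)
  expect_equal(two$inter[two$area_group == "hippocampal"], 1L)
  expect_equal(sum(two$intra_left) + sum(two$intra_right), 0L)

  # edges between "other" regions appear in no group
  other <- hemispheric_counts(network_from_edges(data.frame(
    from = "PVT-L", to = "RSP-L", rho = 0.8, p = 0.02, n = 8L, sign = 1L,
    stringsAsFactors = FALSE)))
  expect_true(all(other[, -1] == 0))
})

test_that("hemispheric counts are symmetric under L/R mirroring", {
  d <- generate_condition_pair(study_preset(seed = 13))
  net <- threshold_network(correlation_matrix(d$cohort_b))
  counts <- hemispheric_counts(net)
  mirror <- function(code) {
    flip <- sub("-L$", "-X", code)
    flip <- sub("-R$", "-L", flip)
    sub("-X$", "-R", flip)
  }
  mnet <- net
  mnet$edges$from <- mirror(net$edges$from)
  mnet$edges$to <- mirror(net$edges$to)
  mcounts <- hemispheric_counts(mnet)
  expect_equal(mcounts$intra_left, counts$intra_right)
  expect_equal(mcounts$intra_right, counts$intra_left)
  expect_equal(mcounts$inter, counts$inter)
})

test_that("positive fraction covers the trivial sign cases", {
  cm <- correlation_matrix(make_null_cohort(seed = 36))
  pos <- cm; pos$rho[] <- 0.3; diag(pos$rho) <- NA
  expect_equal(positive_fraction(pos), 1)
  neg <- cm; neg$rho[] <- -0.3; diag(neg$rho) <- NA
  expect_equal(positive_fraction(neg), 0)
  half <- cm
  ut <- which(upper.tri(half$rho))
  half$rho[ut] <- rep(c(0.5, -0.5), length.out = length(ut))
  half$rho[lower.tri(half$rho)] <- t(half$rho)[lower.tri(half$rho)]
  expect_equal(positive_fraction(half), mean(half$rho[ut] > 0))
})

test_that("regional density contrasts detect a planted shift and respect nulls", {
  a <- make_null_cohort(seed = 37, condition = "a")
  same <- regional_density_contrast(a, a)
  expect_equal(nrow(same), 30)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_w == 1))

  b <- make_null_cohort(seed = 38, condition = "b")
  shift <- 10 * sd(b$densities[, "DG-L"])
  b$densities[, "DG-L"] <- b$densities[, "DG-L"] + shift
  res <- regional_density_contrast(a, b)
  expect_lt(res$p_t[res$code == "DG-L"], 0.001)

  adj <- regional_density_contrast(a, b, adjust = "BH")
  expect_true(all(c("p_t_adj", "p_w_adj") %in% names(adj)))
  expect_true(all(adj$p_t_adj >= adj$p_t - 1e-12))
})

test_that("compare_conditions assembles the full contrast", {
  d <- generate_condition_pair(study_preset(seed = 14))
  ctr <- suppressWarnings(compare_conditions(d$cohort_a, d$cohort_b))
  expect_s3_class(ctr, "fos_contrast")
  expect_equal(ctr$total_connectivity$df, 868)
  expect_named(ctr$lc_contrast, c("LC-L", "LC-R"))
  expect_equal(nrow(ctr$density_tests), 30)
  expect_true(all(ctr$positive_fraction >= 0 & ctr$positive_fraction <= 1))
  # four global metrics per condition
  for (m in list(ctr$metrics_a, ctr$metrics_b))
    expect_true(all(c("global_efficiency", "average_clustering",
                      "average_strength", "average_degree") %in% names(m)))
})
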