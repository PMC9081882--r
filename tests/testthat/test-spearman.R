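test_that("spearman_pair recovers monotone association exactly", {
  expect_equal(spearman_pair(1:5, c(10, 20, 30, 40, 50))$rho, 1.0)
  expect_equal(spearman_pair(1:5, c(5, 4, 3, 2, 1))$rho, -1.0)
  # concordant ranks at n = 5: one permutation per tail attains |rho| = 1
  res <- spearman_pair(1:5, 2^(1:5), method = "exact")
  expect_equal(res$p, 2 / 120)
})

test_that("exact p-values match the brute-force permutation oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    res <- spearman_pair(x, y, method = "exact")
    expect_equal(res$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact p-values handle ties by permuting observed ranks", {
  set.seed(43)
  for (i in 1:15) {
    n <- sample(5:7, 1)
    x <- sample(1:4, n, replace = TRUE)   # guaranteed ties at n >= 5
    y <- rnorm(n)
    if (length(unique(x)) < 2) next
    res <- spearman_pair(x, y, method = "exact")
    expect_equal(res$p, oracle_spearman_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact p-values agree with the classical exact distribution", {
  # independent check against stats::cor.test's exact Spearman p (AS 89),
  # valid for untied data
  set.seed(44)
  for (i in 1:10) {
    n <- sample(5:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    res <- spearman_pair(x, y, method = "exact")
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  }
})

test_that("t approximation matches the closed form", {
  set.seed(45)
  x <- rnorm(20); y <- x + rnorm(20)
  res <- spearman_pair(x, y, method = "t_approx")
  tt <- res$rho * sqrt((20 - 2) / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(-abs(tt), 18))
  # auto switches to the approximation above n = 9
  expect_equal(spearman_pair(x, y, method = "auto")$method, "t_approx")
  expect_equal(spearman_pair(x[1:8], y[1:8], method = "auto")$method, "exact")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(46)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    base <- spearman_pair(x, y)$rho
    expect_equal(spearman_pair(exp(x), y)$rho, base)
    expect_equal(spearman_pair(x, 3 * y + 7)$rho, base)
    expect_equal(spearman_pair(x, exp(y))$rho, base)
  }
})

test_that("degenerate inputs are signalled, not imputed", {
  expect_warning(res <- spearman_pair(rep(1, 5), rnorm(5)), "constant")
  expect_true(is.na(res$rho) && is.na(res$p))
  expect_error(spearman_pair(1:2, 2:1), "at least 3")
  expect_error(suppressWarnings(spearman_pair(c(1, NA, 3, NA), c(1, 2, 3, 4))),
               "at least 3")
})

test_that("correlation_matrix covers all 435 pairs symmetrically", {
  co <- make_null_cohort(n_animals = 8, seed = 21)
  cm <- correlation_matrix(co)
  expect_s3_class(cm, "fos_corr")
  ut <- upper.tri(cm$rho)
  expect_equal(sum(ut), 435L)
  expect_false(anyNA(cm$rho[ut]))
  expect_false(anyNA(cm$pvals[ut]))
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(cm$pvals, t(cm$pvals))
  expect_true(all(is.na(diag(cm$rho))))
  expect_true(all(abs(cm$rho[ut]) <= 1))
  expect_true(all(cm$n_pairs[ut] == 8))
})

test_that("fast vectorized path agrees with per-pair computation", {
  co <- make_null_cohort(n_animals = 8, seed = 22)
  cm <- correlation_matrix(co)        # fast path: no NA, no ties
  idx <- cbind(c(1, 5, 12), c(2, 18, 30))
  for (k in seq_len(nrow(idx))) {
    res <- spearman_pair(co$densities[, idx[k, 1]],
                         co$densities[, idx[k, 2]], method = "exact")
    expect_equal(cm$rho[idx[k, 1], idx[k, 2]], res$rho)
    expect_equal(cm$pvals[idx[k, 1], idx[k, 2]], res$p)
  }
})

test_that("duplicate regions correlate perfectly; missing values drop pairwise", {
  co <- make_null_cohort(n_animals = 8, seed = 23)
  co$densities[, 2] <- co$densities[, 1]
  co$densities[3, 5] <- NA
  cm <- correlation_matrix(co)
  expect_equal(cm$rho[1, 2], 1.0)
  expect_equal(cm$n_pairs[5, 6], 7L)
  expect_equal(cm$n_pairs[1, 2], 8L)
})

test_that("a constant region yields undefined entries with a warning", {
  co <- make_null_cohort(n_animals = 8, seed = 24)
  co$densities[, 4] <- 50
  expect_warning(cm <- correlation_matrix(co), "undefined")
  expect_true(all(is.na(cm$rho[4, -4])))
  expect_warning(z <- all_pairs_z(cm), "excluded")
  expect_length(z, 435 - 29)
})

test_that("iid noise produces no strong correlations at large n", {
  co <- make_null_cohort(n_animals = 1000, seed = 25)
  cm <- correlation_matrix(co)
  expect_lt(max(abs(cm$rho[upper.tri(cm$rho)])), 0.2)
})

test_that("fisher_z is the closed-form atanh with clamping at the poles", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(-0.5), -0.5 * log(3))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
  expect_error(fisher_z(1.2), "not a correlation")
  # strictly increasing and odd
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(fisher_z(r), -fisher_z(rev(r)))
})

test_that("all_pairs_z has fixed atlas-order length and trivial zero case", {
  co <- make_null_cohort(seed = 26)
  cm <- correlation_matrix(co)
  z <- all_pairs_z(cm)
  expect_length(z, 435)
  expect_equal(names(z)[1], "Cg-L|Cg-R")
  zero <- cm
  zero$rho[] <- 0
  diag(zero$rho) <- NA
  expect_equal(unname(all_pairs_z(zero)), rep(0, 435))
})

test_that("thresholding keeps strictly significant edges of both signs", {
  co <- make_null_cohort(seed = 27)
  cm <- correlation_matrix(co)
  flat <- cm; flat$pvals[] <- 0.5
  expect_equal(nrow(threshold_network(flat)$edges), 0L)

  net <- threshold_network(cm, alpha = 0.05)
  expect_true(all(net$edges$p < 0.05))
  # positive significant edges carry atanh weights; negative edges weight 0
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    w <- net$z_weights[e$from, e$to]
    if (e$sign > 0) expect_equal(w, atanh(e$rho)) else expect_equal(w, 0)
  }
  expect_equal(net$z_weights, t(net$z_weights))
  expect_true(all(diag(net$z_weights) == 0))
  expect_error(threshold_network(cm, alpha = 0), "alpha")
  expect_error(threshold_network(cm, alpha = 1), "alpha")
})

test_that("edge sets nest monotonically in alpha", {
  co <- make_null_cohort(seed = 28)
  cm <- correlation_matrix(co)
  alphas <- c(0.001, 0.01, 0.05, 0.2, 0.999999)
  prev <- NULL
  for (a in alphas) {
    e <- threshold_network(cm, alpha = a)$edges
    key <- paste(e$from, e$to)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
  # alpha near 1 keeps every pair whose p-value is below it (exact
  # permutation p-values can be exactly 1, so those pairs never enter)
  pv <- cm$pvals[upper.tri(cm$pvals)]
  expect_equal(length(prev), sum(pv < 0.999999))
})

test_that("BH adjustment prunes the uncorrected edge set", {
  d <- generate_condition_pair(study_preset(seed = 9))
  cm <- correlation_matrix(d$cohort_b)
  raw <- threshold_network(cm, adjust = "none")
  bh <- threshold_network(cm, adjust = "BH")
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(bh$edges) %in% key(raw$edges)))
  expect_lte(nrow(bh$edges), nrow(raw$edges))
})
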