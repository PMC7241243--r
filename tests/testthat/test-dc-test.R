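test_that("column permutation preserves marginals and destroys association", {
  set.seed(51)
  X <- matrix(stats::rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  Xp <- permute_columns(X, seed = 1)
  expect_equal(apply(Xp, 2, sort), apply(X, 2, sort))
  expect_equal(dimnames(Xp), dimnames(X))
  # single-row input is returned unchanged
  expect_equal(permute_columns(X[1, , drop = FALSE]), X[1, , drop = FALSE])
  # perfectly correlated columns decorrelate under independent shuffles
  z <- stats::rnorm(1000)
  XX <- cbind(z, z)
  cors <- vapply(1:100, function(i) {
    Xs <- permute_columns(XX)
    abs(stats::cor(Xs[, 1], Xs[, 2]))
  }, 0)
  expect_lt(mean(cors), 0.1)
})

test_that("dc_test is reproducible from its seed and respects the p-value floor", {
  set.seed(52)
  x1 <- matrix(stats::rnorm(50 * 8), 50, 8)
  x2 <- matrix(stats::rnorm(50 * 8), 50, 8)
  f1 <- dc_test(x1, x2, n_perm = 100, seed = 9)
  f2 <- dc_test(x1, x2, n_perm = 100, seed = 9)
  expect_identical(f1$table, f2$table)
  f3 <- dc_test(x1, x2, n_perm = 100, seed = 10)
  expect_false(identical(f1$table$p_value, f3$table$p_value))
  # p-values live in [1/n_perm, 1]
  expect_true(all(f1$table$p_value >= 1 / 100))
  expect_true(all(f1$table$p_value <= 1))
  expect_equal(f1$table$significant, f1$table$p_value < 0.05)
})

test_that("a strong connectivity difference reaches the minimum attainable p-value", {
  set.seed(53)
  S <- toeplitz_matrix(6, 0.9)
  x1 <- sample_gaussian(S, 300)
  x2 <- matrix(stats::rnorm(300 * 6), 300, 6)
  colnames(x2) <- colnames(x1)
  fit <- dc_test(x1, x2, n_perm = 100, seed = 3)
  expect_true(all(fit$table$significant))
  expect_true(any(fit$table$p_value == 1 / 100))
})

test_that("p-values are approximately uniform under the global null", {
  set.seed(54)
  pv <- unlist(lapply(1:50, function(r) {
    x1 <- matrix(stats::rnorm(100 * 10), 100, 10)
    x2 <- matrix(stats::rnorm(100 * 10), 100, 10)
    dc_test(x1, x2, n_perm = 200)$table$p_value
  }))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("correlation-based results are scale invariant", {
  set.seed(55)
  x1 <- matrix(stats::rnorm(40 * 6), 40, 6)
  x2 <- matrix(stats::rnorm(40 * 6), 40, 6)
  for (ms in c("pearson", "spearman")) {
    a <- dc_test(x1, x2, measure = ms, n_perm = 50, seed = 4)
    b <- dc_test(2 * x1, 2 * x2, measure = ms, n_perm = 50, seed = 4)
    expect_equal(a$table$p_value, b$table$p_value)
  }
})

test_that("MI-based dc_test works for every estimator and matches a slow oracle", {
  set.seed(56)
  x1 <- matrix(stats::rnorm(30 * 4), 30, 4)
  x2 <- matrix(stats::rnorm(30 * 4), 30, 4)
  for (est in c("empirical", "miller_madow", "shrinkage",
                "schurmann_grassberger")) {
    fit <- dc_test(x1, x2, measure = "mi", estimator = est, n_perm = 20,
                   seed = 5)
    # observed chi agrees with the association-matrix route
    A1 <- association_matrix(x1, "mi", est)
    A2 <- association_matrix(x2, "mi", est)
    expect_equal(fit$table$chi_g1, unname(node_connectivity(A1)),
                 tolerance = 1e-12)
    expect_equal(fit$table$delta_chi,
                 unname(differential_connectivity(A1, A2)),
                 tolerance = 1e-12)
  }
})

test_that("spearman dc_test equals pearson dc_test on pre-ranked data", {
  set.seed(57)
  x1 <- matrix(stats::rnorm(30 * 5), 30, 5)
  x2 <- matrix(stats::rnorm(30 * 5), 30, 5)
  a <- dc_test(x1, x2, measure = "spearman", n_perm = 50, seed = 6)
  b <- dc_test(apply(x1, 2, rank), apply(x2, 2, rank),
               measure = "pearson", n_perm = 50, seed = 6)
  expect_equal(a$table$delta_chi, b$table$delta_chi, tolerance = 1e-12)
  expect_equal(a$table$p_value, b$table$p_value)
})

test_that("dc_test validates inputs and supports BH adjustment", {
  x1 <- matrix(stats::rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  x2 <- matrix(stats::rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "z")))
  expect_error(dc_test(x1, x2), "do not match")
  expect_error(dc_test(x1[, 1:2], x1), "same features")
  expect_error(dc_test(x1[1:2, ], x1[1:2, ]), "at least 3")
  expect_error(dc_test(x1, x1, alpha = 1.2), "alpha")
  set.seed(58)
  x2 <- matrix(stats::rnorm(30), 10, 3, dimnames = dimnames(x1))
  fit <- dc_test(x1, x2, n_perm = 50, seed = 1, p_adjust = "BH")
  expect_true("p_adjusted" %in% names(fit$table))
  expect_equal(fit$table$p_adjusted, stats::p.adjust(fit$table$p_value, "BH"))
  expect_equal(fit$table$significant, fit$table$p_adjusted < fit$alpha)
})

test_that("dc_test methods print, summarize, and expose coefficients", {
  set.seed(59)
  x1 <- matrix(stats::rnorm(60), 20, 3)
  x2 <- matrix(stats::rnorm(60), 20, 3)
  fit <- dc_test(x1, x2, n_perm = 30, seed = 2)
  expect_output(print(fit), "Differential connectivity test")
  expect_output(print(summary(fit)), "ordered by significance")
  expect_equal(unname(coef(fit)), fit$table$delta_chi)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
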