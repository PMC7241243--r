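check_corr <- function(S) {
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
}

test_that("Toeplitz matrices follow the AR(1) pattern exactly and stay PD", {
  expect_equal(toeplitz_matrix(4, 0)$matrix, diag(4))
  m <- toeplitz_matrix(4, 0.5)$matrix
  expect_equal(m[1, ], c(1, 0.5, 0.25, 0.125))
  for (rho in c(0.3, 0.6, 0.9)) {
    S <- toeplitz_matrix(20, rho)$matrix
    ij <- abs(outer(1:20, 1:20, "-"))
    expect_equal(S, rho^ij, tolerance = 1e-15)
    check_corr(S)
  }
  expect_error(toeplitz_matrix(20, 1), "singular")
  expect_error(toeplitz_matrix(1, 0.5), "at least 2")
})

test_that("Hardin perturbation bounds entry changes and preserves PD", {
  base <- toeplitz_matrix(20, 0.5)
  expect_identical(perturb_hardin(base, eps_noise = 0), base)
  set.seed(61)
  for (i in 1:50) {
    pert <- perturb_hardin(base, eps_noise = 0.01, edim = 2)
    d <- abs(pert$matrix - base$matrix)
    expect_lte(max(d), 2 * 0.01)
    expect_equal(unname(diag(pert$matrix)), rep(1, 20))
    expect_gt(min(eigen(pert$matrix, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  # noise scale must stay below the smallest eigenvalue
  expect_error(perturb_hardin(toeplitz_matrix(20, 0.99), eps_noise = 0.01),
               "eigenvalue")
})

test_that("hub correlations interpolate from rho to rho_min as specified", {
  r <- hub_correlations(5, 0.8, 0.2, 2)
  expect_equal(r[1], 0.8)           # i = 2: exactly rho
  expect_equal(r[2], 0.8 - (1 / 3)^2 * 0.6, tolerance = 1e-15)  # 0.7333
  expect_equal(r[4], 0.2)           # i = g: exactly rho_min
  expect_error(hub_correlations(5, 0.5, 0.6), "rho_min")
  expect_error(hub_correlations(2, 0.5), "at least 3")
})

test_that("hub matrices are block structured with zero cross-group entries", {
  m <- hub_matrix(c(5, 4), rho = 0.3, rho_min = 0.1)
  S <- m$raw
  # raw entries match the attenuation formula to machine precision
  expect_equal(S[1, 2:5], hub_correlations(5, 0.3, 0.1), tolerance = 1e-15)
  expect_equal(S[6, 7:9], hub_correlations(4, 0.3, 0.1), tolerance = 1e-15)
  # non-hub pairs within a group and all cross-group pairs are zero
  expect_equal(S[2:5, 2:5], diag(4))
  expect_true(all(S[1:5, 6:9] == 0))
  check_corr(m$matrix)
  # PD-safe parameters leave the matrix unrepaired
  expect_equal(m$matrix, m$raw)
  # strong rho with the default 15/5 groups triggers the repair warning
  expect_warning(hub_matrix(c(15, 5), rho = 0.8), "positive definite")
})

test_that("Beta moment inversion round-trips through the moment formulas", {
  sh <- beta_shape_from_moments(0.5, 0.1)
  expect_equal(sh$alpha, 0.75)
  expect_equal(sh$beta, 0.75)
  sh <- beta_shape_from_moments(0.2, 0.01)
  expect_equal(c(sh$alpha, sh$beta), c(3, 12))
  set.seed(62)
  for (i in 1:50) {
    mu <- stats::runif(1, 0.05, 0.95)
    s2 <- stats::runif(1, 0.1, 0.9) * mu * (1 - mu)
    sh <- beta_shape_from_moments(mu, s2)
    ab <- sh$alpha + sh$beta
    expect_equal(sh$alpha / ab, mu, tolerance = 1e-10)
    expect_equal(sh$alpha * sh$beta / (ab^2 * (ab + 1)), s2, tolerance = 1e-10)
  }
  # symmetric case: alpha = beta for any valid variance
  sh <- beta_shape_from_moments(0.5, 0.2)
  expect_equal(sh$alpha, sh$beta)
  expect_error(beta_shape_from_moments(0.5, 0.3), "valid Beta")
})

test_that("vine matrices are valid correlation matrices, PD across seeds", {
  sh <- beta_shape_from_moments(0.6, 0.1)
  for (s in 1:50) {
    S <- vine_matrix(20, sh$alpha, sh$beta, seed = s)$matrix
    check_corr(S)
  }
  # symmetric Beta centers the signed off-diagonal correlations at zero
  set.seed(63)
  m <- mean(vapply(1:200, function(i) {
    S <- vine_matrix(8, 0.75, 0.75)$matrix
    mean(S[upper.tri(S)])
  }, 0))
  expect_lt(abs(m), 0.05)
})

test_that("average absolute correlation summarizes the upper triangle", {
  expect_equal(average_abs_correlation(diag(5)), 0)
  expect_equal(average_abs_correlation(toeplitz_matrix(3, 0.5)),
               (0.5 + 0.25 + 0.5) / 3)
  S <- matrix(-0.3, 4, 4)
  diag(S) <- 1
  expect_equal(average_abs_correlation(S), 0.3)
})

test_that("vine calibration round-trips and is monotone over achievable targets", {
  mus <- vapply(c(0.5, 0.6, 0.7, 0.8), function(t)
    calibrate_mu(t, p = 20, sigma2 = 0.1, n_matrices = 20, seed = 64), 0)
  expect_true(all(diff(mus) >= 0))
  # fresh draws at the calibrated mean reproduce the target
  sh <- beta_shape_from_moments(mus[2], 0.1)
  set.seed(65)
  achieved <- mean(vapply(1:30, function(i)
    average_abs_correlation(vine_matrix(20, sh$alpha, sh$beta)), 0))
  expect_lt(abs(achieved - 0.6), 0.05)
  # targets just below the attainable floor return the boundary with a warning
  expect_warning(mu_floor <- calibrate_mu(0.4, n_matrices = 10, seed = 66),
                 "floor")
  expect_equal(mu_floor, 0.5)
  expect_error(calibrate_mu(0.1, n_matrices = 10, seed = 66),
               "not achievable")
})

test_that("Gaussian sampling reproduces the target correlation structure", {
  S <- toeplitz_matrix(5, 0.6)
  X <- sample_gaussian(S, 5000, seed = 67)
  expect_equal(dim(X), c(5000, 5))
  expect_true(max(abs(stats::cor(X) - S$matrix)) < 0.05)
  X0 <- sample_gaussian(diag(8), 5000, seed = 68)
  C0 <- stats::cor(X0)
  diag(C0) <- 0
  expect_lt(max(abs(C0)), 0.06)
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(sample_gaussian(bad, 10), "positive definite")
})

test_that("lag-1 correlation of sampled Toeplitz data recovers rho", {
  for (rho in c(0.3, 0.6, 0.9)) {
    X <- sample_gaussian(toeplitz_matrix(20, rho), 2000, seed = round(100 * rho))
    A <- association_matrix(X)
    lag1 <- A$weights[cbind(1:19, 2:20)]
    expect_lt(abs(mean(lag1) - rho), 0.05)
  }
})

test_that("correlation matrices survive a CSV round trip", {
  S <- perturb_hardin(toeplitz_matrix(6, 0.4), seed = 69)
  path <- tempfile(fileext = ".csv")
  write_corr_matrix(S, path)
  expect_equal(read_corr_matrix(path), S$matrix, tolerance = 1e-12)
})
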