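test_that("equal-frequency discretization balances bins and handles ties", {
  expect_equal(discretize(1:9, 3)$labels, rep(1:3, each = 3))
  # default bin count is the cube root rule
  expect_equal(discretize(seq_len(27))$n_bins, 3L)
  expect_equal(discretize(seq_len(28))$n_bins, 4L)
  # constant input occupies one bin
  d <- discretize(rep(2.5, 10))
  expect_true(all(d$labels == 1L))
  # tied values always share a bin
  d <- discretize(c(1, 1, 1, 2, 3, 4), 3)
  expect_equal(length(unique(d$labels[1:3])), 1L)
  # balanced occupancy for distinct values at several n / n_bins combos
  set.seed(41)
  for (n in c(10, 30, 101)) {
    for (nb in c(2, 3, 7)) {
      lab <- discretize(stats::rnorm(n), nb)$labels
      expect_true(all(lab >= 1 & lab <= nb))
      occ <- tabulate(lab, nb)
      expect_lte(diff(range(occ)), 1)
    }
  }
  expect_error(discretize(1:5, 6), "exceed")
  expect_error(discretize(3), "at least 2")
})

test_that("equal-width discretization splits the range evenly", {
  lab <- discretize(c(0, 0.1, 0.4, 0.6, 0.9, 1), 2, scheme = "equal_width")$labels
  expect_equal(lab, c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("empirical entropy reproduces the worked three-bin example and the oracle", {
  expect_equal(entropy(c(2, 7, 1))$value, 0.8018, tolerance = 1e-4)
  expect_equal(entropy(c(5, 5, 5, 5))$value, log(4), tolerance = 1e-12)
  expect_equal(entropy(10)$value, 0)
  set.seed(7)
  for (i in 1:50) {
    counts <- random_counts()
    expect_equal(entropy(counts)$value, oracle_entropy(counts),
                 tolerance = 1e-12)
    expect_gte(entropy(counts)$value, 0)
    expect_lte(entropy(counts)$value, log(sum(counts > 0)) + 1e-12)
  }
  expect_error(entropy(c(0, 0)), "all-zero")
  expect_error(entropy(c(-1, 2)), "nonnegative")
})

test_that("Miller-Madow equals empirical plus the exact bias term", {
  expect_equal(entropy(c(2, 7, 1), "miller_madow")$value,
               0.8018 + (3 - 1) / (2 * 10), tolerance = 1e-4)
  set.seed(8)
  for (i in 1:100) {
    counts <- random_counts()
    gap <- entropy(counts, "miller_madow")$value - entropy(counts)$value
    expect_equal(gap, (sum(counts > 0) - 1) / (2 * sum(counts)),
                 tolerance = 1e-12)
  }
})

test_that("shrinkage estimator matches its closed form and keeps lambda in [0,1]", {
  # hand evaluation: lambda* = (1-0.54)/(9*0.206667) = 0.24731,
  # shrunken p = lambda/3 + (1-lambda) * (0.2, 0.7, 0.1)
  e <- entropy(c(2, 7, 1), "shrinkage")
  lam <- (1 - 0.54) / (9 * sum((1 / 3 - c(0.2, 0.7, 0.1))^2))
  pl <- lam / 3 + (1 - lam) * c(0.2, 0.7, 0.1)
  expect_equal(e$lambda_star, lam, tolerance = 1e-10)
  expect_equal(e$value, -sum(pl * log(pl)), tolerance = 1e-10)
  set.seed(9)
  for (i in 1:1000) {
    e <- entropy(random_counts(), "shrinkage")
    expect_gte(e$lambda_star, 0)
    expect_lte(e$lambda_star, 1)
  }
  # uniform counts have a degenerate denominator -> full shrinkage
  expect_equal(entropy(c(4, 4, 4, 4), "shrinkage")$lambda_star, 1)
})

test_that("Dirichlet-prior estimator follows the digamma formula as written", {
  counts <- c(2, 7, 1)
  m <- 3
  N <- 1 / m
  n <- 10
  tot <- n + m * N
  expected <- sum((counts + N) * (digamma(tot + 1) - digamma(counts + N + 1))) / tot
  expect_equal(entropy(counts, "schurmann_grassberger")$value, expected,
               tolerance = 1e-12)
  # explicit prior overrides the default 1/m
  e <- entropy(counts, "schurmann_grassberger", prior_N = 0.5)
  tot2 <- n + m * 0.5
  expect_equal(e$value,
               sum((counts + 0.5) * (digamma(tot2 + 1) -
                                       digamma(counts + 0.5 + 1))) / tot2,
               tolerance = 1e-12)
  expect_equal(e$prior_N, 0.5)
})

test_that("single-occupied-bin tables have zero empirical-core entropy", {
  expect_equal(entropy(10)$value, 0)
  expect_equal(entropy(10, "miller_madow")$value, 0)
  expect_equal(entropy(10, "shrinkage")$value, 0)
})

test_that("MI from joint counts: identity, independence, nonnegativity, symmetry", {
  expect_equal(mi_from_counts(diag(5, 2)), log(2), tolerance = 1e-12)
  expect_equal(mi_from_counts(matrix(2, 2, 2)), 0, tolerance = 1e-12)
  set.seed(10)
  for (i in 1:50) {
    joint <- matrix(stats::rpois(6, 3), 2, 3)
    if (sum(joint) == 0) joint[1] <- 1
    expect_gte(mi_from_counts(joint), -1e-12)
    expect_equal(mi_from_counts(joint), mi_from_counts(t(joint)),
                 tolerance = 1e-12)
  }
})

test_that("MI of a variable with itself equals its binned entropy", {
  set.seed(11)
  x <- stats::rnorm(60)
  lab <- discretize(x)$labels
  h <- entropy(tabulate(lab, max(lab)))$value
  expect_equal(mutual_information(x, x), h, tolerance = 1e-12)
})

test_that("empirical MI approaches the Gaussian closed form at large n", {
  set.seed(12)
  xy <- gaussian_pair(10000, 0.9)
  mi <- mutual_information(xy[, 1], xy[, 2])
  expect_equal(mi, -0.5 * log(1 - 0.81), tolerance = 0.15)
})

test_that("empirical MI is monotone in |rho| for Gaussian data", {
  set.seed(13)
  med <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    stats::median(vapply(1:20, function(i) {
      xy <- gaussian_pair(5000, rho)
      mutual_information(xy[, 1], xy[, 2])
    }, 0))
  }, 0)
  expect_true(all(diff(med) > 0))
})
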