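#' @title Structured random correlation models
#' @description Constructors for the three structured correlation models used
#'   in the simulation studies (Toeplitz/autoregressive, hub, and
#'   average/vine), plus the Hardin-style random perturbation, multivariate
#'   Gaussian sampling, and the vine-mean calibration.
#' @name corr_structures
NULL

.new_corr_model <- function(kind, matrix, rho = NA_real_, params = list()) {
  dimnames(matrix) <- NULL
  structure(list(kind = kind, rho = rho, p = nrow(matrix),
                 params = params, matrix = matrix),
            class = "corr_model")
}

#' @export
print.corr_model <- function(x, ...) {
  cat(sprintf("Correlation model: kind = %s, p = %d, rho = %s\n",
              x$kind, x$p, format(x$rho)))
  ev <- eigen(x$matrix, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf("  min eigenvalue = %.3e, mean |off-diagonal| = %.4f\n",
              min(ev), average_abs_correlation(x)))
  invisible(x)
}

#' @export
as.matrix.corr_model <- function(x, ...) x$matrix

.corr_matrix_of <- function(m, arg = "model") {
  w <- if (inherits(m, "corr_model")) m$matrix else m
  if (!is.matrix(w) || !is.numeric(w)) {
    stop(sprintf("'%s' must be a corr_model or numeric matrix", arg))
  }
  w
}

# Eigenvalue-clip + renormalize fallback used whenever a constructed matrix
# is not positive definite; always warns, because downstream entries then
# deviate from the nominal structure.
.ensure_pd <- function(S, floor = 1e-8) {
  ei <- eigen(S, symmetric = TRUE)
  if (min(ei$values) > floor) return(S)
  warning("correlation matrix not positive definite; ",
          "eigenvalues clipped and matrix renormalized")
  v <- pmax(ei$values, floor)
  S2 <- ei$vectors %*% (v * t(ei$vectors))
  d <- sqrt(diag(S2))
  S2 <- S2 / tcrossprod(d)
  diag(S2) <- 1
  (S2 + t(S2)) / 2
}

#' Toeplitz (autoregressive) correlation matrix
#'
#' Entry (i, j) equals \eqn{\rho^{|i-j|}}: adjacent features are most
#' correlated and correlation decays exponentially with index distance.
#' Positive definite for any \eqn{0 \le \rho < 1}.
#'
#' @param p dimension (>= 2).
#' @param rho decay parameter in [0, 1).
#' @return A \code{"corr_model"} object (kind \code{"toeplitz"}).
#' @examples
#' toeplitz_matrix(4, 0.5)$matrix[1, ]  # 1 0.5 0.25 0.125
#' @export
toeplitz_matrix <- function(p, rho) {
  if (!is.numeric(p) || p < 2) stop("'p' must be at least 2")
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("'rho' must be in [0, 1): the limit rho = 1 is singular")
  }
  S <- stats::toeplitz(rho^(0:(p - 1)))
  .new_corr_model("toeplitz", S, rho = rho)
}

#' Randomly perturb a correlation matrix (Hardin-style)
#'
#' Adds noise \eqn{\epsilon (u_i' u_j)} to every off-diagonal entry, where
#' the \eqn{u_i} are independent random unit vectors in \code{edim}
#' dimensions. The diagonal stays exactly 1, and positive definiteness is
#' preserved whenever \code{eps_noise} is below the smallest eigenvalue of
#' the input (the construction shifts the spectrum by at most
#' \code{eps_noise}).
#'
#' @param model a \code{"corr_model"} object.
#' @param eps_noise noise scale (default 0.01); must be smaller than the
#'   smallest eigenvalue of the input matrix.
#' @param edim dimension of the random unit vectors (default 2); small
#'   \code{edim} gives strongly structured noise.
#' @param seed optional integer seed.
#' @return A perturbed \code{"corr_model"} of the same kind.
#' @export
perturb_hardin <- function(model, eps_noise = 0.01, edim = 2, seed = NULL) {
  if (!inherits(model, "corr_model")) stop("'model' must be a corr_model")
  if (eps_noise < 0) stop("'eps_noise' must be nonnegative")
  if (eps_noise == 0) return(model)
  S <- model$matrix
  lam_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (eps_noise >= lam_min) {
    stop(sprintf(
      "'eps_noise' (%g) must be below the smallest eigenvalue (%g)",
      eps_noise, lam_min))
  }
  with_seed(seed, {
    p <- nrow(S)
    U <- matrix(stats::rnorm(edim * p), edim, p)
    U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
    E <- crossprod(U)           # unit diagonal, entries in [-1, 1]
    S2 <- S + eps_noise * (E - diag(p))
    S2 <- .ensure_pd(S2)
    out <- .new_corr_model(model$kind, S2, rho = model$rho,
                           params = c(model$params,
                                      list(eps_noise = eps_noise,
                                           edim = edim)))
    out
  })
}

#' Hub-to-member correlations of one hub group
#'
#' For a group of g features whose first member is the hub, member
#' \eqn{i = 2, \dots, g} correlates with the hub as
#' \deqn{\Sigma_{1,i} = \rho - ((i-2)/(g-2))^\gamma (\rho - \rho_{min}),}
#' i.e. attenuating from exactly \eqn{\rho} (i = 2) down to exactly
#' \eqn{\rho_{min}} (i = g).
#'
#' @param g group size (>= 3).
#' @param rho hub correlation of the closest member, in [0, 1].
#' @param rho_min weakest hub correlation, in [0, rho].
#' @param gamma attenuation exponent (2 = quadratic attenuation).
#' @return Numeric vector of length g - 1.
#' @export
hub_correlations <- function(g, rho, rho_min = 0, gamma = 2) {
  if (g < 3) stop("hub groups need at least 3 members")
  if (rho_min > rho) stop("'rho_min' may not exceed 'rho'")
  if (rho < 0 || rho > 1) stop("'rho' must be in [0, 1]")
  i <- seq.int(2, g)
  rho - ((i - 2) / (g - 2))^gamma * (rho - rho_min)
}

#' Hub correlation structure
#'
#' Block-diagonal correlation model in which each group has one hub feature
#' correlated with the group members with attenuating strength (see
#' \code{\link{hub_correlations}}); non-hub pairs within a group and all
#' cross-group pairs are uncorrelated. Groups are independent. The raw
#' structure can be indefinite for strong \code{rho} together with large
#' groups; in that case eigenvalues are clipped and the matrix renormalized,
#' with a warning (the \code{raw} component keeps the unrepaired matrix).
#'
#' @param group_sizes integer vector of group sizes, each >= 3. The default
#'   c(15, 5) gives two unequal groups of 20 features in total.
#' @param rho strongest hub-member correlation.
#' @inheritParams hub_correlations
#' @return A \code{"corr_model"} (kind \code{"hub"}) whose \code{params}
#'   carry the group sizes and attenuation settings and whose \code{raw}
#'   element is the pre-repair matrix.
#' @export
hub_matrix <- function(group_sizes = c(15, 5), rho, rho_min = 0, gamma = 2) {
  if (any(group_sizes < 3)) stop("every hub group needs at least 3 members")
  p <- sum(group_sizes)
  S <- diag(p)
  off <- 0L
  for (g in group_sizes) {
    r <- hub_correlations(g, rho, rho_min, gamma)
    idx <- off + seq.int(2, g)
    S[off + 1L, idx] <- S[idx, off + 1L] <- r
    off <- off + g
  }
  out <- .new_corr_model("hub", .ensure_pd(S), rho = rho,
                         params = list(group_sizes = group_sizes,
                                       rho_min = rho_min, gamma = gamma))
  out$raw <- S
  out
}

#' Beta shape parameters from mean and variance
#'
#' Inverts the Beta moment relations \eqn{\mu = \alpha/(\alpha+\beta)} and
#' \eqn{\sigma^2 = \alpha\beta / ((\alpha+\beta)^2 (\alpha+\beta+1))}:
#' \eqn{\alpha = \mu(\mu(1-\mu)/\sigma^2 - 1)}, \eqn{\beta = \alpha(1/\mu - 1)}.
#'
#' @param mu mean in (0, 1).
#' @param sigma2 variance; must satisfy \code{sigma2 < mu * (1 - mu)}.
#' @return List with elements \code{alpha} and \code{beta}.
#' @examples
#' beta_shape_from_moments(0.5, 0.1)  # alpha = beta = 0.75
#' @export
beta_shape_from_moments <- function(mu, sigma2) {
  if (!is.numeric(mu) || mu <= 0 || mu >= 1) stop("'mu' must be in (0, 1)")
  if (!is.numeric(sigma2) || sigma2 <= 0 || sigma2 >= mu * (1 - mu)) {
    stop("'sigma2' must be in (0, mu * (1 - mu)) for valid Beta moments")
  }
  alpha <- mu * (mu * (1 - mu) / sigma2 - 1)
  list(alpha = alpha, beta = alpha * (1 / mu - 1))
}

#' Random correlation matrix by the vine method
#'
#' Samples partial correlations from a Beta(\code{alpha}, \code{beta})
#' distribution rescaled from [0, 1] to [-1, 1] and converts them to a full
#' correlation matrix through the recursive C-vine construction, which is
#' positive definite by construction for partial correlations strictly
#' inside (-1, 1).
#'
#' @param p dimension (>= 2).
#' @param alpha,beta Beta shape parameters of the partial-correlation
#'   distribution (see \code{\link{beta_shape_from_moments}}).
#' @param seed optional integer seed.
#' @return A \code{"corr_model"} (kind \code{"average"}); \code{rho} records
#'   the realized mean absolute off-diagonal correlation.
#' @export
vine_matrix <- function(p, alpha, beta, seed = NULL) {
  if (p < 2) stop("'p' must be at least 2")
  with_seed(seed, {
    P <- matrix(0, p, p)
    # clamp away from +/-1: bimodal Beta shapes (alpha, beta < 1) can draw
    # the numeric endpoints, which would make the matrix exactly singular
    pc <- 2 * stats::rbeta(p * (p - 1) / 2, alpha, beta) - 1
    P[upper.tri(P)] <- pmin(pmax(pc, -1 + 1e-8), 1 - 1e-8)
    S <- diag(p)
    for (k in seq_len(p - 1)) {
      for (i in seq.int(k + 1, p)) {
        r <- P[k, i]
        if (k > 1) {
          for (l in seq.int(k - 1, 1)) {
            r <- r * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) + P[l, i] * P[l, k]
          }
        }
        S[k, i] <- S[i, k] <- r
      }
    }
    # near-singular draws (many extreme partials) can lose definiteness to
    # floating point; a ridge of order 1e-9 restores it without touching
    # the correlation structure at any statistically relevant digit
    lam <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (lam <= 1e-10) {
      delta <- 1e-9 - min(lam, 0)
      S <- (S + delta * diag(p)) / (1 + delta)
      diag(S) <- 1
    }
    m <- .new_corr_model("average", S,
                         params = list(alpha = alpha, beta = beta))
    m$rho <- average_abs_correlation(m)
    m
  })
}

#' Mean absolute off-diagonal correlation
#'
#' \eqn{\frac{2}{p^2 - p} \sum_{i > j} |\rho_{ij}|}, the summary the
#' average-correlation (vine) model is calibrated against.
#'
#' @param model a \code{"corr_model"} or square correlation matrix.
#' @return Nonnegative scalar.
#' @export
average_abs_correlation <- function(model) {
  m <- .corr_matrix_of(model)
  mean(abs(m[upper.tri(m)]))
}

#' Calibrate the vine Beta mean to a target average correlation
#'
#' Finds the Beta mean \code{mu} (at fixed variance \code{sigma2}) such that
#' the Monte-Carlo mean of \code{\link{average_abs_correlation}} over
#' \code{n_matrices} vine draws matches \code{target_rho}. The search runs
#' over the monotone-increasing branch \code{mu} in [0.5, mu_max) of the
#' response (the response is U-shaped in \code{mu} with its minimum at 0.5;
#' see the package vignette). Common random numbers make the Monte-Carlo
#' objective deterministic, so a bracketed root search applies.
#'
#' Targets slightly below the branch floor return \code{mu = 0.5} with a
#' warning; targets more than 0.05 below it raise a calibration error.
#'
#' @param target_rho target mean absolute correlation in (0, 1).
#' @param p matrix dimension used during calibration.
#' @param sigma2 Beta variance (fixed during calibration).
#' @param n_matrices Monte-Carlo draws per objective evaluation.
#' @param seed integer seed for the common-random-number objective.
#' @param tol calibration tolerance on the average correlation scale.
#' @return The calibrated \code{mu} (scalar).
#' @export
calibrate_mu <- function(target_rho, p = 20, sigma2 = 0.1, n_matrices = 30,
                         seed = 1, tol = 0.02) {
  if (target_rho <= 0 || target_rho >= 1) {
    stop("'target_rho' must be in (0, 1)")
  }
  mu_max <- 0.5 + sqrt(max(0, 0.25 - sigma2))  # moment-validity bound
  hi <- mu_max - 1e-4
  f <- function(mu) {
    sh <- beta_shape_from_moments(mu, sigma2)
    vals <- with_seed(seed, vapply(seq_len(n_matrices), function(b)
      average_abs_correlation(vine_matrix(p, sh$alpha, sh$beta)), 0))
    mean(vals) - target_rho
  }
  f_lo <- f(0.5)
  if (f_lo >= 0) {
    if (f_lo > 0.05) {
      stop(sprintf(paste0(
        "calibration target %.3f not achievable at sigma2 = %g ",
        "(minimum attainable average correlation is %.3f at mu = 0.5)"),
        target_rho, sigma2, f_lo + target_rho))
    }
    warning("target at or below the attainable floor; returning mu = 0.5")
    return(0.5)
  }
  if (f(hi) < 0) stop("calibration target not bracketed on (0.5, mu_max)")
  stats::uniroot(f, c(0.5, hi), tol = tol / 10)$root
}

#' Sample multivariate Gaussian data from a correlation model
#'
#' Draws n samples from N(0, Sigma) with Sigma the model's correlation
#' matrix (all variances 1), via \code{MASS::mvrnorm}.
#'
#' @param model a \code{"corr_model"} or positive-definite correlation
#'   matrix.
#' @param n number of samples.
#' @param seed optional integer seed.
#' @return n x p numeric matrix with columns \code{V1..Vp}.
#' @export
sample_gaussian <- function(model, n, seed = NULL) {
  S <- .corr_matrix_of(model)
  .check_square_symmetric(S, "model")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("correlation matrix is not positive definite")
  }
  with_seed(seed, {
    x <- MASS::mvrnorm(n, mu = rep(0, nrow(S)), Sigma = S)
    x <- matrix(x, nrow = n)  # mvrnorm drops dims when n = 1
    colnames(x) <- paste0("V", seq_len(ncol(x)))
    x
  })
}

#' Export / import a correlation model matrix as headered CSV
#'
#' @param model a \code{"corr_model"} or matrix.
#' @param path file path.
#' @return \code{write_corr_matrix} returns the path invisibly;
#'   \code{read_corr_matrix} returns the matrix.
#' @export
write_corr_matrix <- function(model, path) {
  m <- .corr_matrix_of(model)
  colnames(m) <- paste0("V", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corr_matrix
#' @export
read_corr_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  dimnames(m) <- NULL
  m
}
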