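#' Pearson correlation between two variables
#'
#' Thin validated wrapper around \code{stats::cor} enforcing the contract
#' used throughout the package: equal lengths of at least 3 and nonzero
#' variance in both inputs.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in [-1, 1].
#' @export
pearson_cor <- function(x, y) {
  .check_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero-variance input")
  }
  stats::cor(x, y)
}

#' Spearman rank correlation between two variables
#'
#' Equals the Pearson correlation of average ranks (ties receive their
#' average rank).
#'
#' @inheritParams pearson_cor
#' @return Correlation in [-1, 1].
#' @export
spearman_cor <- function(x, y) {
  .check_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero-variance input")
  }
  stats::cor(x, y, method = "spearman")
}

.check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  invisible(NULL)
}

# Symmetric MI weight matrix from an integer label matrix L (n x p), with
# per-column bin counts nb. Marginal entropies are computed on the full bin
# grid; the joint table for a pair is the full nb_i x nb_j grid.
.mi_weights <- function(L, nb, hfun) {
  n <- nrow(L)
  p <- ncol(L)
  Hm <- numeric(p)
  for (i in seq_len(p)) Hm[i] <- hfun(tabulate(L[, i], nb[i]), n)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    Li <- L[, i]
    nbi <- nb[i]
    for (j in seq.int(i + 1L, p)) {
      jt <- tabulate(Li + nbi * (L[, j] - 1L), nbi * nb[j])
      W[i, j] <- W[j, i] <- Hm[i] + Hm[j] - hfun(jt, n)
    }
  }
  diag(W) <- Hm
  W
}

# Correlation weight matrix with zero-variance columns forced to weight 0.
.cor_weights <- function(x, method) {
  W <- suppressWarnings(stats::cor(x, method = method))
  W[!is.finite(W)] <- 0
  diag(W) <- 1
  W
}

#' Build a weighted association (adjacency) matrix
#'
#' Computes all pairwise associations between the columns of a samples x
#' features matrix using Pearson correlation, Spearman correlation, or
#' mutual information under one of four entropy estimators. The result is the
#' weighted adjacency matrix of the feature association network.
#'
#' Constant (zero-variance) features do not abort the computation: their
#' weights against every partner are set to 0 and a warning names them. The
#' diagonal (1 for correlations, the marginal entropy for MI) is ignored by
#' downstream connectivity computations.
#'
#' @param x numeric matrix or data frame, samples in rows, features in
#'   columns (n >= 3, p >= 2).
#' @param measure \code{"pearson"}, \code{"spearman"} or \code{"mi"}.
#' @param estimator entropy estimator for \code{measure = "mi"}.
#' @inheritParams mutual_information
#' @return Object of class \code{"assoc_matrix"}: list with \code{weights}
#'   (p x p symmetric matrix with feature dimnames), \code{measure},
#'   \code{estimator} (MI only) and \code{features}.
#' @examples
#' X <- cbind(a = c(1, 2, 4), b = c(1, 3, 3))
#' association_matrix(X)$weights
#' @export
association_matrix <- function(x,
                               measure = c("pearson", "spearman", "mi"),
                               estimator = c("empirical", "miller_madow",
                                             "shrinkage",
                                             "schurmann_grassberger"),
                               n_bins = NULL,
                               scheme = c("equal_frequency", "equal_width"),
                               prior_N = NULL) {
  measure <- match.arg(measure)
  estimator <- match.arg(estimator)
  scheme <- match.arg(scheme)
  x <- .as_feature_matrix(x)
  if (ncol(x) < 2) stop("need at least 2 features")
  if (nrow(x) < 3) stop("need at least 3 samples")

  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning(sprintf("constant features set to zero weight: %s",
                    paste(colnames(x)[const], collapse = ", ")))
  }

  if (measure == "mi") {
    disc <- lapply(seq_len(ncol(x)), function(j)
      discretize(x[, j], n_bins = n_bins, scheme = scheme))
    L <- vapply(disc, `[[`, integer(nrow(x)), "labels")
    nb <- vapply(disc, `[[`, integer(1), "n_bins")
    nb[const] <- 1L  # constant columns occupy one bin
    W <- .mi_weights(L, nb, .entropy_fun(estimator, prior_N))
  } else {
    W <- .cor_weights(x, measure)
  }
  if (any(const)) {
    W[const, ] <- 0
    W[, const] <- 0
    diag(W)[const] <- if (measure == "mi") 0 else 1
  }
  dimnames(W) <- list(colnames(x), colnames(x))
  structure(list(weights = W, measure = measure,
                 estimator = if (measure == "mi") estimator else NULL,
                 features = colnames(x)),
            class = "assoc_matrix")
}

#' @export
as.matrix.assoc_matrix <- function(x, ...) x$weights

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("Association matrix: %d features, measure = %s%s\n",
              length(x$features), x$measure,
              if (is.null(x$estimator)) "" else
                paste0(" (", x$estimator, ")")))
  w <- x$weights[seq_len(min(6, nrow(x$weights))),
                 seq_len(min(6, ncol(x$weights))), drop = FALSE]
  print(round(w, 3))
  if (nrow(x$weights) > 6) cat("...\n")
  invisible(x)
}
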