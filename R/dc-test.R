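#' Permutation test for differential connectivity
#'
#' The central fitting function of the package. Given two samples x features
#' matrices measured under two conditions, it builds the weighted association
#' network of each group (correlation or mutual information), computes each
#' feature's connectivity \eqn{\chi_i} (sum of absolute edge weights) and the
#' differential connectivity \eqn{\Delta\chi_i = \chi_i^{G1} - \chi_i^{G2}},
#' and assesses significance against a column-permutation null.
#'
#' For each of \code{n_perm} replicates, every column of both matrices is
#' independently permuted (destroying all associations while preserving each
#' feature's marginal distribution) and the permuted differential
#' connectivity is recorded, giving a per-feature null distribution
#' \eqn{D_i}. The p-value is
#' \deqn{P_i = (1 + \#\{|D_i| > |\Delta\chi_i|\}) / N_{perm},}
#' clipped to 1; ties count as non-exceeding, and the smallest attainable
#' p-value is \eqn{1/N_{perm}}. The comparison is two-sided on the magnitude
#' because \eqn{\Delta\chi} can take either sign. A feature is flagged
#' significant when its (optionally BH-adjusted) p-value is below
#' \code{alpha}.
#'
#' For \code{measure = "mi"} the columns are discretized once per group and
#' permutations act on the bin labels; this is equivalent to permuting the
#' raw columns (binning is invariant under reordering) and avoids re-binning
#' in the permutation loop. Marginal entropies are likewise permutation
#' invariant and cached.
#'
#' @param x1,x2 numeric matrices (samples x features) for group 1 and
#'   group 2, with matching feature columns; each needs at least 3 rows.
#' @param measure association measure: \code{"pearson"}, \code{"spearman"}
#'   or \code{"mi"}.
#' @param estimator entropy estimator when \code{measure = "mi"}.
#' @param n_perm number of permutation replicates (default 1000).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed making the result fully reproducible; the
#'   caller's RNG state is restored afterwards. \code{NULL} uses the ambient
#'   RNG stream.
#' @param p_adjust \code{"none"} (raw permutation p-values, the default) or
#'   \code{"BH"} for Benjamini-Hochberg adjustment of the significance flag.
#' @inheritParams mutual_information
#' @return Object of class \code{"dc_test"}. Component \code{table} is a
#'   data frame with one row per feature: \code{feature}, \code{chi_g1},
#'   \code{chi_g2}, \code{delta_chi}, \code{p_value} (and
#'   \code{p_adjusted} if requested) and \code{significant}. Supporting
#'   components record the measure, estimator, permutation configuration and
#'   group sizes. Methods: \code{print}, \code{summary}, \code{coef} (the
#'   \eqn{\Delta\chi} vector) and \code{plot}.
#' @examples
#' set.seed(1)
#' x1 <- matrix(rnorm(300), 50, 6)
#' x2 <- matrix(rnorm(300), 50, 6)
#' fit <- dc_test(x1, x2, n_perm = 100, seed = 7)
#' summary(fit)
#' @export
dc_test <- function(x1, x2,
                    measure = c("pearson", "spearman", "mi"),
                    estimator = c("empirical", "miller_madow", "shrinkage",
                                  "schurmann_grassberger"),
                    n_perm = 1000, alpha = 0.05, seed = NULL,
                    n_bins = NULL, scheme = c("equal_frequency", "equal_width"),
                    prior_N = NULL,
                    p_adjust = c("none", "BH")) {
  measure <- match.arg(measure)
  estimator <- match.arg(estimator)
  scheme <- match.arg(scheme)
  p_adjust <- match.arg(p_adjust)
  x1 <- .as_feature_matrix(x1, "x1")
  x2 <- .as_feature_matrix(x2, "x2")
  if (ncol(x1) != ncol(x2)) stop("'x1' and 'x2' must have the same features")
  if (!identical(colnames(x1), colnames(x2))) {
    stop("feature names of 'x1' and 'x2' do not match")
  }
  if (nrow(x1) < 3 || nrow(x2) < 3) stop("each group needs at least 3 samples")
  if (!is.numeric(n_perm) || n_perm < 1) stop("'n_perm' must be >= 1")
  n_perm <- as.integer(n_perm)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  p <- ncol(x1)

  with_seed(seed, {
    if (measure == "mi") {
      hfun <- .entropy_fun(estimator, prior_N)
      st1 <- .mi_state(x1, n_bins, scheme)
      st2 <- .mi_state(x2, n_bins, scheme)
      chi_fun <- function(s, perm) {
        L <- if (perm) apply(s$L, 2, sample) else s$L
        colSums(abs(.mi_weights_cached(L, s$nb, s$Hm, hfun))) -
          abs(s$Hm)  # remove diagonal contribution
      }
      g1 <- st1
      g2 <- st2
      # marginal entropies (invariant under permutation)
      g1$Hm <- vapply(seq_len(p), function(i)
        hfun(tabulate(g1$L[, i], g1$nb[i]), nrow(g1$L)), 0)
      g2$Hm <- vapply(seq_len(p), function(i)
        hfun(tabulate(g2$L[, i], g2$nb[i]), nrow(g2$L)), 0)
    } else {
      # Spearman = Pearson on average ranks; rank once, permutations of the
      # ranked columns are the ranks of permuted columns.
      g1 <- list(M = if (measure == "spearman") apply(x1, 2, rank) else x1)
      g2 <- list(M = if (measure == "spearman") apply(x2, 2, rank) else x2)
      chi_fun <- function(s, perm) {
        M <- if (perm) apply(s$M, 2, sample) else s$M
        C <- .cor_weights(M, "pearson")
        colSums(abs(C)) - 1
      }
    }

    const1 <- apply(x1, 2, function(v) diff(range(v)) == 0)
    const2 <- apply(x2, 2, function(v) diff(range(v)) == 0)
    if (any(const1 | const2)) {
      warning(sprintf("constant features carry zero weight: %s",
                      paste(colnames(x1)[const1 | const2], collapse = ", ")))
    }

    chi1 <- chi_fun(g1, perm = FALSE)
    chi2 <- chi_fun(g2, perm = FALSE)
    chi1[const1] <- 0
    chi2[const2] <- 0
    delta <- chi1 - chi2

    exceed <- integer(p)
    for (b in seq_len(n_perm)) {
      d_perm <- chi_fun(g1, perm = TRUE) - chi_fun(g2, perm = TRUE)
      exceed <- exceed + (abs(d_perm) > abs(delta))
    }
    p_value <- pmin(1, (1 + exceed) / n_perm)
    p_adj <- if (p_adjust == "BH") stats::p.adjust(p_value, "BH") else NULL
    significant <- (p_adj %||% p_value) < alpha

    tab <- data.frame(feature = colnames(x1),
                      chi_g1 = unname(chi1),
                      chi_g2 = unname(chi2),
                      delta_chi = unname(delta),
                      p_value = unname(p_value),
                      stringsAsFactors = FALSE)
    if (!is.null(p_adj)) tab$p_adjusted <- unname(p_adj)
    tab$significant <- unname(significant)

    structure(list(table = tab, measure = measure,
                   estimator = if (measure == "mi") estimator else NULL,
                   n_perm = n_perm, alpha = alpha, seed = seed,
                   p_adjust = p_adjust,
                   n1 = nrow(x1), n2 = nrow(x2), p = p),
              class = "dc_test")
  })
}

.mi_state <- function(x, n_bins, scheme) {
  disc <- lapply(seq_len(ncol(x)), function(j)
    discretize(x[, j], n_bins = n_bins, scheme = scheme))
  list(L = vapply(disc, `[[`, integer(nrow(x)), "labels"),
       nb = vapply(disc, `[[`, integer(1), "n_bins"))
}

# MI weight matrix with precomputed marginal entropies Hm.
.mi_weights_cached <- function(L, nb, Hm, hfun) {
  n <- nrow(L)
  p <- ncol(L)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    Li <- L[, i]
    nbi <- nb[i]
    Hi <- Hm[i]
    for (j in seq.int(i + 1L, p)) {
      jt <- tabulate(Li + nbi * (L[, j] - 1L), nbi * nb[j])
      W[i, j] <- W[j, i] <- Hi + Hm[j] - hfun(jt, n)
    }
  }
  diag(W) <- Hm
  W
}

#' Independently permute each column of a matrix
#'
#' Each column's values are shuffled with an independent random order,
#' preserving every marginal distribution but destroying all between-column
#' association. This is the resampling step of the differential-connectivity
#' null.
#'
#' @param x numeric matrix.
#' @param seed optional integer seed.
#' @return Matrix of the same dimensions and dimnames.
#' @export
permute_columns <- function(x, seed = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("'x' must be a matrix")
  if (nrow(x) < 2) return(x)
  with_seed(seed, {
    out <- apply(x, 2, sample)
    dimnames(out) <- dimnames(x)
    out
  })
}

#' @export
print.dc_test <- function(x, ...) {
  cat(sprintf(
    "Differential connectivity test (%s%s)\n",
    x$measure,
    if (is.null(x$estimator)) "" else paste0(", ", x$estimator)))
  cat(sprintf("  groups: n1 = %d, n2 = %d, features = %d\n",
              x$n1, x$n2, x$p))
  cat(sprintf("  permutations: %d, alpha = %g%s\n", x$n_perm, x$alpha,
              if (x$p_adjust == "BH") " (BH adjusted)" else ""))
  cat(sprintf("  significant features: %d / %d\n",
              sum(x$table$significant), x$p))
  invisible(x)
}

#' @export
summary.dc_test <- function(object, ...) {
  tab <- object$table
  structure(list(fit = object,
                 n_significant = sum(tab$significant),
                 top = tab[order(tab$p_value,
                                 -abs(tab$delta_chi)), , drop = FALSE]),
            class = "summary.dc_test")
}

#' @export
print.summary.dc_test <- function(x, ...) {
  print(x$fit)
  cat("\nFeatures ordered by significance:\n")
  print(utils::head(x$top, 10), row.names = FALSE)
  if (nrow(x$top) > 10) cat("...\n")
  invisible(x)
}

#' @export
coef.dc_test <- function(object, ...) {
  stats::setNames(object$table$delta_chi, object$table$feature)
}

#' @export
plot.dc_test <- function(x, ...) {
  tab <- x$table
  cols <- ifelse(tab$significant, "firebrick", "grey60")
  graphics::barplot(tab$delta_chi, names.arg = tab$feature, col = cols,
                    border = NA, las = 2,
                    ylab = expression(Delta * chi),
                    main = sprintf("Differential connectivity (%s)",
                                   x$measure), ...)
  graphics::abline(h = 0)
  invisible(x)
}
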