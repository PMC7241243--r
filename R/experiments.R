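#' @title Scripted simulation experiments
#' @description Drivers reproducing the package's simulation designs at
#'   configurable scale: type-I-error calibration under the global null,
#'   power against structured correlation models, and power on kinetic-model
#'   populations, plus the two-measure overlap summary.
#' @name experiments
NULL

.measure_label <- function(measure, estimator) {
  ifelse(measure == "mi", paste0("mi_", estimator), measure)
}

.new_report <- function(df, kind) {
  structure(df, class = c("dc_experiment", "data.frame"), kind = kind)
}

#' @export
print.dc_experiment <- function(x, ...) {
  cat(sprintf("Differential connectivity experiment report (%s)\n",
              attr(x, "kind")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Type-I-error calibration under the global null
#'
#' Both groups are drawn independently from N(0, I_p), so no feature is
#' differentially connected; the fraction of features declared significant
#' estimates the test's type-I error, which should sit at the nominal alpha
#' for every sample size and measure.
#'
#' @param n_values vector of per-group sample sizes.
#' @param p number of features.
#' @param replicates simulation replicates per cell.
#' @param measures association measures to test.
#' @param estimator entropy estimator for MI measures.
#' @param n_perm,alpha permutation-test settings.
#' @param seed master seed; every source of randomness in the experiment
#'   flows from it.
#' @return A \code{"dc_experiment"} data frame with one row per
#'   (n, measure): columns \code{n}, \code{measure}, \code{replicates},
#'   \code{type1_error} (mean fraction significant). Per-replicate rates are
#'   kept in \code{attr(, "detail")}.
#' @export
type1_experiment <- function(n_values = c(25, 100, 500), p = 20,
                             replicates = 10, measures = "pearson",
                             estimator = "empirical", n_perm = 200,
                             alpha = 0.05, seed = NULL) {
  with_seed(seed, {
    detail <- list()
    for (n in n_values) {
      for (ms in measures) {
        rates <- vapply(seq_len(replicates), function(r) {
          x1 <- matrix(stats::rnorm(n * p), n, p)
          x2 <- matrix(stats::rnorm(n * p), n, p)
          fit <- dc_test(x1, x2, measure = ms, estimator = estimator,
                         n_perm = n_perm, alpha = alpha)
          mean(fit$table$significant)
        }, 0)
        detail[[length(detail) + 1L]] <-
          data.frame(n = n, measure = .measure_label(ms, estimator),
                     replicate = seq_len(replicates), rate = rates)
      }
    }
    detail <- do.call(rbind, detail)
    agg <- stats::aggregate(rate ~ n + measure, detail, mean)
    out <- data.frame(n = agg$n, measure = agg$measure,
                      replicates = replicates, type1_error = agg$rate)
    out <- out[order(out$measure, out$n), ]
    rep_out <- .new_report(out, "type1")
    attr(rep_out, "detail") <- detail
    rep_out
  })
}

.structure_model <- function(structure, rho, p, perturb, mu_cache,
                             sigma2 = 0.1) {
  switch(structure,
    toeplitz = {
      m <- toeplitz_matrix(p, min(rho, 0.99))
      # the Hardin perturbation needs eps below the smallest eigenvalue;
      # near-singular matrices (rho -> 1) are used unperturbed
      if (perturb && rho > 0) {
        tryCatch(perturb_hardin(m), error = function(e) m)
      } else {
        m
      }
    },
    hub = {
      gs <- if (p == 20) c(15, 5) else c(p - max(3, floor(p / 4)),
                                         max(3, floor(p / 4)))
      suppressWarnings(hub_matrix(gs, rho))
    },
    average = {
      sh <- beta_shape_from_moments(mu_cache[[as.character(rho)]], sigma2)
      vine_matrix(p, sh$alpha, sh$beta)
    },
    stop(sprintf("unknown structure '%s'", structure))
  )
}

#' Power experiment against structured correlation models
#'
#' Group 1 is sampled from a structured correlation model (Toeplitz, hub or
#' vine/average) and group 2 from uncorrelated N(0, I) of the same size, so
#' every feature is differentially connected whenever rho > 0; the median
#' number of significant features over replicates measures power. Set
#' \code{contrast = "same_structure"} to instead draw both groups from the
#' structured model (a global-null configuration).
#'
#' For the Toeplitz structure each replicate perturbs the matrix with
#' Hardin-style noise (eps 0.01, edim 2) before sampling; the average
#' structure calibrates its Beta mean per rho once and then draws a fresh
#' vine matrix per replicate.
#'
#' @param structure \code{"toeplitz"}, \code{"hub"} or \code{"average"}.
#' @param rho_values correlation strengths.
#' @param n_values per-group sample sizes.
#' @inheritParams type1_experiment
#' @param contrast comparison group: uncorrelated Gaussian (default) or a
#'   second draw from the same structured model.
#' @param perturb apply the Hardin perturbation to Toeplitz matrices.
#' @return A \code{"dc_experiment"} data frame keyed by (structure, rho, n,
#'   measure) with the median significant-feature count per cell;
#'   per-replicate counts in \code{attr(, "detail")}.
#' @export
power_experiment <- function(structure = "toeplitz",
                             rho_values = c(0.3, 0.6, 0.9),
                             n_values = c(50, 100, 500), p = 20,
                             measures = "pearson", estimator = "empirical",
                             replicates = 10, n_perm = 200, alpha = 0.05,
                             contrast = c("uncorrelated", "same_structure"),
                             perturb = TRUE, seed = NULL) {
  contrast <- match.arg(contrast)
  with_seed(seed, {
    mu_cache <- list()
    if (structure == "average") {
      for (rho in rho_values) {
        mu_cache[[as.character(rho)]] <- calibrate_mu(rho, p = p)
      }
    }
    detail <- list()
    for (rho in rho_values) {
      for (n in n_values) {
        for (ms in measures) {
          counts <- vapply(seq_len(replicates), function(r) {
            model <- .structure_model(structure, rho, p, perturb, mu_cache)
            x1 <- sample_gaussian(model, n)
            x2 <- if (contrast == "uncorrelated") {
              matrix(stats::rnorm(n * p), n, p)
            } else {
              sample_gaussian(model, n)
            }
            colnames(x2) <- colnames(x1)
            fit <- dc_test(x1, x2, measure = ms, estimator = estimator,
                           n_perm = n_perm, alpha = alpha)
            sum(fit$table$significant)
          }, 0)
          detail[[length(detail) + 1L]] <-
            data.frame(structure = structure, rho = rho, n = n,
                       measure = .measure_label(ms, estimator),
                       replicate = seq_len(replicates), count = counts)
        }
      }
    }
    detail <- do.call(rbind, detail)
    agg <- stats::aggregate(count ~ structure + rho + n + measure, detail,
                            stats::median)
    out <- data.frame(agg[c("structure", "rho", "n", "measure")],
                      replicates = replicates, median_significant = agg$count)
    out <- out[order(out$measure, out$rho, out$n), ]
    rep_out <- .new_report(out, "power")
    attr(rep_out, "detail") <- detail
    rep_out
  })
}

#' Power experiment on kinetic-model populations
#'
#' Group 2 is a population simulated from the kinetic model at epsilon = 1
#' (the unperturbed reference); group 1 is simulated at each grid epsilon.
#' The median number of significant features per cell summarizes how
#' detectable the global kinetic perturbation is for each association
#' measure.
#'
#' @param epsilon_values perturbation multipliers for group 1.
#' @param n_values population sizes per group.
#' @param model a \code{"kinetic_model"} (default: the built-in
#'   oscillator).
#' @inheritParams type1_experiment
#' @inheritParams generate_group
#' @return A \code{"dc_experiment"} data frame keyed by (epsilon, n,
#'   measure); per-replicate counts in \code{attr(, "detail")}.
#' @export
kinetic_experiment <- function(epsilon_values = c(1 / 3, 1, 3),
                               n_values = c(50, 100),
                               model = oscillator_model(),
                               measures = "pearson", estimator = "empirical",
                               replicates = 5, n_perm = 200, alpha = 0.05,
                               jitter_fraction = 0.1, t_sample = 20,
                               seed = NULL) {
  with_seed(seed, {
    detail <- list()
    for (eps in epsilon_values) {
      for (n in n_values) {
        for (r in seq_len(replicates)) {
          x1 <- generate_group(model, n, epsilon = eps,
                               jitter_fraction = jitter_fraction,
                               t_sample = t_sample)
          x2 <- generate_group(model, n, epsilon = 1,
                               jitter_fraction = jitter_fraction,
                               t_sample = t_sample)
          for (ms in measures) {
            fit <- suppressWarnings(
              dc_test(x1, x2, measure = ms, estimator = estimator,
                      n_perm = n_perm, alpha = alpha))
            detail[[length(detail) + 1L]] <-
              data.frame(epsilon = eps, n = n,
                         measure = .measure_label(ms, estimator),
                         replicate = r, count = sum(fit$table$significant))
          }
        }
      }
    }
    detail <- do.call(rbind, detail)
    agg <- stats::aggregate(count ~ epsilon + n + measure, detail,
                            stats::median)
    out <- data.frame(agg[c("epsilon", "n", "measure")],
                      replicates = replicates, median_significant = agg$count)
    out <- out[order(out$measure, out$epsilon, out$n), ]
    rep_out <- .new_report(out, "kinetic")
    attr(rep_out, "detail") <- detail
    rep_out
  })
}

#' Overlap of significant features between two test results
#'
#' Set arithmetic on the significance flags of two differential-connectivity
#' results over the same features, the summary used to compare association
#' measures: how many features each measure finds exclusively and how many
#' both find.
#'
#' @param result_a,result_b \code{"dc_test"} objects over identical
#'   feature sets.
#' @return Data frame with one row: \code{only_in_a}, \code{only_in_b},
#'   \code{overlap}, \code{total_a}, \code{total_b}. The identity
#'   \code{total_a = only_in_a + overlap} always holds.
#' @export
overlap_summary <- function(result_a, result_b) {
  if (!inherits(result_a, "dc_test") || !inherits(result_b, "dc_test")) {
    stop("inputs must be dc_test results")
  }
  fa <- result_a$table$feature
  fb <- result_b$table$feature
  if (!identical(sort(fa), sort(fb))) {
    stop("the two results cover different feature sets")
  }
  sig_a <- fa[result_a$table$significant]
  sig_b <- fb[result_b$table$significant]
  data.frame(only_in_a = length(setdiff(sig_a, sig_b)),
             only_in_b = length(setdiff(sig_b, sig_a)),
             overlap = length(intersect(sig_a, sig_b)),
             total_a = length(sig_a),
             total_b = length(sig_b))
}
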