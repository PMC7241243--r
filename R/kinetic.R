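#' Define a kinetic ODE model
#'
#' A kinetic model bundles species names, rate constants \code{k}, Michaelis
#' constants \code{Km}, initial concentrations \code{c0} and a right-hand
#' side evaluator. Population sampling (see \code{\link{generate_group}})
#' jitters these parameters per individual and scales them globally by a
#' perturbation multiplier epsilon.
#'
#' @param species character vector of species names (the features of the
#'   generated data).
#' @param k nonnegative rate constants.
#' @param Km nonnegative Michaelis constants (may be empty).
#' @param c0 nonnegative initial concentrations, one per species.
#' @param rhs function \code{(t, state, k, Km)} returning the vector of
#'   concentration derivatives; must be defined for nonnegative states.
#' @return Object of class \code{"kinetic_model"}.
#' @seealso \code{\link{oscillator_model}} for the packaged example model.
#' @export
kinetic_model <- function(species, k, Km, c0, rhs) {
  if (!is.character(species) || length(species) < 1) {
    stop("'species' must be a character vector")
  }
  if (length(c0) != length(species)) {
    stop("'c0' needs one entry per species")
  }
  if (any(k < 0) || any(Km < 0) || any(c0 < 0)) {
    stop("kinetic parameters must be nonnegative")
  }
  if (!is.function(rhs)) stop("'rhs' must be a function(t, state, k, Km)")
  structure(list(species = species, k = as.numeric(k), Km = as.numeric(Km),
                 c0 = stats::setNames(as.numeric(c0), species), rhs = rhs),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat(sprintf("Kinetic model: %d species, %d rate constants, %d Michaelis constants\n",
              length(x$species), length(x$k), length(x$Km)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in five-species oscillator model (synthetic)
#'
#' A synthetic negative-feedback oscillator packaged as the default kinetic
#' model for population simulation: an autocatalytic two-species core
#' (mass-action Brusselator) driving a linear two-step cascade and a fifth
#' species with bilinear production and saturable (Michaelis-Menten)
#' removal. All core reaction terms are first order in their rate constants
#' with unscaled states, so the global perturbation multiplier epsilon acts
#' (to leading order) as a time rescaling: epsilon > 1 speeds the
#' oscillation up, epsilon < 1 slows and flattens it within a fixed
#' observation window, while limit-cycle amplitudes stay comparable.
#'
#' This model is a stand-in constructed for testability; it is not a fit to
#' any published reaction network.
#'
#' @return A \code{"kinetic_model"} with species \code{M1..M5}; \code{M1},
#'   \code{M2} and \code{M5} have nonzero initial concentrations.
#' @examples
#' mod <- oscillator_model()
#' traj <- simulate_trajectory(mod, times = seq(0, 100, 0.5))
#' @export
oscillator_model <- function() {
  rhs <- function(t, state, k, Km) {
    s <- pmax(state, 0)
    c(k[1] - k[2] * s[1] - k[3] * s[1] + k[4] * s[1]^2 * s[2],
      k[3] * s[1] - k[4] * s[1]^2 * s[2],
      k[5] * s[2] - k[6] * s[3],
      k[7] * s[3] - k[8] * s[4],
      k[9] * s[1] * s[4] - k[10] * s[5] / (Km[1] + s[5]))
  }
  kinetic_model(species = paste0("M", 1:5),
                k = c(1, 1, 3, 1, 0.4, 0.4, 0.4, 0.4, 0.2, 1),
                Km = 0.05,
                c0 = c(1.2, 2.5, 0, 0, 0.1),
                rhs = rhs)
}

#' Draw one individual's jittered parameter set
#'
#' Every rate constant, Michaelis constant and nonzero initial concentration
#' is drawn independently from a uniform distribution centered on its base
#' value: U((1 - f) * base, (1 + f) * base) with f the jitter fraction
#' (default 0.10, i.e. base +/- 10\%). Zero-valued initial concentrations
#' stay exactly zero.
#'
#' @param model a \code{"kinetic_model"}.
#' @param jitter_fraction relative half-width f in [0, 1).
#' @param seed optional integer seed.
#' @return List with jittered \code{k}, \code{Km}, \code{c0}.
#' @export
draw_individual <- function(model, jitter_fraction = 0.1, seed = NULL) {
  if (!inherits(model, "kinetic_model")) stop("'model' must be a kinetic_model")
  f <- jitter_fraction
  if (!is.numeric(f) || f < 0 || f >= 1) {
    stop("'jitter_fraction' must be in [0, 1)")
  }
  with_seed(seed, {
    jit <- function(v) v * stats::runif(length(v), 1 - f, 1 + f)
    c0 <- model$c0
    nz <- c0 > 0
    c0[nz] <- jit(c0[nz])
    list(k = jit(model$k), Km = jit(model$Km), c0 = c0)
  })
}

#' Apply the global perturbation multiplier
#'
#' Multiplies every rate constant, Michaelis constant and initial
#' concentration by epsilon, the scaling that defines the perturbed
#' condition (group 1) relative to the unperturbed model (epsilon = 1).
#' Composition is multiplicative: applying epsilon1 then epsilon2 equals
#' applying epsilon1 * epsilon2.
#'
#' @param pars parameter list with \code{k}, \code{Km}, \code{c0} (as
#'   returned by \code{\link{draw_individual}}).
#' @param epsilon positive multiplier.
#' @return Scaled parameter list.
#' @export
apply_perturbation <- function(pars, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop("'epsilon' must be a single positive number")
  }
  list(k = epsilon * pars$k, Km = epsilon * pars$Km, c0 = epsilon * pars$c0)
}

.ode_solve <- function(model, pars, times, rtol, atol) {
  func <- function(t, y, parms) list(model$rhs(t, y, parms$k, parms$Km))
  out <- try(deSolve::ode(y = stats::setNames(pars$c0, model$species),
                          times = times, func = func, parms = pars,
                          rtol = rtol, atol = atol, maxsteps = 1e5),
             silent = TRUE)
  istate <- attr(out, "istate")
  if (inherits(out, "try-error") || !all(is.finite(out)) ||
      nrow(out) < length(times) ||
      (!is.null(istate) && istate[1] < 0)) {
    stop("ODE integration failed for the supplied parameters")
  }
  out
}

#' Simulate a concentration trajectory
#'
#' Integrates the model ODEs (stiff-capable \code{deSolve::ode}, default
#' lsoda) over the requested time grid.
#'
#' @param model a \code{"kinetic_model"}.
#' @param pars parameter list (\code{k}, \code{Km}, \code{c0}); defaults to
#'   the model's base parameters.
#' @param times numeric vector of output times.
#' @param rtol,atol integrator tolerances; part of the simulation
#'   specification so runs are reproducible.
#' @return Matrix with a \code{time} column and one column per species.
#' @export
simulate_trajectory <- function(model, pars = NULL, times = seq(0, 100, 0.1),
                                rtol = 1e-8, atol = 1e-10) {
  if (!inherits(model, "kinetic_model")) stop("'model' must be a kinetic_model")
  pars <- pars %||% list(k = model$k, Km = model$Km, c0 = model$c0)
  unclass(.ode_solve(model, pars, times, rtol, atol))
}

#' Simulate one individual and sample at a fixed time
#'
#' Integrates from 0 to \code{t_sample} and returns the concentration vector
#' at the sampling time. Tiny negative concentrations from integration error
#' are clipped to zero; negatives beyond the clip tolerance raise a warning.
#'
#' @inheritParams simulate_trajectory
#' @param t_sample sampling time (> 0); the default 20 sits just past the
#'   transient of the built-in oscillator, where individuals' oscillation
#'   phases have begun to disperse but are not yet fully uniform -- the
#'   regime in which a global kinetic perturbation shows up most clearly in
#'   the cross-sectional correlation structure.
#' @param clip_tol magnitude below which negative concentrations are
#'   silently clipped to zero.
#' @return Named concentration vector (one entry per species).
#' @export
simulate_individual <- function(model, pars = NULL, t_sample = 20,
                                rtol = 1e-8, atol = 1e-10, clip_tol = 1e-6) {
  if (!is.numeric(t_sample) || t_sample <= 0) stop("'t_sample' must be > 0")
  pars <- pars %||% list(k = model$k, Km = model$Km, c0 = model$c0)
  out <- .ode_solve(model, pars, c(0, t_sample), rtol, atol)
  state <- out[nrow(out), model$species]
  if (any(state < -clip_tol)) {
    warning("negative concentrations beyond the clip tolerance; check the model")
  }
  pmax(state, 0)
}

#' Generate a population feature matrix from a kinetic model
#'
#' Row j of the output is the concentration snapshot of individual j:
#' parameters are jittered per individual (see
#' \code{\link{draw_individual}}), scaled by the group's perturbation
#' multiplier (see \code{\link{apply_perturbation}}), integrated, and
#' sampled at \code{t_sample}.
#'
#' @inheritParams simulate_individual
#' @inheritParams draw_individual
#' @param n population size.
#' @param epsilon global perturbation multiplier (1 = unperturbed
#'   reference condition).
#' @param seed optional integer seed; the same seed reproduces the matrix
#'   exactly.
#' @return n x (number of species) matrix with species column names.
#' @export
generate_group <- function(model, n, epsilon = 1, jitter_fraction = 0.1,
                           t_sample = 20, seed = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  if (!is.numeric(n) || n < 1) stop("'n' must be a positive integer")
  with_seed(seed, {
    rows <- vapply(seq_len(n), function(j) {
      pars <- apply_perturbation(draw_individual(model, jitter_fraction),
                                 epsilon)
      simulate_individual(model, pars, t_sample = t_sample,
                          rtol = rtol, atol = atol)
    }, numeric(length(model$species)))
    x <- t(rows)
    colnames(x) <- model$species
    x
  })
}

#' Summarize oscillation features of a trajectory
#'
#' For each species, reports over the late part of the trajectory (the
#' second half by default, past the transient): the amplitude (max - min),
#' the mean level, the relative amplitude, and the number of zero crossings
#' of the mean-detrended trace (a frequency proxy: crossings scale with
#' oscillation frequency over a fixed window).
#'
#' @param traj trajectory matrix from \code{\link{simulate_trajectory}}.
#' @param window_frac fraction of the trajectory (from the end) to analyze.
#' @return Data frame with columns \code{species}, \code{amplitude},
#'   \code{mean}, \code{rel_amplitude}, \code{crossings}.
#' @export
oscillation_summary <- function(traj, window_frac = 0.5) {
  if (!is.matrix(traj) || nrow(traj) < 4) {
    stop("'traj' must be a trajectory matrix with several time points")
  }
  idx <- seq.int(max(1, floor(nrow(traj) * (1 - window_frac))), nrow(traj))
  sp <- setdiff(colnames(traj), "time")
  res <- lapply(sp, function(s) {
    x <- traj[idx, s]
    xc <- x - mean(x)
    data.frame(species = s,
               amplitude = max(x) - min(x),
               mean = mean(x),
               rel_amplitude = (max(x) - min(x)) / max(mean(x), 1e-12),
               crossings = sum(diff(sign(xc)) != 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
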