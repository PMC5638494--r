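#' Multi-exponential fluorescence decay model
#'
#' Describes a total-intensity decay I(t) = sum_i a_i exp(-t / tau_i) with
#' normalised pre-exponential factors. Amplitudes are renormalised to sum to
#' one and components are sorted by increasing lifetime.
#'
#' @param amplitudes positive pre-exponential factors (any scale; normalised
#'   internally so that they sum to 1).
#' @param lifetimes_ns positive decay times in nanoseconds, one per amplitude
#'   (1 to 3 components).
#' @return An object of class `decay_model` with elements `amplitudes`,
#'   `lifetimes_ns` and `n_components`.
#' @examples
#' decay_model(c(0.7, 0.3), c(1, 5))
#' @export
decay_model <- function(amplitudes, lifetimes_ns) {
  amplitudes <- as.numeric(amplitudes)
  lifetimes_ns <- as.numeric(lifetimes_ns)
  if (length(amplitudes) != length(lifetimes_ns))
    stop("amplitudes and lifetimes_ns must have the same length")
  n <- length(lifetimes_ns)
  if (n < 1L || n > 3L)
    stop("decay_model supports 1 to 3 components, got ", n)
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0))
    stop("all amplitudes must be finite and > 0")
  if (any(!is.finite(lifetimes_ns)) || any(lifetimes_ns <= 0))
    stop("all lifetimes must be finite and > 0")
  ord <- order(lifetimes_ns)
  amplitudes <- amplitudes[ord] / sum(amplitudes)
  structure(
    list(amplitudes = amplitudes,
         lifetimes_ns = lifetimes_ns[ord],
         n_components = n),
    class = "decay_model")
}

#' Anisotropy decay model
#'
#' Describes r(t) = sum_i r0_i exp(-t / phi_i) where the r0_i are fractional
#' anisotropies and the phi_i rotational correlation times. The total
#' fundamental anisotropy sum(r0_i) may not exceed 0.4, the rigid-limit
#' maximum for a one-photon dipole system.
#'
#' @param r0 positive fractional anisotropies (1 or 2 components).
#' @param phi_ns positive rotational correlation times in nanoseconds.
#' @return An object of class `anisotropy_model` with components sorted by
#'   increasing correlation time.
#' @export
anisotropy_model <- function(r0, phi_ns) {
  r0 <- as.numeric(r0)
  phi_ns <- as.numeric(phi_ns)
  if (length(r0) != length(phi_ns))
    stop("r0 and phi_ns must have the same length")
  n <- length(r0)
  if (n < 1L || n > 2L)
    stop("anisotropy_model supports 1 or 2 components, got ", n)
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop("all fractional anisotropies must be finite and > 0")
  if (sum(r0) > 0.4 + 1e-12)
    stop("sum of fractional anisotropies exceeds the fundamental limit 0.4")
  if (any(!is.finite(phi_ns)) || any(phi_ns <= 0))
    stop("all correlation times must be finite and > 0")
  ord <- order(phi_ns)
  structure(
    list(r0 = r0[ord], phi_ns = phi_ns[ord], n_components = n),
    class = "anisotropy_model")
}

#' Two-segment breakpoint model for critical-concentration series
#'
#' Continuous hinge model for steady-state pyrene fluorescence F versus total
#' actin concentration \[a\]:
#' F = f_c + l_s (\[a\] - cc) below the breakpoint and
#' F = f_c + r_s (\[a\] - cc) above it. The breakpoint cc is the critical
#' concentration (free G-actin at steady state) and f_c the emission there.
#'
#' @param f_c emission at the breakpoint (arbitrary units).
#' @param l_s,r_s slopes below and above the breakpoint (au per micromolar).
#' @param cc_um critical concentration in micromolar, > 0.
#' @return An object of class `breakpoint_model`.
#' @export
breakpoint_model <- function(f_c, l_s, r_s, cc_um) {
  stopifnot(is.finite(f_c), is.finite(l_s), is.finite(r_s), is.finite(cc_um))
  if (cc_um <= 0) stop("cc_um must be > 0")
  structure(list(f_c = f_c, l_s = l_s, r_s = r_s, cc_um = cc_um),
            class = "breakpoint_model")
}

#' Evaluate a breakpoint model
#'
#' @param model a [breakpoint_model()].
#' @param conc_um actin concentrations (micromolar).
#' @return Predicted emission at each concentration.
#' @export
predict_breakpoint <- function(model, conc_um) {
  stopifnot(inherits(model, "breakpoint_model"))
  d <- conc_um - model$cc_um
  model$f_c + ifelse(d <= 0, model$l_s * d, model$r_s * d)
}

#' Sigmoidal binding-isotherm model
#'
#' Empirical Boltzmann sigmoid used for cosedimentation isotherms:
#' y(x) = (y_min - y_max) / (1 + exp((x - x0) / dx)) + y_max,
#' where y is the molecular-weight-corrected bound-protein ratio, x the total
#' ligand concentration, x0 the inflection concentration and dx the width of
#' the transition.
#'
#' @param y_min,y_max lower and upper plateaus (y_max >= y_min).
#' @param x0_um inflection concentration (micromolar).
#' @param dx_um transition width (micromolar), > 0.
#' @return An object of class `sigmoid_model`.
#' @export
sigmoid_model <- function(y_min, y_max, x0_um, dx_um) {
  stopifnot(is.finite(y_min), is.finite(y_max), is.finite(x0_um),
            is.finite(dx_um))
  if (y_max < y_min) stop("y_max must be >= y_min")
  if (dx_um <= 0) stop("dx_um must be > 0")
  structure(list(y_min = y_min, y_max = y_max, x0_um = x0_um, dx_um = dx_um),
            class = "sigmoid_model")
}

#' Evaluate a sigmoid model
#' @param model a [sigmoid_model()].
#' @param x_um ligand concentrations (micromolar).
#' @return Predicted bound ratio at each concentration.
#' @export
predict_sigmoid <- function(model, x_um) {
  stopifnot(inherits(model, "sigmoid_model"))
  (model$y_min - model$y_max) /
    (1 + exp((x_um - model$x0_um) / model$dx_um)) + model$y_max
}

#' Rising biexponential transient model
#'
#' y(t) = a1 (1 - exp(-t/t1)) + a2 (1 - exp(-t/t2)) with t1 <= t2, the
#' empirical form used for stopped-flow pyrene fluorescence transients.
#'
#' @param a1,a2 amplitudes in signal units.
#' @param t1_s,t2_s time constants in seconds; reordered so that t1 <= t2.
#' @return An object of class `biexp_model`.
#' @export
biexp_model <- function(a1, a2, t1_s, t2_s) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(t1_s), is.finite(t2_s))
  if (t1_s <= 0 || t2_s <= 0) stop("time constants must be > 0")
  if (t1_s > t2_s) {
    tmp <- c(a1, t1_s); a1 <- a2; t1_s <- t2_s; a2 <- tmp[1]; t2_s <- tmp[2]
  }
  structure(list(a1 = a1, a2 = a2, t1_s = t1_s, t2_s = t2_s),
            class = "biexp_model")
}

#' Evaluate a biexponential transient model
#' @param model a [biexp_model()].
#' @param time_s times in seconds.
#' @return Predicted signal.
#' @export
predict_biexp <- function(model, time_s) {
  stopifnot(inherits(model, "biexp_model"))
  model$a1 * (1 - exp(-time_s / model$t1_s)) +
    model$a2 * (1 - exp(-time_s / model$t2_s))
}

#' Additive Gaussian noise specification
#'
#' All synthetic generators take a `noise_spec`; `sigma` is the standard
#' deviation of i.i.d. Gaussian noise added to every sample (in the trace's
#' own intensity units) and `seed` makes the pseudo-random stream
#' reproducible: identical seed and parameters give bit-identical output.
#'
#' @param sigma noise standard deviation, >= 0. Zero gives noiseless output.
#' @param seed optional integer seed for the pseudo-random stream.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, seed = NULL) {
  stopifnot(is.finite(sigma), sigma >= 0)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(sigma = sigma, seed = seed), class = "noise_spec")
}

# Apply a noise spec to a numeric vector. Seeds the stream (restoring the
# caller's RNG state afterwards) so generator output is reproducible.
.add_noise <- function(x, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  if (noise$sigma == 0) return(x)
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(noise$seed)
  }
  x + stats::rnorm(length(x), 0, noise$sigma)
}

#' Fit report container
#'
#' Returned by every fitting operation. Carries the fitted domain model, the
#' asymptotic standard deviations of its parameters, the reduced chi-square,
#' convergence state and residuals. A non-converged report flags its
#' parameters as unusable.
#'
#' @param model the fitted domain model object.
#' @param parameter_sd named numeric vector of asymptotic standard deviations.
#' @param chi_sq_reduced residual sum of squares divided by degrees of freedom.
#' @param n_iterations iterations used by the optimiser.
#' @param converged logical convergence flag.
#' @param residuals numeric residual vector (data minus fit).
#' @param flags character vector of quality warnings.
#' @return An object of class `fit_report`.
#' @export
fit_report <- function(model, parameter_sd = numeric(), chi_sq_reduced = NA_real_,
                       n_iterations = NA_integer_, converged = TRUE,
                       residuals = numeric(), flags = character()) {
  structure(
    list(model = model, parameter_sd = parameter_sd,
         chi_sq_reduced = chi_sq_reduced, n_iterations = n_iterations,
         converged = converged, residuals = residuals, flags = flags),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Fit report (", class(x$model)[1], ")\n", sep = "")
  cat("  converged:", x$converged,
      " chi^2_red:", format(x$chi_sq_reduced, digits = 4),
      " iterations:", x$n_iterations, "\n")
  p <- unlist(x$model[!vapply(x$model, is.character, logical(1))])
  p <- p[!grepl("n_components", names(p))]
  for (i in seq_along(p))
    cat(sprintf("  %-14s %12.6g\n", names(p)[i], p[[i]]))
  if (length(x$parameter_sd))
    cat("  sd:", paste(names(x$parameter_sd),
                       format(x$parameter_sd, digits = 3), sep = " = ",
                       collapse = ", "), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Multi-exponential decay:", x$n_components, "component(s)\n")
  cat("  a  :", paste(format(x$amplitudes, digits = 4), collapse = ", "), "\n")
  cat("  tau:", paste(format(x$lifetimes_ns, digits = 4), collapse = ", "),
      "ns\n")
  invisible(x)
}

#' @export
print.anisotropy_model <- function(x, ...) {
  cat("Anisotropy decay:", x$n_components, "component(s)\n")
  cat("  r0 :", paste(format(x$r0, digits = 4), collapse = ", "), "\n")
  cat("  phi:", paste(format(x$phi_ns, digits = 4), collapse = ", "), "ns\n")
  invisible(x)
}
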