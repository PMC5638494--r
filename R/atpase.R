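# NADH-coupled ATPase analysis: A340 slope fitting, rate computation and
# activity/inhibition profiles. In the coupled assay each hydrolysed ATP is
# regenerated at the cost of one oxidised NADH, so the rate of A340 decrease
# is proportional to the steady-state hydrolysis rate.

#' Fit the A340 slope of an NADH trace
#'
#' Ordinary least-squares line over an analysis window (default the central
#' 80% of the trace, avoiding mixing and depletion artefacts at the ends).
#' The R-squared of the window fit is reported as a linearity diagnostic;
#' R^2 < 0.9 raises a nonlinearity flag.
#'
#' @param trace an `absorbance_trace` data frame (columns `time_s`, `a340`).
#' @param window optional numeric `c(start_s, stop_s)` overriding the
#'   default window.
#' @return A list with `slope_abs_per_s`, `slope_sd`, `r_squared`,
#'   `window_s` and `flags`.
#' @export
fit_a340_slope <- function(trace, window = NULL) {
  stopifnot(all(c("time_s", "a340") %in% names(trace)))
  t <- trace$time_s
  if (is.null(window)) {
    span <- range(t)
    window <- span[1] + c(0.1, 0.9) * diff(span)
  }
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 10) stop("need at least 10 points in the analysis window")
  fit <- stats::lm(a340 ~ time_s, data = trace[keep, ])
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  flags <- character()
  if (is.finite(r2) && r2 < 0.9) flags <- c(flags, "nonlinear window")
  list(slope_abs_per_s = unname(stats::coef(fit)[2]),
       slope_sd = sm$coefficients[2, 2],
       r_squared = r2, window_s = window, flags = flags)
}

#' ATPase activity from an A340 slope
#'
#' Converts the NADH absorbance slope to an ATP turnover rate: the molar
#' NADH oxidation rate is -slope / (eps x path); dividing by the motor
#' concentration gives k in uM_ATP per second per uM protein (1:1 NADH:ATP
#' coupling stoichiometry). A `m_atp` molarity divisor is accepted for the
#' literal normalisation k = -slope / (eps_path x M_ATP); the default
#' (`m_atp = NULL`) uses the motor-concentration normalisation that matches
#' the reported activity units.
#'
#' @param slope dA340/dt in absorbance per second (negative for hydrolysis).
#' @param eps_path molar absorptivity x path length in 1/M (default 6220:
#'   NADH at 340 nm, 1 cm).
#' @param hmm_um motor (HMM) concentration in micromolar, > 0.
#' @param m_atp optional ATP molarity (M) for the literal normalisation.
#' @param noise_sd optional slope standard deviation; a positive slope
#'   larger than 2 x this raises a negative-rate flag.
#' @return A list of class `atpase_result` with `rate_k`
#'   (uM_ATP s^-1 uM_protein^-1 in the default mode), `slope_abs_per_s`,
#'   `eps_path_per_m`, `hmm_um` and `flags`.
#' @examples
#' atpase_rate(-6.22e-4, hmm_um = 0.5)   # 0.2 uM ATP /s per uM HMM
#' @export
atpase_rate <- function(slope, eps_path = 6220, hmm_um = 0.5, m_atp = NULL,
                        noise_sd = 0) {
  if (eps_path <= 0) stop("eps_path must be > 0")
  if (is.null(m_atp) && hmm_um <= 0) stop("hmm_um must be > 0")
  flags <- character()
  if (slope > 2 * noise_sd && slope > 0)
    flags <- c(flags, "negative rate: absorbance increases")
  nadh_molar_per_s <- -slope / eps_path
  rate_k <- if (is.null(m_atp)) {
    nadh_molar_per_s * 1e6 / hmm_um
  } else {
    if (m_atp <= 0) stop("m_atp must be > 0")
    -slope / (eps_path * m_atp)
  }
  structure(
    list(rate_k = rate_k, slope_abs_per_s = slope,
         eps_path_per_m = eps_path, hmm_um = hmm_um, flags = flags),
    class = "atpase_result")
}

#' ATPase activity profile versus ligand concentration
#'
#' Collects per-condition rates into a profile and expresses each as a
#' fraction of the ligand-free control (which must be present and is 1 by
#' definition). Monotonicity is not assumed.
#'
#' @param lmod_um ligand concentrations, must include 0 (the control).
#' @param rates numeric activities, or a list of `atpase_result` objects.
#' @return A data frame of class `activity_profile` with columns `lmod_um`,
#'   `rate_k`, `fraction_of_control`, sorted by concentration.
#' @export
activity_profile <- function(lmod_um, rates) {
  if (is.list(rates) && !is.numeric(rates))
    rates <- vapply(rates, function(r) r$rate_k, numeric(1))
  if (length(lmod_um) != length(rates))
    stop("one rate per concentration required")
  i0 <- which(lmod_um == 0)
  if (length(i0) == 0)
    stop("profile must include a 0-ligand control")
  control <- rates[i0[1]]
  if (control <= 0) stop("control rate must be > 0")
  ord <- order(lmod_um)
  out <- data.frame(lmod_um = lmod_um[ord], rate_k = rates[ord],
                    fraction_of_control = rates[ord] / control)
  class(out) <- c("activity_profile", "data.frame")
  out
}
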