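# Side-binding quantification: cosedimentation densitometry ratios and the
# empirical sigmoidal isotherm, plus stopped-flow biexponential kinetics.

#' Molecular-weight-corrected densitometry ratios
#'
#' For each gel lane computes the ratio of pelleted ligand to pelleted actin
#' from stain band volumes, corrected for molecular weight and optionally
#' for per-protein staining efficiency:
#' ratio = (V_lmod / (MW_lmod stain_lmod)) / (V_actin / (MW_actin stain_actin)).
#' Lanes with a zero actin band are dropped with a warning (no filament
#' pellet, no ratio).
#'
#' @param table a `densitometry_table` data frame with columns
#'   `lmod_total_um`, `band_volume_actin`, `band_volume_lmod`.
#' @param mw_actin_kda,mw_lmod_kda molecular weights (defaults 42 and 62, or
#'   the table's own attributes when present).
#' @param stain_actin,stain_lmod Coomassie staining-efficiency coefficients
#'   (default 1).
#' @return A data frame with columns `lmod_total_um` and `ratio`.
#' @export
densitometry_ratio <- function(table, mw_actin_kda = NULL, mw_lmod_kda = NULL,
                               stain_actin = 1, stain_lmod = 1) {
  stopifnot(all(c("lmod_total_um", "band_volume_actin", "band_volume_lmod")
                %in% names(table)))
  if (is.null(mw_actin_kda)) mw_actin_kda <- attr(table, "mw_actin_kda") %||% 42
  if (is.null(mw_lmod_kda)) mw_lmod_kda <- attr(table, "mw_lmod_kda") %||% 62
  if (any(table$band_volume_actin < 0) || any(table$band_volume_lmod < 0))
    stop("band volumes must be >= 0")
  keep <- table$band_volume_actin > 0
  if (!all(keep))
    warning(sum(!keep), " lane(s) dropped: zero actin band volume")
  tb <- table[keep, , drop = FALSE]
  ratio <- (tb$band_volume_lmod / (mw_lmod_kda * stain_lmod)) /
    (tb$band_volume_actin / (mw_actin_kda * stain_actin))
  data.frame(lmod_total_um = tb$lmod_total_um, ratio = ratio)
}

#' Fit the sigmoidal binding isotherm
#'
#' Least-squares fit of the Boltzmann sigmoid
#' y = (y_min - y_max) / (1 + exp((x - x0) / dx)) + y_max to bound-ratio
#' data. The curve passes through (y_min + y_max) / 2 at the inflection x0.
#' Flat data (no curvature beyond 5% of the data range across the span) are
#' flagged unidentifiable.
#'
#' @param x ligand concentrations (micromolar), at least 5 points.
#' @param y bound ratios.
#' @return A [fit_report()] whose `model` is a [sigmoid_model()].
#' @export
fit_sigmoid <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 5) stop("need at least 5 points")
  resid_fn <- function(par) {
    (par[1] - par[2]) / (1 + exp((x - par[3]) / abs(par[4]))) + par[2] - y
  }
  rng <- diff(range(y))
  span <- diff(range(x))
  starts <- lapply(c(0.05, 0.15, 0.4), function(w)
    c(min(y), max(y), stats::median(x), w * span))
  res <- .lm_multistart(resid_fn, starts)
  if (is.null(res))
    return(fit_report(NULL, converged = FALSE,
                      flags = "non-convergence: all starts failed"))
  par <- res$par
  model <- sigmoid_model(y_min = min(par[1], par[2]),
                         y_max = max(par[1], par[2]),
                         x0_um = par[3], dx_um = abs(par[4]))
  flags <- character()
  if (rng < 0.05 * max(abs(y), 1e-12) || diff(range(predict_sigmoid(model, x))) <
      0.05 * max(rng, 1e-12))
    flags <- c(flags, "unidentifiable: no curvature")
  sd <- res$sd
  names(sd) <- c("y_min", "y_max", "x0_um", "dx_um")
  fit_report(model, parameter_sd = sd, chi_sq_reduced = res$chi_sq_reduced,
             n_iterations = res$n_iterations, converged = res$converged,
             residuals = res$residuals, flags = flags)
}

#' Fit a rising biexponential stopped-flow transient
#'
#' Fits y(t) = a1 (1 - exp(-t/t1)) + a2 (1 - exp(-t/t2)) by damped least
#' squares with multi-start time constants. Components are reordered so
#' t1 <= t2. When the slow amplitude is less certain than its own magnitude
#' (sd(a2) > |a2|) the fit falls back to a single exponential and reports it
#' as a degenerate biexponential (a2 = 0), flagged
#' `"single-exponential fallback"`.
#'
#' @param trace a `stopped_flow_trace` data frame (columns `time_s`,
#'   `signal_au`).
#' @return A [fit_report()] whose `model` is a [biexp_model()].
#' @export
fit_biexponential <- function(trace) {
  stopifnot(all(c("time_s", "signal_au") %in% names(trace)))
  t <- trace$time_s
  y <- trace$signal_au
  span <- max(t[t > 0])
  resid2 <- function(par) {
    a <- par[1:2]; tc <- abs(par[3:4])
    a[1] * (1 - exp(-t / tc[1])) + a[2] * (1 - exp(-t / tc[2])) - y
  }
  amp <- y[length(y)]
  tgrid <- exp(seq(log(span / 200), log(span), length.out = 6))
  starts <- lapply(tgrid, function(t0) c(amp / 2, amp / 2, t0, 4 * t0))
  res <- .lm_multistart(resid2, starts)
  if (is.null(res))
    return(fit_report(NULL, converged = FALSE,
                      flags = "non-convergence: all starts failed"))
  a <- res$par[1:2]; tc <- abs(res$par[3:4])
  ord <- order(tc)
  a <- a[ord]; tc <- tc[ord]
  sd <- res$sd[c(ord, 2 + ord)]
  names(sd) <- c("a1", "a2", "t1_s", "t2_s")
  flags <- character()
  if (is.finite(sd["a2"]) && sd["a2"] > abs(a[2])) {
    # slow amplitude unresolved: refit single exponential
    resid1 <- function(par) par[1] * (1 - exp(-t / abs(par[2]))) - y
    res1 <- .lm_multistart(resid1, lapply(tgrid, function(t0) c(amp, t0)))
    if (!is.null(res1)) {
      a <- c(res1$par[1], 0)
      tc <- c(abs(res1$par[2]), abs(res1$par[2]))
      sd <- c(a1 = unname(res1$sd[1]), a2 = 0, t1_s = unname(res1$sd[2]),
              t2_s = NA_real_)
      res <- res1
      flags <- c(flags, "single-exponential fallback")
    }
  }
  model <- structure(list(a1 = a[1], a2 = a[2], t1_s = tc[1], t2_s = tc[2]),
                     class = "biexp_model")
  fit_report(model, parameter_sd = sd, chi_sq_reduced = res$chi_sq_reduced,
             n_iterations = res$n_iterations, converged = res$converged,
             residuals = res$residuals, flags = flags)
}

#' Observed-rate versus concentration line
#'
#' Ordinary least-squares fit of the fast observed rate 1/t1 against ligand
#' concentration, the standard diagnostic for a second-order binding step
#' (slope ~ association rate constant, intercept ~ dissociation).
#'
#' @param lmod_um ligand concentrations (micromolar), at least 3.
#' @param fits list of [biexp_model()]s (or `fit_report`s holding them), one
#'   per concentration.
#' @return A list with `slope`, `intercept`, their standard deviations, and
#'   the underlying `lm` fit.
#' @export
rate_vs_concentration <- function(lmod_um, fits) {
  if (length(lmod_um) < 3) stop("need at least 3 concentrations")
  if (length(fits) != length(lmod_um))
    stop("one fit per concentration required")
  models <- lapply(fits, function(f) if (inherits(f, "fit_report")) f$model else f)
  k_obs <- vapply(models, function(m) 1 / m$t1_s, numeric(1))
  fit <- stats::lm(k_obs ~ lmod_um)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_sd = sm[2, 2], intercept_sd = sm[1, 2], fit = fit)
}
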