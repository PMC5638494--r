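# Pyrene polymerisation kinetics: ionic strength bookkeeping, half-maximal
# slope extraction, rate normalisation, and the critical-concentration
# breakpoint fit.

# dissociation stoichiometry: ion charge and count per formula unit
.salt_table <- list(
  KCl   = data.frame(z = c(+1, -1), n = c(1, 1)),
  NaCl  = data.frame(z = c(+1, -1), n = c(1, 1)),
  MgCl2 = data.frame(z = c(+2, -1), n = c(1, 2)),
  CaCl2 = data.frame(z = c(+2, -1), n = c(1, 2)),
  Na2SO4 = data.frame(z = c(+1, -2), n = c(2, 1))
)

#' Ionic strength of a salt mixture
#'
#' Dissociates each salt by its fixed stoichiometry (KCl -> K+ + Cl-;
#' MgCl2 -> Mg2+ + 2 Cl-; ...) and sums over all ions. The `"squared"`
#' convention is the standard ionic strength (1/2) sum c_i z_i^2; the
#' `"as_printed"` convention, (1/2) sum c_i |z_i|, drops the square and is
#' provided for comparability with charge-weighted reports. The two agree
#' for purely monovalent salts.
#'
#' @param salts named numeric vector of molar salt concentrations, e.g.
#'   `c(KCl = 0.1, MgCl2 = 0.002)`. Supported salts: KCl, NaCl, MgCl2,
#'   CaCl2, Na2SO4.
#' @param convention `"squared"` (default) or `"as_printed"`.
#' @return Ionic strength in molar.
#' @examples
#' ionic_strength(c(KCl = 0.1, MgCl2 = 0.002))   # high-salt assay buffer
#' @export
ionic_strength <- function(salts, convention = c("squared", "as_printed")) {
  convention <- match.arg(convention)
  if (length(salts) == 0) return(0)
  if (is.null(names(salts)) || any(!nzchar(names(salts))))
    stop("salts must be a named vector of molar concentrations")
  if (any(salts < 0)) stop("concentrations must be >= 0")
  unknown <- setdiff(names(salts), names(.salt_table))
  if (length(unknown))
    stop("unknown salt(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(names(.salt_table), collapse = ", "))
  total <- 0
  for (s in names(salts)) {
    tab <- .salt_table[[s]]
    w <- if (convention == "squared") tab$z^2 else abs(tab$z)
    total <- total + salts[[s]] * sum(tab$n * w)
  }
  total / 2
}

#' Standard salt conditions of the polymerisation assays
#'
#' @param label `"low"` (10 mM KCl + 0.5 mM MgCl2), `"medium"` (50 mM KCl +
#'   1 mM MgCl2) or `"high"` (100 mM KCl + 2 mM MgCl2).
#' @return Named molar concentration vector usable with [ionic_strength()].
#' @export
salt_condition <- function(label = c("low", "medium", "high")) {
  label <- match.arg(label)
  switch(label,
         low    = c(KCl = 0.010, MgCl2 = 0.0005),
         medium = c(KCl = 0.050, MgCl2 = 0.001),
         high   = c(KCl = 0.100, MgCl2 = 0.002))
}

#' Polymerisation rate at half-maximal change
#'
#' Locates the time of half-maximal fluorescence change by linear
#' interpolation of the first crossing of (f_min + f_max) / 2, then
#' estimates the rate as the ordinary-least-squares slope over the points
#' whose intensity lies within `window_frac` of the total amplitude around
#' the half-maximal level. For a monotone sigmoidal assembly curve this is
#' the maximal slope.
#'
#' @param trace a `pyrene_trace` data frame (columns `time_s`,
#'   `intensity_au`).
#' @param window_frac half-width of the slope window as a fraction of total
#'   amplitude (default 0.05).
#' @return A list of class `rate_result` with `slope_au_per_s`, `t_half_s`,
#'   `f_min`, `f_max` and `flags`.
#' @export
extract_rate <- function(trace, window_frac = 0.05) {
  stopifnot(all(c("time_s", "intensity_au") %in% names(trace)))
  y <- trace$intensity_au
  t <- trace$time_s
  f_min <- min(y); f_max <- max(y)
  amp <- f_max - f_min
  noise_est <- stats::mad(diff(y)) / sqrt(2)
  if (amp < 5 * noise_est)
    stop("trace amplitude below 5x the noise estimate; no resolvable rise")
  half <- (f_min + f_max) / 2
  above <- y >= half
  cross <- which(diff(above) != 0)
  flags <- character()
  if (length(cross) == 0) stop("trace never crosses its half-maximal level")
  if (length(cross) > 1)
    flags <- c(flags, "multiple half-crossings: first crossing used")
  i <- cross[1]
  # linear interpolation of the first crossing
  t_half <- t[i] + (half - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
  in_window <- abs(y - half) <= window_frac * amp
  if (sum(in_window) < 2) {
    # sparse grid: fall back to the two bracketing points
    in_window <- seq_along(y) %in% c(i, i + 1L)
    flags <- c(flags, "window too narrow for grid: secant slope used")
  }
  fit <- stats::lm(y[in_window] ~ t[in_window])
  structure(
    list(slope_au_per_s = unname(stats::coef(fit)[2]), t_half_s = t_half,
         f_min = f_min, f_max = f_max, flags = flags),
    class = "rate_result")
}

#' Normalise a polymerisation rate to spontaneous assembly
#'
#' Fold change = sample slope / spontaneous slope, where the spontaneous
#' rate comes from an actin-only trace under the same conditions.
#'
#' @param sample,spontaneous `rate_result` objects from [extract_rate()].
#' @return The dimensionless fold change.
#' @export
normalise_rate <- function(sample, spontaneous) {
  stopifnot(inherits(sample, "rate_result"),
            inherits(spontaneous, "rate_result"))
  if (spontaneous$slope_au_per_s <= 0)
    stop("spontaneous slope must be > 0")
  sample$slope_au_per_s / spontaneous$slope_au_per_s
}

#' Fit the critical-concentration breakpoint model
#'
#' Fits the continuous two-segment line F = f_c + l_s ([a] - cc) below the
#' breakpoint and F = f_c + r_s ([a] - cc) above it to a steady-state
#' intensity-versus-concentration series. For a fixed breakpoint the model
#' is linear in (f_c, l_s, r_s), so the fit profiles the residual sum of
#' squares over candidate breakpoints spanning the data, then refines the
#' best interval by golden-section search.
#'
#' Flags: `"unidentifiable: slopes equal"` when |l_s - r_s| < 5% of |r_s|
#' (the breakpoint of a straight line is undefined), and
#' `"breakpoint at span boundary"` when the estimate sits at the edge of
#' the concentration range.
#'
#' @param series a `cc_series` data frame (columns `conc_um`,
#'   `intensity_au`), at least 5 points.
#' @return A [fit_report()] whose `model` is a [breakpoint_model()].
#' @examples
#' s <- gen_cc_series(breakpoint_model(10, 0.5, 40, 0.12))
#' fit_critical_concentration(s)$model$cc_um
#' @export
fit_critical_concentration <- function(series) {
  stopifnot(all(c("conc_um", "intensity_au") %in% names(series)))
  x <- series$conc_um
  y <- series$intensity_au
  n <- length(x)
  if (n < 5) stop("need at least 5 points to fit a breakpoint")
  sse_at <- function(cc) {
    lo <- pmin(x - cc, 0)
    hi <- pmax(x - cc, 0)
    # .lm.fit for speed: this is evaluated hundreds of times per profile
    sum(stats::.lm.fit(cbind(1, lo, hi), y)$residuals^2)
  }
  # profile over a dense grid inside the span, then refine around the best
  span <- range(x)
  grid <- seq(span[1], span[2], length.out = 512)
  sse <- vapply(grid, sse_at, numeric(1))
  k <- which.min(sse)
  lo_b <- grid[max(k - 1, 1)]
  hi_b <- grid[min(k + 1, length(grid))]
  opt <- stats::optimize(sse_at, interval = c(lo_b, hi_b), tol = 1e-10)
  cc <- opt$minimum
  lo <- pmin(x - cc, 0); hi <- pmax(x - cc, 0)
  fit <- stats::lm(y ~ lo + hi)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0  # rank-deficient when the breakpoint leaves one side empty
  sm <- suppressWarnings(summary(fit))$coefficients
  sd_of <- function(nm) if (nm %in% rownames(sm)) sm[nm, 2] else NA_real_
  model <- breakpoint_model(f_c = unname(cf[1]), l_s = unname(cf[2]),
                            r_s = unname(cf[3]), cc_um = cc)
  flags <- character()
  if (abs(model$l_s - model$r_s) < 0.05 * abs(model$r_s))
    flags <- c(flags, "unidentifiable: slopes equal")
  tol_edge <- 1e-3 * diff(span)
  if (cc - span[1] < tol_edge || span[2] - cc < tol_edge)
    flags <- c(flags, "breakpoint at span boundary")
  dof <- max(n - 4, 1)
  fit_report(model,
             parameter_sd = c(f_c = sd_of("(Intercept)"), l_s = sd_of("lo"),
                              r_s = sd_of("hi"), cc_um = NA_real_),
             chi_sq_reduced = sum(stats::resid(fit)^2) / dof,
             converged = TRUE, residuals = stats::resid(fit), flags = flags)
}
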