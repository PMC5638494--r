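# Independent oracles used across the suite.

# trapezoidal quadrature on an irregular grid
trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

# direct summation evaluation of a multi-exponential decay (independent of
# the package's internal evaluator)
oracle_decay <- function(a, tau, t) {
  vapply(t, function(ti) sum(a * exp(-ti / tau)), numeric(1))
}

# phase/modulation of a decay by numeric Fourier quadrature of the
# time-domain law (independent of the closed-form transforms); fine-grid
# trapezoid handles the oscillatory integrand reliably
oracle_phase_mod <- function(a, tau, f_mhz) {
  omega <- 2 * pi * f_mhz * 1e-3
  t <- seq(0, 60 * max(tau), length.out = 400000L)
  decay <- oracle_decay(a, tau, t)
  n <- trapz(t, decay * sin(omega * t))
  d <- trapz(t, decay * cos(omega * t))
  j0 <- trapz(t, decay)
  list(phase_deg = atan2(n, d) * 180 / pi,
       modulation = sqrt(n^2 + d^2) / j0)
}

# brute-force breakpoint scan: exhaustive SSE minimisation on a fine grid
oracle_breakpoint_scan <- function(x, y, step = 1e-3) {
  ccs <- seq(min(x) + step, max(x) - step, by = step)
  sse <- vapply(ccs, function(cc) {
    sum(stats::.lm.fit(cbind(1, pmin(x - cc, 0), pmax(x - cc, 0)),
                       y)$residuals^2)
  }, numeric(1))
  ccs[which.min(sse)]
}

# coarse lattice search for a biexponential rise (amplitudes solved linearly)
oracle_biexp_lattice <- function(t, y, t_grid) {
  best <- NULL
  for (t1 in t_grid) for (t2 in t_grid) {
    if (t2 < t1) next
    X <- cbind(1 - exp(-t / t1), 1 - exp(-t / t2))
    fit <- stats::.lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(t1 = t1, t2 = t2, a = fit$coefficients, sse = sse)
  }
  best
}
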