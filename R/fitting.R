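# Internal Levenberg-Marquardt wrapper around minpack.lm::nls.lm with
# multi-start initialisation. Returns the best-by-SSE start together with
# asymptotic parameter standard deviations from the Jacobian.

.lm_multistart <- function(residual_fn, starts, lower = NULL, upper = NULL,
                           maxiter = 500) {
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = residual_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = maxiter, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(NULL)
  n <- length(best$fvec)
  p <- length(best$par)
  dof <- max(n - p, 1L)
  s2 <- best$deviance / dof
  sds <- rep(NA_real_, p)
  names(sds) <- names(best$par)
  cov <- tryCatch(s2 * solve(best$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    sds <- sqrt(pmax(d, 0))
    names(sds) <- names(best$par)
  }
  list(par = best$par, sd = sds, deviance = best$deviance,
       chi_sq_reduced = s2, n_iterations = best$niter,
       converged = best$info %in% 1:4, residuals = best$fvec)
}

# log-spaced multi-start lifetime/correlation-time grids over [lo, hi]
.log_starts <- function(n_components, n_starts = 8, lo = 0.1, hi = 50) {
  base <- exp(seq(log(lo), log(hi), length.out = n_starts))
  lapply(base, function(t0) {
    # spread components geometrically around the start value
    t0 * 2^(seq_len(n_components) - (n_components + 1) / 2)
  })
}
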