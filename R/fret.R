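# Inter-monomer FRET: inner-filter correction, donor-band integration,
# transfer efficiency, f' and its temperature dependence. The relative f'
# (E / F_DA normalised to the lowest temperature) reports the flexibility of
# the protein matrix between donor and acceptor and remains valid when one
# donor transfers to several acceptors.

#' Inner-filter correction of an emission spectrum
#'
#' Multiplies intensities by 10^((A_ex + A_em) / 2), the standard
#' first-order correction for attenuation of the excitation and emission
#' beams by sample absorbance. Zero absorbances (pre-corrected data) leave
#' the spectrum unchanged.
#'
#' @param spectrum an `emission_spectrum` data frame (columns
#'   `wavelength_nm`, `intensity_au`).
#' @param a_ex,a_em sample absorbances at the excitation and emission
#'   wavelengths, >= 0.
#' @return The corrected spectrum (attributes preserved).
#' @export
inner_filter_correct <- function(spectrum, a_ex = 0, a_em = 0) {
  stopifnot(all(c("wavelength_nm", "intensity_au") %in% names(spectrum)))
  if (a_ex < 0 || a_em < 0) stop("absorbances must be >= 0")
  spectrum$intensity_au <- spectrum$intensity_au * 10^((a_ex + a_em) / 2)
  spectrum
}

#' Integrate a spectral band
#'
#' Trapezoidal area under the spectrum over a closed wavelength band, with
#' linear interpolation of the intensity at the band edges so the result is
#' independent of grid registration.
#'
#' @param spectrum an `emission_spectrum` data frame.
#' @param lo_nm,hi_nm band limits (defaults 435-485 nm, the donor band).
#' @return The band area (intensity x nm).
#' @export
integrate_band <- function(spectrum, lo_nm = 435, hi_nm = 485) {
  stopifnot(all(c("wavelength_nm", "intensity_au") %in% names(spectrum)))
  w <- spectrum$wavelength_nm
  if (min(w) > lo_nm || max(w) < hi_nm)
    stop("spectrum grid does not cover the band ", lo_nm, "-", hi_nm, " nm")
  inside <- w > lo_nm & w < hi_nm
  edge <- stats::approx(w, spectrum$intensity_au, xout = c(lo_nm, hi_nm))$y
  xs <- c(lo_nm, w[inside], hi_nm)
  ys <- c(edge[1], spectrum$intensity_au[inside], edge[2])
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' FRET efficiency from donor quenching
#'
#' E = 1 - F_DA / F_D, where F_D and F_DA are the integrated donor emissions
#' without and with acceptor. Noise can push E slightly negative; such
#' values are reported as-is (never clipped) with a warning attribute left
#' to the caller.
#'
#' @param f_d integrated donor-only emission, > 0.
#' @param f_da integrated donor emission with acceptor present.
#' @return The transfer efficiency (dimensionless fraction).
#' @examples
#' fret_efficiency(100, 74)   # 26% transfer
#' @export
fret_efficiency <- function(f_d, f_da) {
  if (any(f_d <= 0)) stop("f_d must be > 0")
  1 - f_da / f_d
}

#' Build a temperature series of f' values
#'
#' For each temperature computes E = 1 - F_DA / F_D and f' = E / F_DA, then
#' the relative f' by normalising to the lowest temperature (which is
#' exactly 1 there by construction).
#'
#' @param records data frame with columns `temperature_c`, `f_d`, `f_da`
#'   (one row per temperature, at least 2).
#' @param condition optional condition label carried as an attribute.
#' @return A data frame of class `fret_series` with columns
#'   `temperature_c`, `f_d`, `f_da`, `efficiency`, `f_prime`,
#'   `relative_f_prime`, sorted by temperature.
#' @export
f_prime_series <- function(records, condition = "") {
  stopifnot(is.data.frame(records),
            all(c("temperature_c", "f_d", "f_da") %in% names(records)))
  if (nrow(records) < 2) stop("need at least 2 temperatures")
  if (anyDuplicated(records$temperature_c))
    stop("temperatures must be distinct")
  out <- records[order(records$temperature_c), , drop = FALSE]
  out$efficiency <- fret_efficiency(out$f_d, out$f_da)
  out$f_prime <- out$efficiency / out$f_da
  if (out$f_prime[1] == 0)
    stop("f' at the lowest temperature is zero; cannot normalise")
  out$relative_f_prime <- out$f_prime / out$f_prime[1]
  rownames(out) <- NULL
  attr(out, "condition") <- condition
  class(out) <- c("fret_series", "data.frame")
  out
}

#' Temperature slope of the relative f'
#'
#' Ordinary least-squares slope of relative f' versus temperature; a
#' steeper slope indicates a more flexible protein matrix between donor and
#' acceptor.
#'
#' @param series a `fret_series` (from [f_prime_series()]), at least 3
#'   temperatures.
#' @return A list with `slope` (per degree C), `slope_sd`, `intercept` and
#'   the underlying `lm` fit.
#' @export
temperature_slope <- function(series) {
  stopifnot(inherits(series, "fret_series") || is.data.frame(series))
  if (nrow(series) < 3) stop("need at least 3 temperatures")
  fit <- stats::lm(relative_f_prime ~ temperature_c, data = series)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_sd = sm[2, 2], fit = fit)
}

#' Compare the temperature slopes of two f' series
#'
#' Difference of the [temperature_slope()] estimates (a minus b) with its
#' propagated standard deviation, for testing whether one condition makes
#' the filament matrix more flexible than the other.
#'
#' @param series_a,series_b `fret_series` objects.
#' @return A list with `delta_slope`, `delta_sd` and the two slopes.
#' @export
compare_temperature_slopes <- function(series_a, series_b) {
  a <- temperature_slope(series_a)
  b <- temperature_slope(series_b)
  list(delta_slope = a$slope - b$slope,
       delta_sd = sqrt(a$slope_sd^2 + b$slope_sd^2),
       slope_a = a$slope, slope_b = b$slope)
}

#' Integrate a generated spectrum set into f' records
#'
#' Convenience bridge from [gen_fret_spectra()] output to the record format
#' of [f_prime_series()]: integrates the 435-485 nm donor band of every
#' spectrum and pairs donor-only with donor+acceptor areas per temperature.
#'
#' @param spectra list of `emission_spectrum` objects.
#' @return A data frame with columns `temperature_c`, `f_d`, `f_da`.
#' @export
spectra_to_records <- function(spectra) {
  temps <- vapply(spectra, attr, numeric(1), "temperature_c")
  cond <- vapply(spectra, attr, character(1), "condition")
  area <- vapply(spectra, integrate_band, numeric(1))
  ut <- sort(unique(temps))
  data.frame(
    temperature_c = ut,
    f_d = vapply(ut, function(tc)
      area[temps == tc & cond == "donor-only"][1], numeric(1)),
    f_da = vapply(ut, function(tc)
      area[temps == tc & cond == "donor+acceptor"][1], numeric(1)))
}
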