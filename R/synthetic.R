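# Synthetic raw-data generators. Each generator produces, from known
# ground-truth parameters, one of the raw measurement types the analysis
# stages consume, so every stage can be verified by forward-inverse
# parameter recovery. Noise is additive i.i.d. Gaussian (noise_spec).

# total intensity of a decay_model on a time grid
.decay_intensity <- function(decay, time_ns) {
  drop(exp(-outer(time_ns, 1 / decay$lifetimes_ns)) %*% decay$amplitudes)
}

# r(t) of an anisotropy_model (zero model allowed via NULL)
.aniso_r <- function(aniso, time_ns) {
  if (is.null(aniso)) return(rep(0, length(time_ns)))
  drop(exp(-outer(time_ns, 1 / aniso$phi_ns)) %*% aniso$r0)
}

#' Generate polarized fluorescence decay traces
#'
#' Builds I_VV(t) and I_VH(t) from a total-intensity decay I(t) and an
#' anisotropy decay r(t) by inverting the magic relations
#' I_VV = I (1 + 2 r) / 3 and G I_VH = I (1 - r) / 3, so the noiseless pair
#' satisfies I_VV + 2 G I_VH = I(t) exactly and the anisotropy computed from
#' the pair reproduces r(t).
#'
#' @param decay a [decay_model()] for the total intensity.
#' @param aniso an [anisotropy_model()], or `NULL` for isotropic emission
#'   (r(t) = 0).
#' @param g_factor instrument polarization sensitivity ratio G > 0.
#' @param time_ns strictly increasing time grid in nanoseconds (default
#'   1024 points over 0-50 ns).
#' @param noise a [noise_spec()]; noise is added independently to both
#'   polarized channels.
#' @return A data frame of class `polarized_decay` with columns `time_ns`,
#'   `i_vv`, `i_vh`, and attribute `g_factor`.
#' @examples
#' tr <- gen_polarized_decay(decay_model(1, 3), anisotropy_model(0.2, 35.9))
#' head(tr)
#' @export
gen_polarized_decay <- function(decay, aniso = NULL, g_factor = 1,
                                time_ns = seq(0, 50, length.out = 1024),
                                noise = noise_spec()) {
  stopifnot(inherits(decay, "decay_model"),
            is.null(aniso) || inherits(aniso, "anisotropy_model"))
  if (g_factor <= 0) stop("g_factor must be > 0")
  if (any(diff(time_ns) <= 0)) stop("time grid must be strictly increasing")
  itot <- .decay_intensity(decay, time_ns)
  r <- .aniso_r(aniso, time_ns)
  i_vv <- itot * (1 + 2 * r) / 3
  i_vh <- itot * (1 - r) / (3 * g_factor)
  out <- data.frame(time_ns = time_ns,
                    i_vv = .add_noise(i_vv, noise),
                    i_vh = .add_noise(i_vh, .shift_seed(noise, 1L)))
  attr(out, "g_factor") <- g_factor
  class(out) <- c("polarized_decay", "data.frame")
  out
}

# derive an independent but reproducible stream for a second channel
.shift_seed <- function(noise, k) {
  if (is.null(noise$seed)) return(noise)
  noise_spec(noise$sigma, noise$seed + k)
}

# analytic sine/cosine transforms of a multi-exponential decay, i.e. the
# Fourier transform of I(t) = sum a_i exp(-t/tau_i): components enter with
# their fractional intensities f_i = a_i tau_i / sum(a_j tau_j), so
# N(w) = sum f_i w tau_i / (1 + w^2 tau_i^2), D(w) = sum f_i / (1 + ...),
# phase = atan(N/D), modulation = sqrt(N^2 + D^2)
.freq_response <- function(decay, freq_mhz) {
  omega <- 2 * pi * freq_mhz * 1e-3  # rad/ns for f in MHz, tau in ns
  f_int <- decay$amplitudes * decay$lifetimes_ns
  f_int <- f_int / sum(f_int)
  wt <- outer(omega, decay$lifetimes_ns)
  den <- 1 + wt^2
  n <- drop((wt / den) %*% f_int)
  d <- drop((1 / den) %*% f_int)
  list(phase_deg = atan2(n, d) * 180 / pi,
       modulation = sqrt(n^2 + d^2))
}

#' Generate a frequency-domain phase/modulation sweep
#'
#' Computes the phase shift and demodulation ratio of a multi-exponential
#' decay at each modulation frequency from the analytic sine and cosine
#' transforms (the Fourier transform of the decay law, in which each
#' component carries its fractional intensity a_i tau_i / sum(a_j tau_j)).
#' For a single component these reduce to tan(phase) = omega tau and
#' modulation = 1 / sqrt(1 + omega^2 tau^2).
#'
#' @param decay a [decay_model()].
#' @param freq_mhz strictly increasing modulation frequencies in MHz.
#' @param noise a [noise_spec()]; sigma is applied to the modulation ratio
#'   and, scaled by 30 (degrees per unit modulation, a typical instrument
#'   ratio), to the phase.
#' @return A data frame of class `frequency_sweep` with columns `freq_mhz`,
#'   `phase_deg`, `modulation`.
#' @export
gen_frequency_sweep <- function(decay,
                                freq_mhz = exp(seq(log(5), log(200),
                                                   length.out = 10)),
                                noise = noise_spec()) {
  stopifnot(inherits(decay, "decay_model"))
  if (length(freq_mhz) == 0) stop("frequency list must not be empty")
  if (any(freq_mhz <= 0)) stop("frequencies must be > 0")
  if (any(diff(freq_mhz) <= 0)) stop("frequencies must be strictly increasing")
  fr <- .freq_response(decay, freq_mhz)
  out <- data.frame(freq_mhz = freq_mhz,
                    phase_deg = .add_noise(fr$phase_deg,
                                           noise_spec(noise$sigma * 30,
                                                      if (is.null(noise$seed)) NULL
                                                      else noise$seed + 1L)),
                    modulation = .add_noise(fr$modulation, noise))
  class(out) <- c("frequency_sweep", "data.frame")
  out
}

# generalized logistic pyrene curve (noiseless)
.pyrene_curve <- function(time_s, f0, fmax, t_half, steepness, plateau_scale) {
  f0 + plateau_scale * (fmax - f0) / (1 + exp(-steepness * (time_s - t_half)))
}

#' Generate a pyrene-actin polymerisation trace
#'
#' Generalized logistic curve standing in for the sigmoidal rise of pyrene
#' fluorescence during actin assembly (lag, growth, plateau). The maximal
#' slope occurs at `t_half` and equals
#' `plateau_scale * (fmax - f0) * steepness / 4`. `plateau_scale` scales the
#' saturation intensity independently of the kinetics, emulating the
#' concentration-dependent increase of pyrene quantum yield produced by
#' filament side-binders.
#'
#' @param f0 baseline fluorescence (monomeric actin).
#' @param fmax reference plateau for `plateau_scale = 1`; `fmax > f0`.
#' @param t_half_s time of half-maximal change (s), within the grid.
#' @param steepness logistic rate constant (1/s), > 0.
#' @param plateau_scale saturation multiplier >= 1; the plateau is
#'   `f0 + plateau_scale * (fmax - f0)`.
#' @param time_s increasing time grid in seconds (default 500 points over
#'   0-2000 s).
#' @param noise a [noise_spec()].
#' @param label condition tag carried through as an attribute.
#' @return A data frame of class `pyrene_trace` with columns `time_s`,
#'   `intensity_au`.
#' @export
gen_pyrene_curve <- function(f0 = 0, fmax = 1, t_half_s = 600,
                             steepness = 0.01, plateau_scale = 1,
                             time_s = seq(0, 2000, length.out = 500),
                             noise = noise_spec(), label = "") {
  if (fmax <= f0) stop("fmax must exceed f0")
  if (steepness <= 0) stop("steepness must be > 0")
  if (plateau_scale < 1) stop("plateau_scale must be >= 1")
  if (t_half_s < min(time_s) || t_half_s > max(time_s))
    stop("t_half_s must lie within the time grid")
  y <- .pyrene_curve(time_s, f0, fmax, t_half_s, steepness, plateau_scale)
  out <- data.frame(time_s = time_s, intensity_au = .add_noise(y, noise))
  attr(out, "label") <- label
  class(out) <- c("pyrene_trace", "data.frame")
  out
}

#' Generate a critical-concentration series
#'
#' Steady-state pyrene emission versus total actin concentration from a
#' continuous two-segment [breakpoint_model()]: below the critical
#' concentration the signal follows the monomer slope, above it the polymer
#' slope.
#'
#' @param model a [breakpoint_model()].
#' @param conc_um strictly increasing actin concentrations in micromolar
#'   (default: the 9-point assay grid 0.03-5).
#' @param noise a [noise_spec()].
#' @return A data frame of class `cc_series` with columns `conc_um`,
#'   `intensity_au`; attribute `unidentifiable_warning` is `TRUE` if the
#'   breakpoint lies outside the concentration span.
#' @export
gen_cc_series <- function(model,
                          conc_um = c(0.03, 0.05, 0.1, 0.3, 0.5, 0.7, 1, 3, 5),
                          noise = noise_spec()) {
  stopifnot(inherits(model, "breakpoint_model"))
  if (any(conc_um <= 0)) stop("concentrations must be > 0")
  if (any(diff(conc_um) <= 0)) stop("concentrations must be strictly increasing")
  outside <- model$cc_um < min(conc_um) || model$cc_um > max(conc_um)
  if (outside)
    warning("breakpoint lies outside the concentration span; ",
            "a downstream fit will be unidentifiable")
  y <- predict_breakpoint(model, conc_um)
  out <- data.frame(conc_um = conc_um, intensity_au = .add_noise(y, noise))
  attr(out, "unidentifiable_warning") <- outside
  class(out) <- c("cc_series", "data.frame")
  out
}

#' Generate a cosedimentation densitometry table
#'
#' Emulates SDS-PAGE band-volume densitometry of high-speed cosedimentation
#' pellets: the bound-protein ratio follows a [sigmoid_model()] of the total
#' ligand concentration, and band volumes are constructed so that the
#' molecular-weight-corrected ratio reproduces that isotherm. Noise is added
#' to the ligand band volumes.
#'
#' @param iso a [sigmoid_model()] for the bound ratio versus concentration.
#' @param lmod_um total ligand (leiomodin) concentrations per lane,
#'   micromolar.
#' @param noise a [noise_spec()]; sigma is in ratio units.
#' @param band_volume_actin stain volume of the actin band in every lane.
#' @param mw_actin_kda,mw_lmod_kda molecular weights used for the correction.
#' @return A data frame of class `densitometry_table` with columns
#'   `lmod_total_um`, `band_volume_actin`, `band_volume_lmod` and molecular
#'   weight attributes.
#' @export
gen_cosed_table <- function(iso, lmod_um, noise = noise_spec(),
                            band_volume_actin = 1000,
                            mw_actin_kda = 42, mw_lmod_kda = 62) {
  stopifnot(inherits(iso, "sigmoid_model"))
  if (any(lmod_um < 0)) stop("concentrations must be >= 0")
  ratio <- .add_noise(predict_sigmoid(iso, lmod_um), noise)
  ratio <- pmax(ratio, 0)
  out <- data.frame(
    lmod_total_um = lmod_um,
    band_volume_actin = rep(band_volume_actin, length(lmod_um)),
    band_volume_lmod = ratio * band_volume_actin * mw_lmod_kda / mw_actin_kda)
  attr(out, "mw_actin_kda") <- mw_actin_kda
  attr(out, "mw_lmod_kda") <- mw_lmod_kda
  class(out) <- c("densitometry_table", "data.frame")
  out
}

#' Generate a stopped-flow binding transient
#'
#' Rising biexponential pyrene-fluorescence change
#' y(t) = a1 (1 - exp(-t/t1)) + a2 (1 - exp(-t/t2)), starting at zero.
#'
#' @param model a [biexp_model()].
#' @param time_s increasing grid starting at 0 (default 1000 points over
#'   0-5 s).
#' @param noise a [noise_spec()].
#' @return A data frame of class `stopped_flow_trace` with columns `time_s`,
#'   `signal_au`.
#' @export
gen_stopped_flow <- function(model,
                             time_s = seq(0, 5, length.out = 1000),
                             noise = noise_spec()) {
  stopifnot(inherits(model, "biexp_model"))
  if (time_s[1] < 0 || any(diff(time_s) <= 0))
    stop("time grid must start at >= 0 and increase")
  out <- data.frame(time_s = time_s,
                    signal_au = .add_noise(predict_biexp(model, time_s), noise))
  class(out) <- c("stopped_flow_trace", "data.frame")
  out
}

#' Generate donor emission spectra for inter-monomer FRET
#'
#' For each temperature, produces a donor-only emission spectrum (Gaussian
#' band, default peak 475 nm / width 35 nm, emulating an IAEDANS-like donor)
#' and an acceptor-present spectrum scaled by (1 - E), so the integrated
#' 435-485 nm donor band ratio F_DA / F_D equals 1 - E exactly in the
#' noiseless case.
#'
#' @param e_by_temperature data frame with columns `temperature_c` and
#'   `efficiency` (transfer efficiency, 0 <= E < 1, one row per temperature).
#' @param peak_nm,width_nm,peak_intensity donor band shape parameters.
#' @param wavelength_nm increasing grid covering at least 435-485 nm with
#'   step <= 2 nm over that band (default 380-600 nm, 1 nm).
#' @param noise a [noise_spec()].
#' @param lmod_um condition tag: ligand concentration.
#' @return A list of data frames of class `emission_spectrum` (columns
#'   `wavelength_nm`, `intensity_au`), two per temperature, with attributes
#'   `temperature_c`, `condition` ("donor-only" or "donor+acceptor") and
#'   `lmod_um`.
#' @export
gen_fret_spectra <- function(e_by_temperature, peak_nm = 475, width_nm = 35,
                             peak_intensity = 1000,
                             wavelength_nm = seq(380, 600, by = 1),
                             noise = noise_spec(), lmod_um = 0) {
  stopifnot(is.data.frame(e_by_temperature),
            all(c("temperature_c", "efficiency") %in% names(e_by_temperature)))
  e <- e_by_temperature$efficiency
  if (any(e < 0 | e >= 1)) stop("efficiencies must satisfy 0 <= E < 1")
  if (min(wavelength_nm) > 435 || max(wavelength_nm) < 485)
    stop("wavelength grid must cover 435-485 nm")
  band <- wavelength_nm >= 435 & wavelength_nm <= 485
  if (max(diff(wavelength_nm[band])) > 2)
    stop("grid step must be <= 2 nm across the integration band")
  donor <- peak_intensity * exp(-0.5 * ((wavelength_nm - peak_nm) / width_nm)^2)
  out <- list()
  for (i in seq_along(e)) {
    for (cond in c("donor-only", "donor+acceptor")) {
      scale <- if (cond == "donor-only") 1 else 1 - e[i]
      sp <- data.frame(
        wavelength_nm = wavelength_nm,
        intensity_au = pmax(.add_noise(donor * scale,
                                       .shift_seed(noise, 2L * i +
                                                     (cond == "donor+acceptor"))),
                            0))
      attr(sp, "temperature_c") <- e_by_temperature$temperature_c[i]
      attr(sp, "condition") <- cond
      attr(sp, "lmod_um") <- lmod_um
      class(sp) <- c("emission_spectrum", "data.frame")
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Generate an NADH-coupled ATPase absorbance trace
#'
#' Linearly decreasing A340 trace whose slope encodes the target ATPase
#' activity: dA/dt = -k hmm eps_path 1e-6 (k in uM_ATP/s per uM protein,
#' hmm in uM, eps_path in 1/M so the 1e-6 converts the micromolar NADH
#' oxidation rate to molar).
#'
#' @param k_target ATPase activity, uM_ATP s^-1 uM_protein^-1, >= 0.
#' @param hmm_um motor (HMM) concentration, micromolar.
#' @param eps_path molar absorptivity times path length, 1/M (default 6220
#'   for NADH at 340 nm, 1 cm path).
#' @param a0 initial absorbance.
#' @param duration_s trace duration in seconds, > 0.
#' @param n_points number of samples.
#' @param noise a [noise_spec()]; sigma in absorbance units.
#' @return A data frame of class `absorbance_trace` with columns `time_s`,
#'   `a340`.
#' @export
gen_nadh_trace <- function(k_target, hmm_um = 0.5, eps_path = 6220,
                           a0 = 0.9, duration_s = 300, n_points = 300,
                           noise = noise_spec()) {
  if (k_target < 0) stop("k_target must be >= 0")
  if (eps_path <= 0) stop("eps_path must be > 0")
  if (duration_s <= 0) stop("duration must be > 0")
  time_s <- seq(0, duration_s, length.out = n_points)
  slope <- -k_target * hmm_um * 1e-6 * eps_path
  out <- data.frame(time_s = time_s,
                    a340 = pmax(.add_noise(a0 + slope * time_s, noise), 0))
  class(out) <- c("absorbance_trace", "data.frame")
  out
}
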