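# actospec

Quantitative analysis of fluorescence-spectroscopic and enzyme-kinetic
measurements of actin assembly and actin side-binding proteins (the
motivating system is cardiac leiomodin-2, an actin filament side-binder of
the tropomodulin family). The package is aimed at protein biophysicists who
collect these assays as delimited text traces and want a tested, scriptable
alternative to per-figure spreadsheet fits.

It implements, as one coherent pipeline:

- **Fluorescence lifetimes** — multi-exponential decay fitting,
  `I(t) = Σ aᵢ exp(−t/τᵢ)`, in the time domain (polarized decay pairs,
  `I_VV + 2·G·I_VH`) and the frequency domain (phase-modulation sweeps,
  fitted jointly through the analytic Fourier transforms of the decay law),
  with amplitude- or intensity-weighted average lifetimes.
- **Anisotropy** — G-factor correction (`G = I_HV/I_HH`), the time-resolved
  ratio `r(t) = (I_VV − G·I_VH)/(I_VV + 2·G·I_VH)`, decay fits
  `r(t) = Σ r₀ᵢ exp(−t/φᵢ)` with the 0.4 fundamental-anisotropy cap, and
  steady-state anisotropy.
- **Polymerisation kinetics** — pyrene-trace rates from the slope at 50% of
  maximal change, normalisation to spontaneous assembly, buffer ionic
  strength, and the critical-concentration breakpoint fit
  `F = F_c + L_s([a]−c_c)` below / `F_c + R_s([a]−c_c)` above the break.
- **Binding** — cosedimentation densitometry ratios with molecular-weight
  correction, the Boltzmann sigmoid isotherm
  `y = (y_min−y_max)/(1+e^{(x−x₀)/dx}) + y_max`, rising biexponential
  stopped-flow fits `y(t) = A₁(1−e^{−t/t₁}) + A₂(1−e^{−t/t₂})`, and
  observed-rate-versus-concentration lines.
- **FRET flexibility** — donor-band (435–485 nm) integration,
  `E = 1 − F_DA/F_D`, the flexibility index `f′ = E/F_DA`, relative-f′
  temperature series and slope comparisons.
- **ATPase** — NADH-coupled assay rates
  `k = (−dA₃₄₀/dt)/(ε·l) · 10⁶/[HMM]` in μM_ATP s⁻¹ μM_protein⁻¹, and
  inhibition profiles versus ligand concentration.
- **Synthetic data** — a seeded generator for every raw data type above, so
  every stage is validated end to end by forward–inverse parameter
  recovery (`run_demo()`).

## Worked example

Fit a lifetime to a noisy synthetic phase/modulation sweep, then a
critical-concentration series:

```r
library(actospec)

sw  <- gen_frequency_sweep(decay_model(1, 2.92),
                           noise = noise_spec(0.002, seed = 11))
fit <- fit_intensity_decay(sw, n_components = 1)
fit
#> Fit report (decay_model)
#>   converged: TRUE  chi^2_red: 3.95e-06  iterations: 8
#>   amplitudes                1
#>   lifetimes_ns        2.91591
#>   sd: tau1 = 0.00265
average_lifetime(fit$model)
#> [1] 2.915915

s <- gen_cc_series(breakpoint_model(10, 0.8, 40, 0.12),
                   noise = noise_spec(0.2, seed = 11))
fit_critical_concentration(s)
#> Fit report (breakpoint_model)
#>   converged: TRUE  chi^2_red: 0.05261  iterations: NA
#>   f_c                 9.68226
#>   l_s                -2.52286
#>   r_s                 40.0129
#>   cc_um               0.11193
#>   sd: f_c = 0.1067, l_s = 2.5533, r_s = 0.0478, cc_um =     NA
```

The lifetime comes back as 2.916 ± 0.003 ns (truth 2.92; the 0.2%
modulation noise sets the uncertainty) and the breakpoint at 0.112 μM
(truth 0.120): at 2% intensity noise on a 9-point series the break is
recoverable to about 7%. The full forward–inverse loop over every stage:

```r
run_demo(seed = 1, sigma_scale = 0)   # noiseless: recovery to rounding error
```

prints one row per headline quantity (lifetime 2.92 ns, slow correlation
time 35.9 ns, steady-state anisotropy 0.083, critical concentration
0.12 μM, FRET efficiencies 26%/32%, ATPase activities 0.04/0.164,
12-/4-fold rate enhancements, 40% residual activity) with the recovered
value and relative error; with `sigma_scale = 1` the same loop runs at
realistic noise. See `vignettes/methods.Rmd` for the models, their
assumptions and the numerical choices.

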