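# pigmentnoise

Visual pigments occasionally activate in darkness by thermal energy alone,
producing electrical events in photoreceptors that are indistinguishable
from single-photon responses. This "dark noise" sets a floor on visual
sensitivity, and its rate differs enormously between rod and cone
pigments. `pigmentnoise` is an R package for quantifying spontaneous
pigment activation three independent ways and checking them against each
other:

1. **Theory.** A statistical-mechanical prediction of the molecular
   thermal-activation rate constant from the pigment's peak absorption
   wavelength λ_max,

   k = A · e^(−x) · Σ_{j=0}^{m−1} x^j / j!,  x = 0.84 · N_A h c / (R T λ_max),

   where m is the nominal number of vibrational modes contributing
   thermal energy, and the attempt frequency A takes one of two empirical
   values: 7.19 × 10⁻⁶ s⁻¹ for pigments with a "closed"
   chromophore-binding pocket (rods) and 1.88 × 10⁻⁴ s⁻¹ for "open"
   pockets (cones) — a 26-fold difference. The truncated exponential sum
   (a Hinshelwood factor) is the probability weight that m classical
   modes jointly supply the barrier energy x·RT.

2. **Dark-current recordings.** Two estimators of the cellular event rate
   from ~10-min suction-pipette recordings in darkness: direct counting
   of quantal events under amplitude (>30% of the single-photon response)
   and kinetics (integration time within 50–200% of the dim-flash
   response) criteria, with a Poisson epoch analysis of the counts; and
   the power-spectral-density difference method, which fits the spectrum
   of the events (full-trace PSD minus quiet-segment PSD, 8.192-s Welch
   segments with 50% overlap) with a scaled power spectrum of the
   single-photon response. Cellular rates convert to molecular rate
   constants via the pigment content (6.5 × 10⁷ molecules per mouse rod).

3. **Microspectrophotometry.** Absorbance-spectrum analysis for the
   chromophore-exchange assay of binding-pocket openness: Beer's-law OD,
   baseline correction, λ_max estimation, degree-10 polynomial isomer
   templates, non-negative unmixing of 11-cis/9-cis pigment fractions
   over 510–750 nm, and saturating-exponential exchange kinetics
   a(1 − e^(−t/τ)). Photochemistry calculators (bleaching fraction
   F = 1 − e^(−IPt), photon-capture collecting area, retinoid
   concentrations) round out the workflow.

A synthetic-data generator (`simulate_dark_trace()`,
`simulate_flash_ensemble()`, `simulate_spectrum()`,
`simulate_exchange_timecourse()`) reproduces the statistical structure of
the real measurements — Poisson-timed quantal events on filtered Gaussian
noise, Poisson photon capture, nomogram-shaped pigment spectra — so every
analysis stage is testable end to end without raw recordings.

## Worked example

Predict the thermal rate of a 481-nm pigment at 37.5 °C, then recover the
event rate from a simulated 600-s dark recording:

```r
library(pigmentnoise)

pred <- predict_rate_constant(pigment_params(481, pocket = "closed"))
pred
#> Thermal-activation rate prediction
#>   k  = 3.727e-11 s^-1 per molecule
#>   x  = 80.9219 (barrier ratio)
#>   sum = 7.22127e+29 (m = 45 terms)

cellular_rate_from_molecular(pred$k_molecular)
#> [1] 0.002423   # predicted events s^-1 cell^-1 for 6.5e7 molecules

spr <- make_spr_template()                  # 2 pA quantal event, T_i ~ 0.54 s
sim <- simulate_dark_trace(duration = 600, event_rate = 0.0024, seed = 4)
ev  <- detect_events(sim$trace, spr)
counting_rate(ev)
#> Rate estimate (counting): 0.003333 s^-1 cell^-1   # 2 events / 600 s

poisson_fit(epoch_counts(ev, duration = 600))$w
#> [1] 0.3333   # events per 100 s epoch

full  <- welch_psd(sim$trace)
quiet <- welch_psd(select_quiet_segment(sim$trace, 60))
fit_rate_from_psd(difference_spectrum(full, quiet), spr)
#> Rate estimate (psd): 0.003364 s^-1 cell^-1

molecular_rate(counting_rate(ev)$rate)
#> [1] 5.128e-11   # s^-1 per molecule
```

The counting and PSD estimators agree with each other and scatter around
the simulated truth (a single 600-s cell at 0.0024 s⁻¹ holds only ~1.4
events, so per-cell estimates are Poisson-noisy; averaging across cells
or seeds converges to the configured rate). Chromophore-exchange
kinetics, fitted on a synthetic time course generated at a 9-cell,
3-hour design:

```r
tc <- simulate_exchange_timecourse(asymptote = 0.72, tau = 37, seed = 3)
fit_exchange_kinetics(tc)
#> Exchange kinetics: a = 0.743 +/- 0.028, tau = 41.7 +/- 5.6 min
```

## Vignette

`vignettes/pigment-dark-noise.Rmd` documents the model and its
assumptions, all tunable parameters with units and defaults, what the
synthetic generator does and does not emulate, and the package's
numerical and design choices.
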