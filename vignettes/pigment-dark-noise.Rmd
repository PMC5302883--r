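---
title: "Quantifying spontaneous visual-pigment activation: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spontaneous visual-pigment activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentnoise)
```

# The problem

A visual pigment is a protein (opsin) holding a retinal chromophore; it
is built to isomerize when it absorbs a photon, but very rarely the same
isomerization happens by thermal energy alone. In a rod photoreceptor
each such spontaneous activation triggers an electrical event identical
to a single-photon response, so the thermal rate is measurable as
discrete "dark noise" — and it matters, because it sets the false-photon
floor of scotopic vision. The rate spans orders of magnitude between
pigments: a mouse rod holds ~6.5 × 10⁷ rhodopsin molecules yet produces
only a few thousandths of an event per second, while cone pigments of
comparable spectral tuning are far noisier.

This package implements three mutually checking routes to the rate: a
thermodynamic prediction from the pigment's absorption peak, two
estimators applied to dark-current recordings, and a
microspectrophotometric assay of the chromophore-binding pocket whose
openness accounts for the rod/cone difference in noise.

# The thermal-activation model

`predict_rate_constant()` evaluates

$$k \;=\; A\, e^{-x} \sum_{j=0}^{m-1} \frac{x^j}{j!},
\qquad
x \;=\; \frac{0.84\, N_A h c}{R\,T\,\lambda_{max}} .$$

The physical picture: the activation barrier is a fixed fraction (0.84)
of the photon energy at $\lambda_{max}$, and the molecule can pool
thermal energy from $m$ classical vibrational modes. The factor
$e^{-x}\sum_{j<m} x^j/j!$ is then the upper-tail probability of a
Poisson distribution — the chance that the pooled modes supply at least
the barrier energy — multiplied by an attempt frequency $A$. Two
empirical $A$ values are built in: $7.19\times10^{-6}$ s⁻¹ for pigments
with a *closed* chromophore-binding pocket (rod pigments) and
$1.88\times10^{-4}$ s⁻¹ for *open* pockets (cone pigments), a 26-fold
ratio. With $m = 45$, $T = 310.5$ K and $\lambda_{max} = 481$ nm the
model gives $3.7\times10^{-11}$ s⁻¹ (closed) and $9.7\times10^{-10}$
s⁻¹ (open).

Three conventions deserve explicit statement because the formula is
often quoted loosely:

* **Units of the exponent.** $hc/\lambda$ is a per-photon energy while
  $RT$ is molar; we multiply by $N_A$ (equivalently, use $k_BT$ per
  molecule) so that $x$ is dimensionless. This is the only reading under
  which the published closed/open predictions are reproduced.
* **Number of terms.** The sum runs over $m$ terms, $j = 0,\dots,m-1$.
  The alternative ($m-1$ terms) fails to reproduce the same predictions.
* **Constant precision.** `physical_constants("precise")` (CODATA,
  thermochemical calorie) is the default and reproduces the predictions
  above to ~1–2%. `physical_constants("printed")` carries the rounded
  three-figure constants often quoted (h = 1.58 × 10⁻³⁷ kcal s,
  c = 3.00 × 10¹⁷ nm/s, R = 1.99 × 10⁻³ kcal K⁻¹ mol⁻¹); because they
  sit in the exponent at $x \approx 81$, the ~0.3% shift in $x$ moves
  $k$ by 10–15%. Both presets are exposed and tested; use "printed" only
  to reproduce a calculation performed with rounded constants.

Numerically the sum is accumulated by the recurrence
$t_{j+1} = t_j\,x/(j+1)$ and, inside the rate, in the log domain
(log-sum-exp), so $x^j$, $j!$ and $e^{-x}$ never overflow or underflow
for $x$ up to several hundred. Against a 50-digit arbitrary-precision
evaluation the double-precision sum agrees to better than $10^{-8}$
relative error over $x \in [0, 200]$, $m \in [1, 60]$.

# Dark-noise estimators

## Single-photon response

`single_photon_response()` applies ensemble fluctuation analysis to
repeated identical dim flashes: with Poisson photon capture, the
trial-to-trial variance-to-mean ratio of the response at the time of the
mean response's transient peak equals the single-photon amplitude $a$.
The mean profile scaled to $a$ is the single-photon waveform $f(t)$.
The peak sample is the single sample at the mean-response maximum
(earliest sample on ties, no averaging window); a zero-variance ensemble
is flagged degenerate rather than silently returning 0/0. The
*integration time* $T_i = \int f\,dt / \max f$ is the kinetics summary
used by the event detector; for a rectangular pulse it is the width, for
an exponential decay the time constant.

## Direct counting

`detect_events()` implements the two published acceptance criteria —
amplitude > 30% of the single-photon amplitude, integration time within
50–200% of the dim-flash $T_i$ — on a trace low-pass filtered at 3 Hz.
The criteria do not by themselves define a detector, so the package
supplies one and documents it:

* zero-phase 4-pole Butterworth filtering (`signal::filtfilt`), so event
  times are not delayed by the filter;
* median baseline subtraction;
* candidate deflections delimited by crossings of 20% of the *filtered*
  template amplitude — the template is passed through the same 3-Hz
  filter before its amplitude is used, keeping the criterion's numerator
  and denominator comparable;
* candidates closer than one integration time are merged (a single
  quantal event can graze the threshold twice);
* each candidate window is extended to its surrounding zero crossings
  (capped at three integration times each side), and its amplitude and
  integration time are measured there and tested against the criteria.

`counting_rate()` divides accepted events by recording time;
`epoch_counts()` + `poisson_fit()` divide the record into complete
100-s epochs (a trailing partial epoch is discarded so all counts have
equal exposure) and fit $p(u) = w^u e^{-w}/u!$ by maximum likelihood,
i.e. $\hat w$ = sample mean. MLE is chosen over least squares on the
histogram; the two coincide asymptotically and MLE is exact at small
counts.

## Power-spectrum difference

`welch_psd()` computes a one-sided averaged periodogram in 8.192-s
segments with 50% overlap, Hann window with power normalization, and
per-segment mean removal; the density integrates to the trace variance
(Parseval). The *difference spectrum* — full dark record minus a quiet
segment — isolates the spontaneous events' spectrum;
`fit_rate_from_psd()` fits it with a scaled power spectrum of $f(t)$
and reads the rate as scale ÷ 8.192 s. For a Poisson event train at
rate $r$ the expected one-sided event spectrum is $2r|F(f)|^2$, which
under this normalization is exactly $r \times$ segment-time $\times$
the template periodogram: the read-out is unbiased by construction, and
simulations confirm it (mean within a few percent at the rates of
interest).

Choices the method statement leaves open, fixed here:

* **Quiet-segment selection** was done by visual inspection in practice;
  `select_quiet_segment()` automates it as the minimum-variance
  contiguous segment (60 s default).
* **Fit band** 0.1–5 Hz: above the drift-dominated lowest bins, below
  the 20-Hz acquisition filter; the DC bin is always excluded.
  Unweighted least squares through the origin; a negative fitted scale
  (possible when a trace holds no events) is clipped to rate 0 with a
  warning.
* **Windowing**: the data spectrum uses a power-normalized Hann window
  (unbiased for broadband spectra); the template, being compactly
  supported and zero-padded, is transformed without a taper. Mixing
  conventions here would bias the scale factor at first order only
  through the window's noise bandwidth, which the power normalization
  removes.

## Pigment content and photochemistry

`collecting_area()` inverts $p_s = 1 - e^{-A_e I}$ for the outer
segment's effective collecting area (proportional to pigment content);
`bleach_fraction()` evaluates the same single-hit law
$F = 1 - e^{-IPt}$ for bleaching exposures (with the in-situ
photosensitivity $P = 5.7\times10^{-9}$ µm², the standard 16-min
exposure at $1.33\times10^6$ photons µm⁻² s⁻¹ gives $F > 99\%$); both
share one implementation of $1 - e^{-x}$. `molecular_rate()` /
`cellular_rate_from_molecular()` convert between per-cell and
per-molecule rates via the pigment count (default $6.5\times10^7$).

# Microspectrophotometry

Spectra are handled as (wavelength, OD) tables on a 2-nm grid, 300–700
nm typical. `baseline_correct()` subtracts a line fitted over 650–700 nm
(pigment-free for pigments peaking ≤ ~570 nm; configurable).
`estimate_lambda_max()` smooths lightly (5-sample running mean), finds
the raw maximum in the α-band search range, and fits a quadratic within
±12 nm; the vertex gives sub-grid resolution. The ±12 nm window is a
deliberate compromise: the α-band is asymmetric, and wider windows bias
the parabola vertex short by more than half a grid step (−0.7 nm at
±20 nm), while ±12 nm keeps the bias below 0.5 nm across 420–560 nm
pigments and still averages ~13 grid points of noise.

For the chromophore-exchange assay, mean spectra of the pure 11-cis and
9-cis pigments are summarized as degree-10 polynomials
(`fit_template()`), fitted on a wavelength axis rescaled to $[-1,1]$ so
the Vandermonde system stays well conditioned. `unmix_fraction()` then
fits each time-point spectrum over 510–750 nm (the long-wavelength
pigment's range; pigment-specific in general) with a *non-negative*
linear combination of the two templates and reports
$c_9/(c_{11}+c_9)$. Non-negativity is imposed because small noise can
otherwise drive one coefficient negative and the fraction outside
$[0,1]$; on noiseless mixtures the recovered fraction equals the mixing
fraction to $<10^{-6}$, so the constraint is inactive where it should
be. `fit_exchange_kinetics()` fits $a(1-e^{-t/\tau})$ with both
parameters free (Levenberg–Marquardt via `minpack.lm`, self-starting
from the data), returning parameter standard errors.

# The synthetic-data generator

The generator produces data with the statistical structure the
estimators assume, at the study's own conditions:

* `simulate_dark_trace()`: homogeneous Poisson event times at the
  configured rate (the biological range of interest is ~0.002–0.015
  s⁻¹), one single-photon waveform added per event, white Gaussian
  noise, and a zero-phase 20-Hz low-pass emulating the acquisition
  filter; 600-s, 1-kHz defaults match a ~10-min recording. Ground-truth
  event times are returned for closure tests.
* `make_spr_template()`: the waveform family
  $a\,(t/t_p)^n e^{n(1-t/t_p)}$ with $n = t_p/\tau_{rec}$; defaults
  (2 pA, $t_p$ = 0.36 s, $\tau_{rec}$ = 0.12 s, so $T_i \approx 0.54$ s)
  emulate the enlarged, slow quantal events of rods lacking fast
  calcium feedback (the preparation that makes single events
  resolvable). $T_i$ has the closed form
  $t_p e^n n^{-(n+1)}\Gamma(n+1)$, used as an analytic oracle in tests.
* `simulate_flash_ensemble()`: per-trial photon counts
  Poisson($A_e I$), so the non-failure fraction follows
  $1-e^{-A_e I}$ and variance-to-mean analysis recovers the template
  amplitude.
* `pigment_template_spectrum()`: the standard A1-pigment α-band
  nomogram shape in the $\lambda_{max}/\lambda$ coordinate (a
  log-Gaussian fallback is included); `simulate_spectrum()` adds linear
  baseline drift and scan-averaged measurement noise (10 scans
  default).
* `simulate_exchange_timecourse()`: the saturating exponential with
  between-cell scatter averaged over $n$ cells; defaults follow a
  9-cell, 3-hour design with asymptote 0.72 and τ = 37 min.

**Noise level.** The white-noise SD defaults to 1.5 pA at 1 kHz, leaving
~0.12 pA after the 3-Hz counting filter against 2-pA events. This puts
detection in the clearly resolved regime the counting method requires:
at the 30% amplitude criterion (~0.6 pA ≈ 5 filtered-noise SDs) the
false-positive rate on event-free noise is negligible, which is a
precondition for unbiased counting at rates as low as 0.002 s⁻¹ (where
even one false event per 600-s trace would be a 70% error). Noisier
regimes can be simulated explicitly, but they are not the regime in
which the two-criterion counting method is meaningful.

**What the generator does not emulate**, and hence what passing tests do
not show about real data: correlated (non-white) instrumentation noise
and slow baseline drift; cell-to-cell variability of the single-photon
amplitude and kinetics; amplitude compression when events overlap;
photoproduct (β-band, meta-state) contributions to spectra; and any
deviation of real event statistics from a homogeneous Poisson process.
The estimators' behaviour under those conditions must be judged on real
recordings.

# Determinism and problem sizes

Every generator takes a `seed` and restores the caller's RNG state, so
fixed seeds give bit-identical data without leaking state between
calls. The test suite exercises the full closure — generate → detect →
count, and generate → PSD → rate — at 0.002 and 0.015 s⁻¹ over 20 seeds
of 300-s traces, plus Poisson dispersion and goodness-of-fit checks on
pooled epochs; the whole suite runs in well under a minute. The
acceptance script uses 600-s traces (100 seeds at the low rate, 60 at
the high) so that the Poisson standard error of the mean recovered rate
is below ~8%; these sizes are the package's accuracy/runtime trade-off
and can be scaled up freely.

# Known limitations

* The event detector is a reasonable reference implementation of the
  published criteria, not a matched filter; at signal-to-noise ratios
  much below the default it will both miss events and pass noise, and
  no claim is made there.
* The PSD estimator inherits the variance of single-trace spectra; on
  one 600-s cell its scatter is large (of order ±50% at 0.0025 s⁻¹),
  matching its role as a cross-check of counting rather than a
  replacement.
* λ_max estimation assumes a single α-band peak inside the search
  range; mixed-pigment spectra should be unmixed first.
* The unmixing range default (510–750 nm) is appropriate for
  long-wavelength cone pigments; other pigment classes need a range
  chosen for their spectral separation.
* The thermal model treats 0.84 and the two $A$ values as fixed
  empirical constants; fitting them, or deriving them from molecular
  theory, is out of scope.
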