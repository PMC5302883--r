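# Run code with a locally seeded RNG, restoring global state afterwards
# so generator calls never leak state into (or absorb state from) callers.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parametric single-photon response template
#'
#' Smooth unimodal waveform of the gamma-like family
#' \eqn{f(t) = a (t/t_p)^n e^{n (1 - t/t_p)}} with `n = time_to_peak /
#' recovery_tau`, peaking at exactly `time_to_peak` with value
#' `peak_amplitude` and decaying with time constant `recovery_tau`. Its
#' integration time has the closed form
#' \eqn{T_i = t_p e^n n^{-(n+1)} \Gamma(n+1)}.
#'
#' Defaults (2 pA, 0.36 s to peak, 0.12 s recovery, so n = 3 and
#' T_i = 0.54 s) emulate the enlarged, slow quantal events of rods
#' lacking GCAPs-mediated fast calcium feedback, the preparation in which
#' dark events are individually resolvable.
#'
#' @param peak_amplitude Peak amplitude a (pA); default 2.
#' @param time_to_peak Time of the peak t_p (s); default 0.36.
#' @param recovery_tau Final decay time constant (s); default 0.12.
#' @param sampling_rate Sampling rate (Hz); default 1000.
#' @return A [single_photon_response()] whose waveform is truncated where
#'   it falls below 1e-6 of the peak.
#' @export
make_spr_template <- function(peak_amplitude = 2, time_to_peak = 0.36,
                              recovery_tau = 0.12, sampling_rate = 1000) {
  if (peak_amplitude <= 0 || time_to_peak <= 0 || recovery_tau <= 0 ||
      sampling_rate <= 0)
    stop("all template parameters must be positive")
  n <- time_to_peak / recovery_tau
  # find the truncation point: f/a < 1e-6 past the peak
  t_end <- time_to_peak
  while (( (t_end / time_to_peak)^n * exp(n * (1 - t_end / time_to_peak)) ) >
           1e-6)
    t_end <- t_end + recovery_tau
  t <- seq(0, t_end, by = 1 / sampling_rate)
  f <- peak_amplitude * (t / time_to_peak)^n * exp(n * (1 - t / time_to_peak))
  f[1] <- 0
  spr_from_waveform(f, sampling_rate)
}

#' Closed-form integration time of the template family
#'
#' \eqn{T_i = t_p e^n n^{-(n+1)} \Gamma(n+1)} for the waveform family of
#' [make_spr_template()]; analytic check value for the numerical
#' [integration_time()].
#'
#' @param time_to_peak,recovery_tau Template parameters (s).
#' @return Integration time (s).
#' @export
template_integration_time <- function(time_to_peak, recovery_tau) {
  n <- time_to_peak / recovery_tau
  time_to_peak * exp(n + lgamma(n + 1) - (n + 1) * log(n))
}

#' Simulate a dark-current recording with spontaneous quantal events
#'
#' Generates a suction-pipette-like dark recording: event times are drawn
#' as a homogeneous Poisson process at `event_rate`, each event adds one
#' single-photon response waveform, white Gaussian instrumentation noise
#' of SD `noise_sd` is added, and the summed trace is passed through a
#' zero-phase low-pass at `acquisition_filter_hz` emulating the recording
#' filter. The ground-truth event times are returned alongside the trace.
#'
#' The default noise SD (1.5 pA white at 1 kHz) leaves about 0.12 pA of
#' noise after the 3 Hz counting filter, so default 2 pA events stand
#' clear of the noise as they do in recordings from rods lacking GCAPs
#' feedback.
#'
#' @param duration Recording length (s); default 600 (a ~10 min dark
#'   record).
#' @param event_rate True spontaneous event rate (s^-1); the biological
#'   regime of interest is roughly 0.002-0.015.
#' @param spr Event waveform, a [single_photon_response()];
#'   default [make_spr_template()].
#' @param noise_sd SD of the white continuous noise before filtering
#'   (pA); default 1.5.
#' @param sampling_rate Sampling rate (Hz); default 1000.
#' @param acquisition_filter_hz Acquisition low-pass cutoff (Hz);
#'   default 20.
#' @param seed Integer seed fixing the realization; `NULL` uses the
#'   current RNG state.
#' @return List with `trace` (a [current_trace()]) and `events` (a
#'   ground-truth [event_list()] of true event start times).
#' @export
simulate_dark_trace <- function(duration = 600, event_rate = 0.005,
                                spr = make_spr_template(),
                                noise_sd = 1.5, sampling_rate = 1000,
                                acquisition_filter_hz = 20, seed = NULL) {
  if (duration <= 0 || event_rate < 0 || noise_sd < 0)
    stop("invalid simulation parameters")
  .with_seed(seed, {
    n <- round(duration * sampling_rate)
    x <- numeric(n)
    n_ev <- stats::rpois(1, event_rate * duration)
    t_ev <- sort(stats::runif(n_ev, 0, duration))
    wf <- spr$waveform
    if (spr$sampling_rate != sampling_rate)
      stop("`spr` sampling rate must match the trace sampling rate")
    for (te in t_ev) {
      i0 <- floor(te * sampling_rate) + 1L
      i1 <- min(n, i0 + length(wf) - 1L)
      if (i0 <= n) x[i0:i1] <- x[i0:i1] + wf[seq_len(i1 - i0 + 1L)]
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
    tr <- current_trace(x, sampling_rate)
    if (!is.null(acquisition_filter_hz) && acquisition_filter_hz > 0)
      tr <- lowpass_trace(tr, acquisition_filter_hz)
    list(trace = tr,
         events = event_list(t_ev, duration = duration))
  })
}

#' Simulate a dim-flash trial ensemble
#'
#' Repeated identical dim flashes with Poisson photon capture: per-trial
#' photon count ~ Poisson(A_e * I); each trial is the count times the
#' single-photon waveform plus filtered Gaussian noise. The fraction of
#' non-failure trials follows \eqn{p_s = 1 - e^{-A_e I}}.
#'
#' @param A_e Effective collecting area (um^2).
#' @param I Flash intensity (photons um^-2 flash^-1).
#' @param n_trials Number of trials.
#' @param spr Event waveform ([make_spr_template()] by default).
#' @param noise_sd White-noise SD before filtering (pA); default 1.5.
#' @param acquisition_filter_hz Acquisition low-pass (Hz); default 20.
#' @param pre_s Baseline time before flash onset (s); default 0.5.
#' @param seed Integer seed or `NULL`.
#' @return A [flash_ensemble()] with ground-truth photon counts as
#'   attribute `photons`.
#' @export
simulate_flash_ensemble <- function(A_e, I, n_trials, spr = make_spr_template(),
                                    noise_sd = 1.5,
                                    acquisition_filter_hz = 20,
                                    pre_s = 0.5, seed = NULL) {
  if (A_e < 0 || I < 0 || n_trials < 1)
    stop("invalid ensemble parameters")
  .with_seed(seed, {
    fs <- spr$sampling_rate
    n_pre <- round(pre_s * fs)
    n <- n_pre + length(spr$waveform)
    photons <- stats::rpois(n_trials, A_e * I)
    clean <- c(numeric(n_pre), spr$waveform)
    trials <- vapply(seq_len(n_trials), function(i) {
      y <- photons[i] * clean
      if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
      if (!is.null(acquisition_filter_hz) && acquisition_filter_hz > 0)
        y <- lowpass_trace(current_trace(y, fs),
                           acquisition_filter_hz)$current
      y
    }, numeric(n))
    structure(flash_ensemble(trials, fs, flash_intensity = I,
                             flash_time = pre_s),
              photons = photons)
  })
}

#' Visual-pigment absorbance template spectrum
#'
#' Normalized alpha-band absorbance of an A1 (retinal-based) visual
#' pigment at a given peak wavelength, using the standard
#' Govardovskii-style nomogram parameterization in the
#' \eqn{x = \lambda_{max}/\lambda} coordinate (so templates at different
#' lambda_max are shifted copies in that coordinate). A simple
#' log-Gaussian fallback form is also available.
#'
#' @param lambda_max Peak wavelength (nm), inside the grid.
#' @param wavelength Wavelength grid (nm); default seq(300, 700, 2).
#' @param form `"govardovskii"` (default) or `"lognormal"`.
#' @return An [absorbance_spectrum()] with peak OD 1 at `lambda_max`.
#' @export
pigment_template_spectrum <- function(lambda_max,
                                      wavelength = seq(300, 700, by = 2),
                                      form = c("govardovskii", "lognormal")) {
  form <- match.arg(form)
  if (lambda_max < min(wavelength) || lambda_max > max(wavelength))
    stop("`lambda_max` must lie within the wavelength grid")
  od <- .alpha_band(lambda_max, wavelength, form)
  pk <- .alpha_band(lambda_max, lambda_max, form) # normalize at the peak
  absorbance_spectrum(wavelength, od / max(pk, max(od)),
                      normalized = TRUE, baseline_corrected = TRUE)
}

.alpha_band <- function(lambda_max, wavelength, form) {
  x <- lambda_max / wavelength
  if (form == "govardovskii") {
    A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
    b <- 0.922; cc <- 1.104
    a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
    1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  } else {
    exp(-log(2) * (log(x) / log(1.06))^2) # log-Gaussian, ~30 nm half-width
  }
}

#' Simulate a measured absorbance spectrum
#'
#' Noisy single-cell (or averaged) absorbance measurement: a pigment
#' template spectrum at `lambda_max` scaled to `peak_od`, plus a linear
#' baseline drift and white measurement noise reduced by scan averaging
#' (`n_scans` averaged scans, emulating routine microspectrophotometric
#' practice).
#'
#' @param lambda_max Peak wavelength (nm).
#' @param wavelength Grid (nm); default seq(300, 700, 2).
#' @param peak_od Peak optical density; default 1.
#' @param noise_sd Per-scan OD noise SD; default 0.05.
#' @param n_scans Number of averaged scans; default 10.
#' @param baseline_drift Linear baseline slope (OD per nm); default 0.
#' @param form Template form, see [pigment_template_spectrum()].
#' @param seed Integer seed or `NULL`.
#' @return An [absorbance_spectrum()] (not baseline-corrected or
#'   normalized).
#' @export
simulate_spectrum <- function(lambda_max, wavelength = seq(300, 700, by = 2),
                              peak_od = 1, noise_sd = 0.05, n_scans = 10,
                              baseline_drift = 0,
                              form = c("govardovskii", "lognormal"),
                              seed = NULL) {
  form <- match.arg(form)
  .with_seed(seed, {
    tpl <- pigment_template_spectrum(lambda_max, wavelength, form)
    od <- peak_od * tpl$od +
      baseline_drift * (wavelength - wavelength[1]) +
      stats::rnorm(length(wavelength), sd = noise_sd / sqrt(n_scans))
    absorbance_spectrum(wavelength, od)
  })
}

#' Simulate a chromophore-exchange time course
#'
#' Mean 9-cis fraction following the saturating exponential
#' \eqn{a (1 - e^{-t/\tau})}, with Gaussian per-cell unmixing noise
#' reduced by averaging over `n_cells` cells. Defaults follow the design
#' of a long-wavelength cone exchange experiment: 9 cells followed over
#' 3 hours with an asymptote of 0.72 and a 37 min time constant.
#'
#' @param asymptote Plateau fraction a; default 0.72.
#' @param tau Time constant (min); default 37.
#' @param times Sampling times (min); default seq(0, 180, 20).
#' @param noise_sd Per-cell SD of the unmixed fraction; default 0.15.
#' @param n_cells Cells averaged per point; default 9.
#' @param seed Integer seed or `NULL`.
#' @return An [exchange_timecourse()] whose `sd` column is the
#'   between-cell SD of each mean.
#' @export
simulate_exchange_timecourse <- function(asymptote = 0.72, tau = 37,
                                         times = seq(0, 180, by = 20),
                                         noise_sd = 0.15, n_cells = 9,
                                         seed = NULL) {
  if (asymptote <= 0 || asymptote > 1 || tau <= 0)
    stop("need 0 < asymptote <= 1 and tau > 0")
  .with_seed(seed, {
    mu <- asymptote * (1 - exp(-times / tau))
    se <- noise_sd / sqrt(n_cells)
    frac <- mu + stats::rnorm(length(times), sd = se)
    frac <- pmin(pmax(frac, -0.1), 1.1)
    exchange_timecourse(times, frac, sd = rep(noise_sd, length(times)))
  })
}
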