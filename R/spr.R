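#' Flash-trial ensemble
#'
#' A set of repeated dim-flash trials from one cell, aligned to flash
#' onset, used to estimate the single-photon response by fluctuation
#' analysis.
#'
#' @param trials Numeric matrix of current (pA), one column per trial,
#'   rows = time samples aligned to flash onset at `flash_time`.
#' @param sampling_rate Sampling rate (Hz).
#' @param flash_intensity Flash strength (photons um^-2 flash^-1), >= 0.
#' @param flash_time Time of flash onset relative to the first row (s).
#' @return An object of class `flash_ensemble`.
#' @export
flash_ensemble <- function(trials, sampling_rate, flash_intensity = NA_real_,
                           flash_time = 0) {
  if (!is.matrix(trials) || !is.numeric(trials) || ncol(trials) < 1)
    stop("`trials` must be a numeric matrix with one column per trial")
  if (!is.na(flash_intensity) && flash_intensity < 0)
    stop("`flash_intensity` must be >= 0")
  structure(
    list(trials = trials, sampling_rate = sampling_rate,
         flash_intensity = flash_intensity, flash_time = flash_time),
    class = "flash_ensemble"
  )
}

#' Integration time of a response waveform
#'
#' Kinetics summary of a photoresponse: the time integral of the waveform
#' divided by its peak amplitude,
#' \eqn{T_i = \int r(t)\,dt / \max r(t)}.
#' For a rectangular pulse this is the pulse width; for a decaying
#' exponential it is the time constant.
#'
#' @param waveform Numeric vector of response samples (pA), or a
#'   `single_photon_response`.
#' @param sampling_rate Sampling rate (Hz); taken from the object when a
#'   `single_photon_response` is given.
#' @return Integration time (s).
#' @export
integration_time <- function(waveform, sampling_rate = NULL) {
  if (inherits(waveform, "single_photon_response")) {
    sampling_rate <- waveform$sampling_rate
    waveform <- waveform$waveform
  }
  if (is.null(sampling_rate)) stop("`sampling_rate` is required")
  pk <- max(waveform)
  if (!is.finite(pk) || pk <= 0)
    stop("waveform has no positive peak; integration time undefined")
  sum(waveform) / sampling_rate / pk
}

#' Estimate the single-photon response from a dim-flash ensemble
#'
#' Fluctuation analysis of repeated identical dim flashes. At the time of
#' the transient peak of the ensemble mean response, photon-count
#' fluctuations make the trial-to-trial variance-to-mean ratio equal to
#' the single-photon response amplitude (Poisson photon capture; the
#' quantal event adds `a` pA per photon, so Var/Mean = a at the peak).
#' The mean response profile is then scaled to that amplitude to give the
#' single-photon response waveform f(t).
#'
#' The peak sample is the single sample at the maximum of the mean
#' response at or after flash onset (earliest sample on ties). When the
#' ensemble variance at the peak is zero the response carries no photon
#' fluctuation information; the returned object has amplitude 0 and its
#' `degenerate` flag set.
#'
#' @param ensemble A [flash_ensemble()] with at least 2 trials.
#' @return An object of class `single_photon_response`: list with
#'   `waveform` (pA, from flash onset), `sampling_rate`, `amplitude` (pA),
#'   `peak_time` (s after flash onset), `integration_time` (s) and
#'   `degenerate` flag.
#' @export
single_photon_response <- function(ensemble) {
  stopifnot(inherits(ensemble, "flash_ensemble"))
  tr <- ensemble$trials
  if (ncol(tr) < 2) stop("need at least 2 trials for fluctuation analysis")
  fs <- ensemble$sampling_rate
  i_on <- max(1L, floor(ensemble$flash_time * fs) + 1L)
  mu <- rowMeans(tr)
  pk <- i_on - 1L + which.max(mu[i_on:length(mu)]) # earliest max
  if (!is.finite(mu[pk]) || mu[pk] <= 0)
    stop("mean response has no positive peak after flash onset")
  v <- stats::var(tr[pk, ])
  a <- v / mu[pk]
  degenerate <- v == 0
  wf <- mu[i_on:length(mu)] * (if (degenerate) 1 else a / mu[pk])
  ti <- integration_time(wf, fs)
  structure(
    list(waveform = wf, sampling_rate = fs, amplitude = a,
         peak_time = (pk - i_on) / fs, integration_time = ti,
         degenerate = degenerate),
    class = "single_photon_response"
  )
}

#' @export
print.single_photon_response <- function(x, ...) {
  cat(sprintf(
    "Single-photon response: a = %.3g pA, T_i = %.3g s, peak at %.3g s%s\n",
    x$amplitude, x$integration_time, x$peak_time,
    if (x$degenerate) " [degenerate: zero ensemble variance]" else ""))
  invisible(x)
}

#' Construct a single-photon response directly from a waveform
#'
#' Wraps an explicit waveform (e.g. a simulated template or an averaged
#' response already scaled to quantal amplitude) as a
#' `single_photon_response`.
#'
#' @param waveform Numeric vector (pA), from flash onset.
#' @param sampling_rate Sampling rate (Hz).
#' @return A `single_photon_response`.
#' @export
spr_from_waveform <- function(waveform, sampling_rate) {
  pk <- which.max(waveform)
  a <- waveform[pk]
  if (a <= 0) stop("waveform has no positive peak")
  structure(
    list(waveform = as.numeric(waveform), sampling_rate = sampling_rate,
         amplitude = a, peak_time = (pk - 1) / sampling_rate,
         integration_time = integration_time(waveform, sampling_rate),
         degenerate = FALSE),
    class = "single_photon_response"
  )
}
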