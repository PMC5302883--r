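#' Welch power spectral density of a current trace
#'
#' One-sided averaged periodogram of a dark-current recording, computed
#' from overlapping segments (8.192 s with 50% overlap by default) with a
#' power-normalized Hann window and per-segment mean removal. The
#' normalization satisfies Parseval's relation: the density integrates to
#' the trace variance, \eqn{\sum S(f)\,\Delta f = \mathrm{Var}(I)}, with
#' \eqn{\Delta f = 1/segment\_length}.
#'
#' @param trace A [current_trace()] at least one segment long.
#' @param segment_length Segment length (s); default 8.192.
#' @param overlap Fractional overlap between segments; default 0.5.
#' @param window `"hann"` or `"rectangle"`.
#' @param demean Remove each segment's mean before transforming
#'   (suppresses the DC leakage from slow drift); default TRUE.
#' @return A `power_spectrum`: data frame with columns `frequency` (Hz)
#'   and `density` (pA^2/Hz), with attributes `segment_length`, `overlap`,
#'   `n_segments` and `sampling_rate`.
#' @export
welch_psd <- function(trace, segment_length = 8.192, overlap = 0.5,
                      window = c("hann", "rectangle"), demean = TRUE) {
  stopifnot(inherits(trace, "current_trace"))
  window <- match.arg(window)
  fs <- trace$sampling_rate
  n <- round(segment_length * fs)
  x <- trace$current
  if (length(x) < n)
    stop("trace shorter than one segment (", segment_length, " s)")
  hop <- max(1L, round(n * (1 - overlap)))
  starts <- seq(1L, length(x) - n + 1L, by = hop)

  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
       else rep(1, n)
  U <- mean(w^2) # window power correction

  nf <- floor(n / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n - 1L)]
    if (demean) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[1:nf]
    acc <- acc + (Mod(X)^2)
  }
  # one-sided PSD: 2 |X|^2 dt / (n U), DC (and Nyquist if present) not doubled
  p <- acc / length(starts) / (fs * n * U)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nf] <- 1
  p <- p * scale2
  freq <- (0:(nf - 1L)) * fs / n
  structure(
    data.frame(frequency = freq, density = p),
    segment_length = n / fs, overlap = overlap,
    n_segments = length(starts), sampling_rate = fs,
    class = c("power_spectrum", "data.frame")
  )
}

#' Difference of two power spectra
#'
#' Bin-wise subtraction of a quiet-segment spectrum from the full-trace
#' spectrum; the residual is the spectrum contributed by the spontaneous
#' events. Negative bins arising from sampling fluctuation are preserved
#' (clipping would bias the subsequent fit).
#'
#' @param full,quiet `power_spectrum` objects on identical frequency grids.
#' @return A `power_spectrum` with `density = full - quiet`.
#' @export
difference_spectrum <- function(full, quiet) {
  stopifnot(inherits(full, "power_spectrum"), inherits(quiet, "power_spectrum"))
  if (nrow(full) != nrow(quiet) ||
      max(abs(full$frequency - quiet$frequency)) > 1e-9)
    stop("spectra are on different frequency grids")
  out <- full
  out$density <- full$density - quiet$density
  out
}

#' Select the quietest segment of a trace
#'
#' Automated surrogate for choosing, by eye, a stretch of recording free
#' of obvious spontaneous events: returns the contiguous sub-trace of the
#' requested length with the minimum variance.
#'
#' @param trace A [current_trace()].
#' @param length_s Desired segment length (s), <= trace duration.
#' @param step_s Search grid step (s); default 1.
#' @return A `current_trace` of the requested length.
#' @export
select_quiet_segment <- function(trace, length_s, step_s = 1) {
  stopifnot(inherits(trace, "current_trace"))
  dur <- trace_duration(trace)
  if (length_s > dur) stop("`length_s` exceeds the trace duration")
  if (length_s == dur) return(trace)
  fs <- trace$sampling_rate
  n <- round(length_s * fs)
  x <- trace$current
  step <- max(1L, round(step_s * fs))
  starts <- unique(c(seq(1L, length(x) - n + 1L, by = step),
                     length(x) - n + 1L))
  # running variance via cumulative sums
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  sm <- cs[starts + n] - cs[starts]
  s2 <- cs2[starts + n] - cs2[starts]
  v <- (s2 - sm^2 / n) / (n - 1)
  s_best <- starts[which.min(v)]
  current_trace(x[s_best:(s_best + n - 1L)], fs, trace$filter_cutoff,
                t0 = trace$t0 + (s_best - 1L) / fs)
}

#' Power spectrum of a single-photon response template
#'
#' Periodogram of the single-photon response waveform zero-padded to one
#' acquisition segment, on the same frequency grid and with the same
#' Parseval normalization as [welch_psd()] (rectangular window: the
#' waveform is compactly supported, so no taper is applied). Under this
#' convention the expected event spectrum of a Poisson event train at
#' rate r is r x segment_length times this template spectrum, which is
#' what makes the scale-factor read-out of [fit_rate_from_psd()] valid.
#'
#' @param spr A [single_photon_response()].
#' @param segment_length Segment length (s); default 8.192.
#' @return A `power_spectrum` data frame.
#' @export
spr_power_spectrum <- function(spr, segment_length = 8.192) {
  stopifnot(inherits(spr, "single_photon_response"))
  fs <- spr$sampling_rate
  n <- round(segment_length * fs)
  if (length(spr$waveform) > n)
    stop("waveform longer than the requested segment")
  f <- c(spr$waveform, numeric(n - length(spr$waveform)))
  nf <- floor(n / 2) + 1L
  X <- stats::fft(f)[1:nf]
  p <- (Mod(X)^2) / (fs * n)
  scale2 <- rep(2, nf)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nf] <- 1
  p <- p * scale2
  structure(
    data.frame(frequency = (0:(nf - 1L)) * fs / n, density = p),
    segment_length = n / fs, overlap = 0, n_segments = 1L,
    sampling_rate = fs,
    class = c("power_spectrum", "data.frame")
  )
}

#' Event rate from the power-spectrum difference
#'
#' Fits the difference spectrum (full dark recording minus quiet segment)
#' with a scaled power spectrum of the single-photon response; the
#' spontaneous event rate is the fitted scale factor divided by the
#' acquisition (segment) time. The scale factor is obtained by unweighted
#' linear least squares through the origin over the fit band, 0.1-5 Hz by
#' default (above the drift-dominated DC bins, below the acquisition
#' filter). A negative fitted scale is reported as rate 0 with a warning.
#'
#' @param diff A `power_spectrum` difference from [difference_spectrum()].
#' @param spr The cell's [single_photon_response()].
#' @param acquisition_s Acquisition segment time (s); default 8.192.
#' @param band Fit band (Hz), default c(0.1, 5); the DC bin is always
#'   excluded.
#' @return A `rate_estimate` (method "psd") with the fitted scale as
#'   attribute `scale`.
#' @export
fit_rate_from_psd <- function(diff, spr, acquisition_s = 8.192,
                              band = c(0.1, 5)) {
  stopifnot(inherits(diff, "power_spectrum"),
            inherits(spr, "single_photon_response"))
  if (isTRUE(spr$degenerate) || max(spr$waveform) <= 0)
    stop("single-photon response template is degenerate")
  tpl <- spr_power_spectrum(spr, segment_length = attr(diff, "segment_length"))
  if (nrow(tpl) != nrow(diff) ||
      max(abs(tpl$frequency - diff$frequency)) > 1e-9)
    stop("template and difference spectrum are on different grids")
  sel <- diff$frequency >= band[1] & diff$frequency <= band[2] &
    diff$frequency > 0
  if (!any(sel)) stop("fit band contains no frequency bins")
  p_t <- tpl$density[sel]
  if (all(p_t == 0)) stop("template spectrum is zero over the fit band")
  s_hat <- sum(p_t * diff$density[sel]) / sum(p_t^2)
  if (s_hat < 0) {
    warning("negative fitted scale; reporting rate 0")
    s_hat <- 0
  }
  est <- rate_estimate(s_hat / acquisition_s, method = "psd",
                       n = attr(diff, "n_segments"))
  attr(est, "scale") <- s_hat
  est
}
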