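#' Uniformly sampled membrane-current trace
#'
#' Container for a suction-pipette current recording: a numeric vector of
#' current samples (pA) at a uniform sampling rate, with the analog
#' low-pass filter cutoff carried along as provenance.
#'
#' @param current Numeric vector of current samples (pA).
#' @param sampling_rate Sampling rate (Hz), > 0.
#' @param filter_cutoff Low-pass cutoff applied to the data (Hz), or `NA`
#'   if unfiltered. Must satisfy `sampling_rate > 2 * filter_cutoff`.
#' @param t0 Time of the first sample (s); default 0.
#' @return An object of class `current_trace`.
#' @examples
#' tr <- current_trace(rnorm(1000), sampling_rate = 1000, filter_cutoff = 20)
#' trace_duration(tr)
#' @export
current_trace <- function(current, sampling_rate, filter_cutoff = NA_real_,
                          t0 = 0) {
  if (!is.numeric(current) || length(current) < 1)
    stop("`current` must be a non-empty numeric vector")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a single positive frequency in Hz")
  if (!is.na(filter_cutoff) && sampling_rate <= 2 * filter_cutoff)
    stop("`sampling_rate` must exceed twice `filter_cutoff` (Nyquist)")
  structure(
    list(current = as.numeric(current), sampling_rate = sampling_rate,
         filter_cutoff = filter_cutoff, t0 = t0),
    class = "current_trace"
  )
}

#' @rdname current_trace
#' @param trace A `current_trace`.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  length(trace$current) / trace$sampling_rate
}

#' @rdname current_trace
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "current_trace"))
  trace$t0 + (seq_along(trace$current) - 1) / trace$sampling_rate
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "Current trace: %.6g s at %g Hz (%d samples), low-pass %s Hz\n",
    trace_duration(x), x$sampling_rate, length(x$current),
    ifelse(is.na(x$filter_cutoff), "none", format(x$filter_cutoff))))
  invisible(x)
}

#' Zero-phase low-pass filtering of a current trace
#'
#' Applies a digital Butterworth low-pass filter forwards and backwards
#' ([signal::filtfilt()]), approximating the analog RC filtering of the
#' acquisition chain without introducing phase delay (so event times are
#' not shifted by filtering).
#'
#' @param trace A [current_trace()].
#' @param cutoff Cutoff frequency (Hz), below the Nyquist frequency.
#' @param order Butterworth order; default 4.
#' @return A filtered `current_trace` with `filter_cutoff` updated.
#' @export
lowpass_trace <- function(trace, cutoff, order = 4) {
  stopifnot(inherits(trace, "current_trace"))
  ny <- trace$sampling_rate / 2
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff >= ny)
    stop("`cutoff` must lie in (0, Nyquist) Hz")
  bf <- signal::butter(order, cutoff / ny, type = "low")
  y <- signal::filtfilt(bf, trace$current)
  current_trace(y, trace$sampling_rate, filter_cutoff = cutoff, t0 = trace$t0)
}

#' Extract a sub-trace by time window
#'
#' @param trace A [current_trace()].
#' @param from,to Window limits (s) relative to the trace start.
#' @return A `current_trace` covering the requested window.
#' @export
subset_trace <- function(trace, from, to) {
  stopifnot(inherits(trace, "current_trace"))
  if (to <= from) stop("`to` must exceed `from`")
  i0 <- max(1L, floor(from * trace$sampling_rate) + 1L)
  i1 <- min(length(trace$current), ceiling(to * trace$sampling_rate))
  current_trace(trace$current[i0:i1], trace$sampling_rate,
                trace$filter_cutoff,
                t0 = trace$t0 + (i0 - 1L) / trace$sampling_rate)
}
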