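#' Criteria for identifying quantal events in dark recordings
#'
#' Acceptance criteria for candidate deflections in a dark-current trace:
#' the event amplitude must exceed a fraction of the cell's single-photon
#' response amplitude, and its integration time must fall within a window
#' around the dim-flash response integration time. Counting is performed
#' on a heavily low-pass filtered copy of the trace.
#'
#' @param amplitude_fraction Minimum event amplitude as a fraction of the
#'   single-photon-response amplitude; default 0.30.
#' @param ti_window Allowed event integration time as (low, high)
#'   fractions of the dim-flash integration time; default c(0.5, 2).
#' @param counting_filter_cutoff Low-pass cutoff (Hz) applied before
#'   identification; default 3.
#' @param candidate_fraction Threshold-crossing level used to delimit
#'   candidate deflections, as a fraction of the single-photon amplitude;
#'   default 0.20 (detector choice, below the acceptance threshold).
#' @return An object of class `event_criteria`.
#' @export
event_criteria <- function(amplitude_fraction = 0.30,
                           ti_window = c(0.5, 2.0),
                           counting_filter_cutoff = 3,
                           candidate_fraction = 0.20) {
  if (amplitude_fraction <= 0 || amplitude_fraction >= 1)
    stop("`amplitude_fraction` must lie in (0, 1)")
  if (length(ti_window) != 2 || ti_window[1] <= 0 ||
      ti_window[2] <= ti_window[1])
    stop("`ti_window` must be (low, high) with 0 < low < high")
  if (counting_filter_cutoff <= 0)
    stop("`counting_filter_cutoff` must be positive")
  structure(
    list(amplitude_fraction = amplitude_fraction, ti_window = ti_window,
         counting_filter_cutoff = counting_filter_cutoff,
         candidate_fraction = candidate_fraction),
    class = "event_criteria"
  )
}

#' Detect quantal events in a dark recording
#'
#' Identifies discrete spontaneous events in a dark-current trace by the
#' two-criterion method: after zero-phase low-pass filtering (3 Hz by
#' default) and median baseline subtraction, contiguous runs above a
#' candidate threshold (20% of the filtered single-photon amplitude)
#' delimit candidate deflections; candidates separated by less than one
#' integration time are merged; each candidate window is extended to the
#' surrounding zero crossings, and the candidate is accepted if its peak
#' amplitude exceeds `amplitude_fraction` of the filtered single-photon
#' amplitude and its integration time lies within `ti_window` times the
#' dim-flash integration time.
#'
#' The single-photon template is passed through the same counting filter
#' before its amplitude is used, so the amplitude criterion compares like
#' with like.
#'
#' @param trace A [current_trace()]; positive deflections are events.
#' @param spr The cell's [single_photon_response()] (non-degenerate).
#' @param criteria An [event_criteria()] object.
#' @return An `event_list`: data frame with columns `time` (s, at event
#'   peak), `amplitude` (pA, on the filtered trace) and
#'   `integration_time` (s), with the trace duration as attribute
#'   `duration`.
#' @export
detect_events <- function(trace, spr, criteria = event_criteria()) {
  stopifnot(inherits(trace, "current_trace"),
            inherits(spr, "single_photon_response"))
  if (isTRUE(spr$degenerate))
    stop("single-photon response is degenerate; cannot set criteria")
  fs <- trace$sampling_rate
  dur <- trace_duration(trace)
  if (dur < 10 * spr$integration_time)
    stop("trace too short: need >= 10 single-photon integration times")

  filt <- lowpass_trace(trace, criteria$counting_filter_cutoff)
  y <- filt$current - stats::median(filt$current)

  # template through the same counting filter; pad so filtfilt edges settle
  pad <- round(2 * fs)
  tpl <- c(numeric(pad), spr$waveform, numeric(pad))
  tpl_f <- lowpass_trace(current_trace(tpl, fs),
                         criteria$counting_filter_cutoff)$current
  a_f <- max(tpl_f)
  ti_ref <- spr$integration_time

  thr <- criteria$candidate_fraction * a_f
  above <- y > thr
  if (!any(above)) return(.empty_event_list(dur))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])

  # merge candidates separated by less than one integration time
  gap <- round(ti_ref * fs)
  merged <- list()
  cur <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - cur[2] < gap) cur[2] <- runs[i, 2]
      else { merged[[length(merged) + 1L]] <- cur; cur <- runs[i, ] }
    }
  }
  merged[[length(merged) + 1L]] <- cur

  out <- lapply(merged, function(rg) {
    # extend to surrounding zero crossings (capped at 3 integration times)
    cap <- round(3 * ti_ref * fs)
    i0 <- rg[1]
    lo <- max(1L, rg[1] - cap)
    while (i0 > lo && y[i0 - 1L] > 0) i0 <- i0 - 1L
    i1 <- rg[2]
    hi <- min(length(y), rg[2] + cap)
    while (i1 < hi && y[i1 + 1L] > 0) i1 <- i1 + 1L
    seg <- y[i0:i1]
    pk <- max(seg)
    ti <- sum(pmax(seg, 0)) / fs / pk
    t_pk <- (i0 - 1L + which.max(seg) - 1L) / fs
    c(time = t_pk, amplitude = pk, integration_time = ti)
  })
  out <- do.call(rbind, out)
  keep <- out[, "amplitude"] > criteria$amplitude_fraction * a_f &
    out[, "integration_time"] >= criteria$ti_window[1] * ti_ref &
    out[, "integration_time"] <= criteria$ti_window[2] * ti_ref
  ev <- as.data.frame(out[keep, , drop = FALSE])
  rownames(ev) <- NULL
  structure(ev, duration = dur, class = c("event_list", "data.frame"))
}

.empty_event_list <- function(duration) {
  structure(
    data.frame(time = numeric(0), amplitude = numeric(0),
               integration_time = numeric(0)),
    duration = duration, class = c("event_list", "data.frame")
  )
}

#' Construct an event list from explicit event times
#'
#' @param time Event times (s), strictly increasing within `[0, duration]`.
#' @param duration Recording duration (s).
#' @param amplitude,integration_time Optional per-event values.
#' @return An `event_list`.
#' @export
event_list <- function(time, duration, amplitude = NA_real_,
                       integration_time = NA_real_) {
  if (is.unsorted(time, strictly = TRUE))
    stop("event times must be strictly increasing")
  if (length(time) && (min(time) < 0 || max(time) > duration))
    stop("event times must lie within [0, duration]")
  structure(
    data.frame(time = time,
               amplitude = rep_len(amplitude, length(time)),
               integration_time = rep_len(integration_time, length(time))),
    duration = duration, class = c("event_list", "data.frame")
  )
}

#' Event rate by direct counting
#'
#' Cellular spontaneous-activation rate as the total number of identified
#' events divided by the total recording time.
#'
#' @param events An `event_list` (from [detect_events()] or
#'   [event_list()]).
#' @param duration Recording duration (s); defaults to the event list's
#'   `duration` attribute.
#' @return A `rate_estimate`: list with `rate` (s^-1 cell^-1), `method`
#'   ("counting"), `n_events` and `duration`.
#' @export
counting_rate <- function(events, duration = attr(events, "duration")) {
  if (is.null(duration) || !is.numeric(duration) || duration <= 0)
    stop("`duration` must be positive")
  rate_estimate(nrow(events) / duration, method = "counting",
                n = nrow(events), duration = duration)
}

#' Rate estimate container
#'
#' @param rate Event rate (s^-1 cell^-1), >= 0.
#' @param method One of "counting", "poisson", "psd".
#' @param n Supporting count (events, epochs or segments).
#' @param duration Total time supporting the estimate (s).
#' @param dispersion Optional spread (SD) of the estimate.
#' @return An object of class `rate_estimate`.
#' @export
rate_estimate <- function(rate, method = c("counting", "poisson", "psd"),
                          n = NA_integer_, duration = NA_real_,
                          dispersion = NA_real_) {
  method <- match.arg(method)
  if (rate < 0) stop("`rate` must be >= 0")
  structure(list(rate = rate, method = method, n = n, duration = duration,
                 dispersion = dispersion),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate (%s): %.4g s^-1 cell^-1\n", x$method, x$rate))
  invisible(x)
}

#' Count events in fixed-length epochs
#'
#' Divides a recording into consecutive epochs (100 s by default) and
#' counts events in each complete epoch; a partial trailing epoch is
#' discarded so that every count has equal exposure, as required for the
#' Poisson fit.
#'
#' @param events An `event_list`.
#' @param duration Recording duration (s).
#' @param epoch_length Epoch length (s); default 100.
#' @return An `epoch_counts` object: integer vector of per-epoch counts
#'   with attribute `epoch_length`.
#' @export
epoch_counts <- function(events, duration = attr(events, "duration"),
                         epoch_length = 100) {
  if (is.null(duration) || duration < epoch_length)
    stop("`duration` must be at least one epoch long")
  n_ep <- floor(duration / epoch_length)
  idx <- floor(events$time / epoch_length) + 1L
  counts <- tabulate(idx[idx <= n_ep], nbins = n_ep)
  structure(as.integer(counts), epoch_length = epoch_length,
            class = "epoch_counts")
}

#' Poisson fit to epoch counts
#'
#' Maximum-likelihood fit of the Poisson distribution
#' \eqn{p(u) = w^u e^{-w} / u!} to per-epoch event counts. The MLE of the
#' mean events per epoch `w` is the sample mean; the cellular rate is
#' `w / epoch_length`.
#'
#' @param counts An [epoch_counts()] object, or an integer vector of
#'   counts with `epoch_length` supplied.
#' @param epoch_length Epoch length (s); taken from `counts` if present.
#' @return List with `w` (events/epoch), `rate` (a `rate_estimate`,
#'   method "poisson") and `n_epochs`.
#' @export
poisson_fit <- function(counts, epoch_length = attr(counts, "epoch_length")) {
  if (length(counts) < 1) stop("need at least one epoch")
  if (is.null(epoch_length)) stop("`epoch_length` is required")
  if (any(counts < 0)) stop("counts must be non-negative")
  w <- mean(counts)
  list(w = w,
       rate = rate_estimate(w / epoch_length, method = "poisson",
                            n = length(counts),
                            duration = length(counts) * epoch_length,
                            dispersion = stats::sd(counts) / epoch_length),
       n_epochs = length(counts))
}

#' Poisson probability of observing u events in an epoch
#'
#' \eqn{p(u) = w^u e^{-w} / u!} with `w` the mean events per epoch.
#'
#' @param u Non-negative integer count(s).
#' @param w Mean events per epoch, >= 0.
#' @return Probability (vectorized over `u`).
#' @export
poisson_pmf <- function(u, w) {
  if (any(u < 0) || any(u != round(u))) stop("`u` must be non-negative integers")
  if (any(w < 0)) stop("`w` must be >= 0")
  stats::dpois(u, w)
}

#' Effective collecting area and photon-capture probability
#'
#' The probability of a dim flash of intensity `I` (photons um^-2)
#' eliciting a response is \eqn{p_s = 1 - e^{-A_e I}} where `A_e` is the
#' outer segment's effective collecting area (um^2), proportional to its
#' pigment content. `collecting_area()` inverts this relation;
#' `success_probability()` is its exact inverse.
#'
#' @param p_success Response probability, in [0, 1).
#' @param I Flash intensity (photons um^-2 flash^-1), > 0.
#' @param A_e Effective collecting area (um^2), >= 0.
#' @return Collecting area (um^2), or success probability.
#' @examples
#' collecting_area(1 - exp(-1), 1) # 1
#' success_probability(0.44, 2)
#' @export
collecting_area <- function(p_success, I) {
  if (any(I <= 0)) stop("`I` must be positive")
  if (any(p_success < 0) || any(p_success >= 1))
    stop("`p_success` must lie in [0, 1); p = 1 implies infinite area")
  -log1p(-p_success) / I
}

#' @rdname collecting_area
#' @export
success_probability <- function(A_e, I) {
  if (any(A_e < 0) || any(I < 0)) stop("`A_e` and `I` must be >= 0")
  -expm1(-A_e * I)
}
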