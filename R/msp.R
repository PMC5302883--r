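#' Optical density from incident and transmitted intensity
#'
#' Beer's law absorbance, \eqn{OD = \log_{10}(I_i / I_t)}, where `I_i` is
#' the light transmitted through a cell-free reference path and `I_t` the
#' light transmitted through the tissue.
#'
#' @param I_incident,I_transmitted Positive intensities (counts).
#' @return Optical density (dimensionless; vectorized).
#' @examples
#' absorbance(10, 1) # 1
#' @export
absorbance <- function(I_incident, I_transmitted) {
  if (any(I_incident <= 0) || any(I_transmitted <= 0))
    stop("intensities must be positive")
  log10(I_incident / I_transmitted)
}

#' Absorbance spectrum container
#'
#' @param wavelength Wavelengths (nm), strictly increasing.
#' @param od Optical density at each wavelength.
#' @param normalized Logical flag: peak OD scaled to 1.
#' @param baseline_corrected Logical flag.
#' @return An `absorbance_spectrum` data frame.
#' @export
absorbance_spectrum <- function(wavelength, od, normalized = FALSE,
                                baseline_corrected = FALSE) {
  if (length(wavelength) != length(od))
    stop("`wavelength` and `od` lengths differ")
  if (is.unsorted(wavelength, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(
    data.frame(wavelength = wavelength, od = od),
    normalized = normalized, baseline_corrected = baseline_corrected,
    class = c("absorbance_spectrum", "data.frame")
  )
}

#' Baseline-correct an absorbance spectrum
#'
#' Fits a straight line to the long-wavelength region where the pigment
#' does not absorb (650-700 nm by default for rod/cone pigments peaking
#' at or below ~570 nm) and subtracts it across the whole spectrum,
#' removing instrumental offset and linear drift.
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param baseline_range Wavelength range (nm) assumed pigment-free.
#' @return A baseline-corrected `absorbance_spectrum`.
#' @export
baseline_correct <- function(spectrum, baseline_range = c(650, 700)) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  sel <- spectrum$wavelength >= baseline_range[1] &
    spectrum$wavelength <= baseline_range[2]
  if (sum(sel) < 2) stop("baseline range covers fewer than 2 points")
  fit <- stats::lm(od ~ wavelength, data = spectrum[sel, ])
  od <- spectrum$od -
    stats::predict(fit, newdata = data.frame(wavelength = spectrum$wavelength))
  absorbance_spectrum(spectrum$wavelength, od,
                      normalized = attr(spectrum, "normalized"),
                      baseline_corrected = TRUE)
}

#' Normalize a spectrum to its peak optical density
#'
#' Divides the spectrum by its maximum OD within the main absorption
#' (alpha) band search range, so the peak OD becomes 1. Idempotent.
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param peak_range Wavelength range (nm) searched for the alpha-band
#'   peak; default c(400, 650).
#' @return A normalized `absorbance_spectrum`.
#' @export
normalize_peak <- function(spectrum, peak_range = c(400, 650)) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  sel <- spectrum$wavelength >= peak_range[1] &
    spectrum$wavelength <= peak_range[2]
  if (!any(sel)) stop("peak range contains no points")
  pk <- max(spectrum$od[sel])
  if (pk <= 0) stop("non-positive peak OD; cannot normalize")
  absorbance_spectrum(spectrum$wavelength, spectrum$od / pk,
                      normalized = TRUE,
                      baseline_corrected = attr(spectrum, "baseline_corrected"))
}

#' Estimate the wavelength of peak absorbance
#'
#' Sub-grid estimate of lambda_max: the spectrum is lightly smoothed
#' (running mean), the raw maximum located within the alpha-band search
#' range, and a quadratic fitted to the points within +/- `half_width` nm
#' of that maximum; the parabola's vertex is returned. Equivariant under
#' wavelength translation and invariant under OD scaling.
#'
#' @param spectrum A baseline-corrected [absorbance_spectrum()].
#' @param peak_range Search range (nm) for the raw maximum.
#' @param half_width Half-width (nm) of the quadratic fit window;
#'   default 12 (wide enough to average noise, narrow enough that the
#'   alpha-band asymmetry biases the vertex by under half a grid step).
#' @param smooth_k Running-mean width in samples (odd); default 5, use 1
#'   to disable.
#' @return Estimated lambda_max (nm).
#' @export
estimate_lambda_max <- function(spectrum, peak_range = c(400, 650),
                                half_width = 12, smooth_k = 5) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  wl <- spectrum$wavelength
  od <- spectrum$od
  if (smooth_k > 1) {
    k <- smooth_k + (smooth_k + 1) %% 2 # force odd
    od <- stats::filter(od, rep(1 / k, k), sides = 2)
    od <- as.numeric(od)
  }
  sel <- which(wl >= peak_range[1] & wl <= peak_range[2] & !is.na(od))
  if (length(sel) < 3) stop("too few points in the peak search range")
  i_pk <- sel[which.max(od[sel])]
  if (i_pk <= min(sel) || i_pk >= max(sel))
    stop("absorbance peak lies on the boundary of the search range")
  win <- which(abs(wl - wl[i_pk]) <= half_width & !is.na(od))
  if (length(win) < 3) stop("quadratic fit window has fewer than 3 points")
  z <- wl[win] - wl[i_pk]
  fit <- stats::lm(od[win] ~ z + I(z^2))
  b <- stats::coef(fit)
  if (!is.finite(b[3]) || b[3] >= 0) return(wl[i_pk]) # flat top: raw maximum
  vertex <- -b[2] / (2 * b[3])
  wl[i_pk] + max(-half_width, min(half_width, vertex))
}

#' Fit a polynomial template to a spectrum
#'
#' Least-squares polynomial (degree 10 by default) describing a mean
#' pigment spectrum over a wavelength range, for use as an unmixing
#' template. The fit is performed on the wavelength axis rescaled to
#' [-1, 1] so that a degree-10 Vandermonde system stays well conditioned.
#'
#' @param spectrum An [absorbance_spectrum()] (typically a mean spectrum).
#' @param degree Polynomial degree; default 10.
#' @param range Wavelength range (nm) of the fit; default the spectrum's
#'   full range.
#' @return A `spectral_template`: list with `coefficients` (ascending
#'   powers of the scaled wavelength), `range`, `r_squared`.
#' @export
fit_template <- function(spectrum, degree = 10, range = NULL) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  if (is.null(range)) range <- base::range(spectrum$wavelength)
  sel <- spectrum$wavelength >= range[1] & spectrum$wavelength <= range[2]
  if (sum(sel) < degree + 1)
    stop("need at least degree + 1 points inside the fit range")
  wl <- spectrum$wavelength[sel]
  od <- spectrum$od[sel]
  z <- .scale_wl(wl, range)
  X <- stats::poly(z, degree, raw = TRUE)
  fit <- stats::lm(od ~ X)
  fitted <- stats::fitted(fit)
  ss_res <- sum((od - fitted)^2)
  ss_tot <- sum((od - mean(od))^2)
  structure(
    list(coefficients = as.numeric(stats::coef(fit)), range = range,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1),
    class = "spectral_template"
  )
}

.scale_wl <- function(wl, range) {
  (2 * wl - range[1] - range[2]) / (range[2] - range[1])
}

#' Evaluate a spectral template at given wavelengths
#'
#' @param template A `spectral_template` from [fit_template()].
#' @param wavelength Wavelengths (nm) inside the template's fit range.
#' @return Predicted OD values.
#' @export
eval_template <- function(template, wavelength) {
  stopifnot(inherits(template, "spectral_template"))
  z <- .scale_wl(wavelength, template$range)
  co <- template$coefficients
  out <- numeric(length(z))
  for (j in seq_along(co)) out <- out + co[j] * z^(j - 1)
  out
}

#' Pair of isomer templates for spectral unmixing
#'
#' @param template_11cis,template_9cis `spectral_template` objects for the
#'   native (11-cis) and exchanged (9-cis) pigment spectra.
#' @param fit_range Wavelength range (nm) over which unmixing is
#'   performed; 510-750 nm is appropriate for long-wavelength-sensitive
#'   cone pigments and is the default.
#' @return A `template_pair`.
#' @export
template_pair <- function(template_11cis, template_9cis,
                          fit_range = c(510, 750)) {
  stopifnot(inherits(template_11cis, "spectral_template"),
            inherits(template_9cis, "spectral_template"))
  structure(list(template_11cis = template_11cis,
                 template_9cis = template_9cis, fit_range = fit_range),
            class = "template_pair")
}

#' Fraction of 9-cis-conjugated pigment by spectral unmixing
#'
#' Fits an observed spectrum over the unmixing range with a non-negative
#' linear combination of the 11-cis and 9-cis polynomial templates; the
#' degree of chromophore exchange is the 9-cis coefficient divided by the
#' coefficient sum.
#'
#' @param spectrum An [absorbance_spectrum()] covering the fit range.
#' @param templates A [template_pair()].
#' @param range Unmixing wavelength range (nm); defaults to the pair's
#'   `fit_range`.
#' @return Fraction of 9-cis pigment in [0, 1], with the two fitted
#'   coefficients as attribute `coefficients`.
#' @export
unmix_fraction <- function(spectrum, templates, range = templates$fit_range) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"),
            inherits(templates, "template_pair"))
  sel <- spectrum$wavelength >= range[1] & spectrum$wavelength <= range[2]
  if (sum(sel) < 2) stop("spectrum does not cover the unmixing range")
  wl <- spectrum$wavelength[sel]
  A <- cbind(c11 = eval_template(templates$template_11cis, wl),
             c9 = eval_template(templates$template_9cis, wl))
  nn <- pracma::lsqnonneg(A, spectrum$od[sel])
  co <- nn$x
  if (sum(co) <= 0)
    stop("both template coefficients are zero; fraction undefined")
  structure(co[2] / sum(co), coefficients = c(c11 = co[1], c9 = co[2]))
}

#' Chromophore-exchange time course container
#'
#' @param time Times (min), non-negative and increasing.
#' @param fraction Fraction of 9-cis-conjugated pigment at each time;
#'   values slightly outside [0, 1] are tolerated (noise).
#' @param sd Optional per-point SD.
#' @return An `exchange_timecourse` data frame.
#' @export
exchange_timecourse <- function(time, fraction, sd = NA_real_) {
  if (any(time < 0) || is.unsorted(time))
    stop("`time` must be non-negative and increasing")
  if (any(fraction < -0.1) || any(fraction > 1.1))
    stop("`fraction` outside [-0.1, 1.1]; check the unmixing")
  structure(
    data.frame(time = time, fraction = fraction,
               sd = rep_len(sd, length(time))),
    class = c("exchange_timecourse", "data.frame")
  )
}

#' Fit saturating-exponential exchange kinetics
#'
#' Least-squares fit of \eqn{a (1 - e^{-t/\tau})} to a chromophore
#' exchange time course, with both the asymptote `a` and the time
#' constant `tau` free (Levenberg-Marquardt).
#'
#' @param timecourse An [exchange_timecourse()] with at least 3 points.
#' @return An `exchange_kinetics` object: list with `asymptote`, `tau`
#'   (min), their standard errors `asymptote_se`, `tau_se`, and the
#'   underlying `nls` fit.
#' @examples
#' tc <- exchange_timecourse(seq(0, 180, 20),
#'                           0.72 * (1 - exp(-seq(0, 180, 20) / 37)))
#' fit_exchange_kinetics(tc)
#' @export
fit_exchange_kinetics <- function(timecourse) {
  stopifnot(inherits(timecourse, "exchange_timecourse"))
  if (nrow(timecourse) < 3) stop("need at least 3 time points")
  a0 <- max(timecourse$fraction, 0.1)
  t_half <- timecourse$time[which.min(abs(timecourse$fraction - a0 / 2))]
  tau0 <- max(t_half / log(2), min(diff(timecourse$time)))
  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ a * (1 - exp(-time / tau)),
                      data = timecourse,
                      start = list(a = a0, tau = tau0),
                      lower = c(a = 0, tau = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("exchange fit failed to converge: ",
                             conditionMessage(e))
  )
  co <- summary(fit)$coefficients
  structure(
    list(asymptote = co["a", "Estimate"], tau = co["tau", "Estimate"],
         asymptote_se = co["a", "Std. Error"], tau_se = co["tau", "Std. Error"],
         fit = fit),
    class = "exchange_kinetics"
  )
}

#' @export
print.exchange_kinetics <- function(x, ...) {
  cat(sprintf(
    "Exchange kinetics: a = %.3f +/- %.3f, tau = %.1f +/- %.1f min\n",
    x$asymptote, x$asymptote_se, x$tau, x$tau_se))
  invisible(x)
}

#' Bleached fraction of pigment under steady light
#'
#' \eqn{F = 1 - e^{-I P t}} for bleaching light intensity `I`
#' (photons um^-2 s^-1), in-situ photosensitivity `P` (um^2) and exposure
#' `t` (s). Shares the single-hit saturation form with
#' [success_probability()].
#'
#' @param I Light intensity (photons um^-2 s^-1), >= 0.
#' @param P Photosensitivity at lambda_max (um^2), >= 0.
#' @param t Exposure duration (s), >= 0.
#' @return Bleached fraction in [0, 1).
#' @examples
#' bleach_fraction(1.33e6, 5.7e-9, 960) # > 0.99
#' @export
bleach_fraction <- function(I, P, t) {
  if (any(I < 0) || any(P < 0) || any(t < 0))
    stop("`I`, `P` and `t` must be >= 0")
  success_probability(P * t, I)
}

#' Retinoid concentration from stock absorbance
#'
#' Beer-Lambert concentration of a retinoid solution from its peak
#' optical density: \eqn{c = OD / (\epsilon l)} with molar extinction
#' coefficient epsilon and path length l. Defaults are for 9-cis-retinal
#' in ethanol measured at 373 nm (epsilon = 36,100 M^-1 cm^-1, 1 cm
#' cuvette).
#'
#' @param od Optical density at the absorption peak, >= 0.
#' @param path_cm Path length (cm); default 1.
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1);
#'   default 36100.
#' @return Concentration (mol/L).
#' @export
retinal_concentration <- function(od, path_cm = 1, epsilon = 36100) {
  if (any(od < 0)) stop("`od` must be >= 0")
  if (path_cm <= 0 || epsilon <= 0)
    stop("`path_cm` and `epsilon` must be positive")
  od / (epsilon * path_cm)
}
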