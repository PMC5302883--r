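#' Barrier ratio of a visual pigment
#'
#' Ratio of the thermal activation-energy barrier to the thermal energy
#' scale, the dimensionless quantity that sits in the exponent of the
#' thermal-activation rate formula. The barrier is taken as a fixed
#' fraction (0.84 by default) of the photon energy at the pigment's peak
#' absorption wavelength, expressed per mole:
#'
#' \deqn{x = 0.84 \, N_A h c / (R T \lambda_{max})}
#'
#' The Avogadro factor converts the per-photon energy \eqn{hc/\lambda} to
#' a molar energy commensurate with \eqn{RT}; equivalently one may divide
#' the photon energy by \eqn{k_B T} per molecule. This is the convention
#' under which the formula's published rate predictions are reproduced.
#'
#' @param lambda_max Peak-absorption wavelength (nm), > 0.
#' @param T Absolute temperature (K), > 0.
#' @param constants A [physical_constants()] object.
#' @param barrier_fraction Fraction of the photon energy at `lambda_max`
#'   equal to the thermal barrier. Fixed model constant; default 0.84.
#' @return Dimensionless barrier ratio (numeric scalar).
#' @examples
#' barrier_ratio(481, 310.5) # about 81
#' @export
barrier_ratio <- function(lambda_max, T, constants = physical_constants(),
                          barrier_fraction = 0.84) {
  if (!is.numeric(lambda_max) || any(lambda_max <= 0))
    stop("`lambda_max` must be positive (nm)")
  if (!is.numeric(T) || any(T <= 0))
    stop("`T` must be positive (K)")
  barrier_fraction * constants$N_A * constants$h * constants$c /
    (constants$R * T * lambda_max)
}

#' Truncated exponential (Hinshelwood) sum
#'
#' Partial sum \eqn{\sum_{j=0}^{m-1} x^j / j!}, the Hinshelwood factor
#' giving the probability weight that `m` classical vibrational modes
#' jointly supply an energy of at least \eqn{x} thermal units. Multiplied
#' by \eqn{e^{-x}} it is the upper tail of a Poisson distribution, so it
#' always lies in (0, e^x].
#'
#' Terms are accumulated by the stable recurrence
#' \eqn{t_{j+1} = t_j \cdot x/(j+1)}; with `log = TRUE` the logarithm of
#' the sum is returned, computed by log-sum-exp over
#' \eqn{j \log x - \log j!} so that downstream products with
#' \eqn{e^{-x}} neither overflow nor underflow.
#'
#' @param x Dimensionless barrier ratio, >= 0.
#' @param m Number of terms (vibrational modes), integer >= 1.
#' @param log If `TRUE`, return the natural log of the sum.
#' @return The partial sum (or its log).
#' @examples
#' hinshelwood_sum(0, 10)   # 1
#' hinshelwood_sum(2, 3)    # 1 + 2 + 2 = 5
#' @export
hinshelwood_sum <- function(x, m, log = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop("`x` must be a single non-negative number")
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 1 || m != round(m))
    stop("`m` must be a single integer >= 1")
  m <- as.integer(m)
  if (log) {
    j <- 0:(m - 1)
    lt <- j * base::log(x) - lgamma(j + 1)
    if (x == 0) lt <- c(0, rep(-Inf, m - 1L))[seq_len(m)]
    mx <- max(lt)
    return(mx + base::log(sum(exp(lt - mx))))
  }
  s <- 1
  term <- 1
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      term <- term * x / j
      s <- s + term
    }
  }
  s
}

#' Predict the spontaneous-activation rate constant of a pigment
#'
#' Molecular thermal-activation rate from the multi-vibrational-mode
#' barrier-crossing model:
#'
#' \deqn{k = A \, e^{-x} \sum_{j=0}^{m-1} x^j / j!}
#'
#' where \eqn{x} is the [barrier_ratio()] set by the pigment's peak
#' absorption wavelength and the temperature, \eqn{m} the nominal number
#' of vibrational modes contributing thermal energy, and \eqn{A} the
#' attempt frequency (which differs ~26-fold between pigments with
#' "closed" rod-like and "open" cone-like chromophore-binding pockets).
#' The product \eqn{e^{-x}\sum} is a Poisson upper-tail probability, so
#' \eqn{0 < k \le A} always, with equality only at \eqn{x = 0}.
#'
#' The rate is evaluated in the log domain, so very large barriers
#' (\eqn{x} of order hundreds) do not underflow intermediate terms.
#'
#' @param params A [pigment_params()] object.
#' @param constants A [physical_constants()] object; the `"precise"`
#'   preset reproduces published predictions, the `"printed"` rounded
#'   constants shift the rate by roughly 10-15%.
#' @param barrier_fraction Barrier-to-photon-energy ratio; default 0.84.
#' @return An object of class `rate_prediction`: list with `k_molecular`
#'   (s^-1 per molecule), `x` (barrier ratio), `sum_value` (Hinshelwood
#'   partial sum), `log_sum`, `params` and `constants`.
#' @examples
#' predict_rate_constant(pigment_params(481))                  # ~3.7e-11 s^-1
#' predict_rate_constant(pigment_params(481, pocket = "open")) # ~9.7e-10 s^-1
#' @export
predict_rate_constant <- function(params, constants = physical_constants(),
                                  barrier_fraction = 0.84) {
  stopifnot(inherits(params, "pigment_params"))
  x <- barrier_ratio(params$lambda_max, params$T, constants,
                     barrier_fraction = barrier_fraction)
  log_sum <- hinshelwood_sum(x, params$m, log = TRUE)
  k <- exp(base::log(params$A) - x + log_sum)
  structure(
    list(k_molecular = k, x = x, sum_value = exp(log_sum),
         log_sum = log_sum, params = params, constants = constants),
    class = "rate_prediction"
  )
}

#' @export
print.rate_prediction <- function(x, ...) {
  cat("Thermal-activation rate prediction\n")
  cat(sprintf("  k  = %.4g s^-1 per molecule\n", x$k_molecular))
  cat(sprintf("  x  = %.4f (barrier ratio)\n", x$x))
  cat(sprintf("  sum = %.6g (m = %d terms)\n", x$sum_value, x$params$m))
  invisible(x)
}

#' Convert between molecular and cellular activation rates
#'
#' A photoreceptor's dark-event rate is the molecular rate constant times
#' the number of pigment molecules it holds (6.5e7 for a mouse rod).
#' `cellular_rate_from_molecular()` and `molecular_rate()` are exact
#' inverses.
#'
#' @param k_molecular Molecular rate constant (s^-1 per molecule).
#' @param cell_rate Cellular event rate (s^-1 per cell).
#' @param n_pigments Number of pigment molecules per cell; default 6.5e7.
#' @return Rate in s^-1 per cell, or s^-1 per molecule.
#' @examples
#' cellular_rate_from_molecular(3.69e-11)  # ~0.0024 s^-1 cell^-1
#' molecular_rate(0.015)                   # ~2.31e-10 s^-1
#' @export
cellular_rate_from_molecular <- function(k_molecular, n_pigments = 6.5e7) {
  if (!is.numeric(n_pigments) || any(n_pigments <= 0))
    stop("`n_pigments` must be positive")
  if (any(k_molecular < 0)) stop("`k_molecular` must be non-negative")
  k_molecular * n_pigments
}

#' @rdname cellular_rate_from_molecular
#' @export
molecular_rate <- function(cell_rate, n_pigments = 6.5e7) {
  if (!is.numeric(n_pigments) || any(n_pigments <= 0))
    stop("`n_pigments` must be positive")
  if (any(cell_rate < 0)) stop("`cell_rate` must be non-negative")
  cell_rate / n_pigments
}
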