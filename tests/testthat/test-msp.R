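test_that("Beer's-law absorbance", {
  expect_identical(absorbance(5, 5), 0)
  expect_identical(absorbance(10, 1), 1)
  expect_equal(absorbance(2, 1), log10(2), tolerance = 1e-15)
  expect_error(absorbance(0, 1), "positive")
})

test_that("baseline correction removes offsets and tilts", {
  tpl <- pigment_template_spectrum(500)
  # constant offset
  off <- absorbance_spectrum(tpl$wavelength, tpl$od + 0.3)
  bc <- baseline_correct(off)
  expect_equal(bc$od[bc$wavelength == 700], 0, tolerance = 1e-3)
  expect_equal(bc$od, tpl$od, tolerance = 1e-2)
  # linear tilt: recovered template within 1% RMS
  tilt <- absorbance_spectrum(tpl$wavelength,
                              tpl$od + 0.1 + 5e-4 * tpl$wavelength)
  bt <- baseline_correct(tilt)
  expect_lt(sqrt(mean((bt$od - tpl$od)^2)), 0.01)
  expect_true(attr(bt, "baseline_corrected"))
})

test_that("peak normalization is idempotent", {
  tpl <- pigment_template_spectrum(500)
  sc <- absorbance_spectrum(tpl$wavelength, 0.37 * tpl$od)
  n1 <- normalize_peak(sc)
  expect_equal(max(n1$od[n1$wavelength >= 400 & n1$wavelength <= 650]), 1)
  expect_equal(normalize_peak(n1)$od, n1$od, tolerance = 1e-12)
  expect_error(normalize_peak(absorbance_spectrum(400:500, rep(-1, 101))),
               "peak")
})

test_that("lambda_max estimation is accurate, equivariant and scale-free", {
  wl <- seq(300, 700, 2)
  # symmetric Gaussian centered at 500 nm
  g <- absorbance_spectrum(wl, exp(-(wl - 500)^2 / (2 * 30^2)))
  expect_equal(estimate_lambda_max(g), 500, tolerance = 0.1)
  # pigment template round trip within half a grid step
  for (lm in c(450, 481, 530))
    expect_equal(estimate_lambda_max(pigment_template_spectrum(lm, wl)), lm,
                 tolerance = 0.5)
  # translation equivariance (+10 nm) and OD-scale invariance
  tpl <- pigment_template_spectrum(500, wl)
  shifted <- absorbance_spectrum(wl + 10, tpl$od)
  expect_equal(estimate_lambda_max(shifted, peak_range = c(400, 660)),
               estimate_lambda_max(tpl) + 10, tolerance = 1e-9)
  scaled <- absorbance_spectrum(wl, 0.123 * tpl$od)
  expect_equal(estimate_lambda_max(scaled), estimate_lambda_max(tpl),
               tolerance = 1e-9)
  # noisy synthetic spectra: 481 +/- 2 nm across seeds
  ests <- vapply(1:10, function(s) {
    sp <- simulate_spectrum(481, noise_sd = 0.03, seed = s)
    estimate_lambda_max(baseline_correct(sp))
  }, 0)
  expect_lt(abs(mean(ests) - 481), 2)
  expect_error(estimate_lambda_max(
    absorbance_spectrum(400:500, seq(0, 1, length.out = 101)),
    peak_range = c(400, 500)), "boundary")
})

test_that("polynomial template fitting is faithful", {
  wl <- seq(510, 750, 2)
  # degree-3 data recovered exactly by a degree-3 fit
  z <- (wl - 630) / 120
  cubic <- absorbance_spectrum(wl, 0.2 + 0.5 * z - 0.3 * z^2 + 0.1 * z^3)
  f3 <- fit_template(cubic, degree = 3)
  expect_lt(max(abs(eval_template(f3, wl) - cubic$od)), 1e-10)
  expect_equal(f3$r_squared, 1, tolerance = 1e-12)
  # constant spectrum -> constant polynomial
  flat <- fit_template(absorbance_spectrum(wl, rep(0.25, length(wl))),
                       degree = 3)
  expect_equal(eval_template(flat, c(520, 600, 740)), rep(0.25, 3),
               tolerance = 1e-9)
  # degree-10 fit of a pigment template: R^2 > 0.99 in range
  lws <- pigment_template_spectrum(558, seq(300, 750, 2))
  f10 <- fit_template(lws, degree = 10, range = c(510, 750))
  expect_gt(f10$r_squared, 0.99)
  expect_error(fit_template(cubic, degree = 200), "points")
})

test_that("unmixing recovers mixture fractions", {
  fx <- lws_template_pair()
  # pure spectra
  expect_equal(as.numeric(unmix_fraction(fx$t11, fx$pair)), 0, tolerance = 1e-6)
  expect_equal(as.numeric(unmix_fraction(fx$t9, fx$pair)), 1, tolerance = 1e-6)
  # noiseless linearity to < 1e-6
  for (f in c(0.25, 0.5, 0.8)) {
    mix <- absorbance_spectrum(fx$wl, (1 - f) * fx$t11$od + f * fx$t9$od)
    expect_equal(as.numeric(unmix_fraction(mix, fx$pair)), f,
                 tolerance = 1e-6)
  }
  # 60/40 mixture with 2% OD noise: within +/- 0.05 across seeds
  fr <- vapply(1:10, function(s) {
    set.seed(40 + s)
    od <- 0.6 * fx$t11$od + 0.4 * fx$t9$od + rnorm(length(fx$wl), sd = 0.02)
    as.numeric(unmix_fraction(absorbance_spectrum(fx$wl, od), fx$pair))
  }, 0)
  expect_lt(max(abs(fr - 0.4)), 0.05)
})

test_that("exchange kinetics fit recovers its parameters", {
  times <- seq(0, 180, by = 20)
  # noiseless self-consistency
  tc0 <- exchange_timecourse(times, 0.72 * (1 - exp(-times / 37)))
  k0 <- fit_exchange_kinetics(tc0)
  expect_equal(k0$asymptote, 0.72, tolerance = 1e-6)
  expect_equal(k0$tau, 37, tolerance = 1e-4)
  # noisy recovery within 20% across seeds (per-cell SD 0.15, 9 cells)
  res <- t(vapply(1:10, function(s) {
    tc <- simulate_exchange_timecourse(0.72, 37, times, noise_sd = 0.15,
                                       n_cells = 9, seed = 60 + s)
    k <- fit_exchange_kinetics(tc)
    c(k$asymptote, k$tau)
  }, numeric(2)))
  expect_lt(abs(mean(res[, 1]) - 0.72) / 0.72, 0.2)
  expect_lt(abs(mean(res[, 2]) - 37) / 37, 0.2)
  expect_error(fit_exchange_kinetics(exchange_timecourse(c(0, 10), c(0, 0.1))),
               "3 time points")
})

test_that("exchange fit accuracy across the parameter plane", {
  # median relative error of both parameters < 10% at noise SD 0.02
  cases <- expand.grid(a = c(0.5, 0.75, 1), tau = c(10, 40, 120))
  rel_err <- t(mapply(function(a, tau, s) {
    times <- seq(0, 180, by = 15)
    tc <- simulate_exchange_timecourse(a, tau, times, noise_sd = 0.02,
                                       n_cells = 1, seed = 70 + s)
    k <- fit_exchange_kinetics(tc)
    c(abs(k$asymptote - a) / a, abs(k$tau - tau) / tau)
  }, cases$a, cases$tau, seq_len(nrow(cases))))
  expect_lt(stats::median(rel_err[, 1]), 0.1)
  expect_lt(stats::median(rel_err[, 2]), 0.1)
})

test_that("bleach fraction follows the single-hit saturation law", {
  expect_identical(bleach_fraction(1e6, 5e-9, 0), 0)
  expect_gt(bleach_fraction(1.33e6, 5.7e-9, 960), 0.99)
  # monotone increasing in each argument
  expect_gt(bleach_fraction(2e6, 5.7e-9, 960), bleach_fraction(1e6, 5.7e-9, 960))
  expect_gt(bleach_fraction(1e6, 6e-9, 960), bleach_fraction(1e6, 5e-9, 960))
  expect_gt(bleach_fraction(1e6, 5e-9, 1200), bleach_fraction(1e6, 5e-9, 960))
  # same 1 - e^-x form as photon-capture probability
  expect_equal(bleach_fraction(3, 0.2, 5), success_probability(1, 3),
               tolerance = 1e-12)
})

test_that("retinoid concentration from stock absorbance", {
  expect_identical(retinal_concentration(0), 0)
  expect_equal(retinal_concentration(0.361), 1.0e-5, tolerance = 1e-12)
  expect_equal(retinal_concentration(c(0.1, 0.2)),
               2 * retinal_concentration(c(0.05, 0.1)), tolerance = 1e-15)
  expect_error(retinal_concentration(0.1, path_cm = 0), "positive")
})
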