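# Frozen expected values below were computed with a 50-digit
# arbitrary-precision evaluation of the barrier ratio and the truncated
# exponential sum (independent of this implementation).

test_that("barrier ratio matches the arbitrary-precision value and scales", {
  expect_equal(barrier_ratio(481, 310.5), 80.9218969540312, tolerance = 1e-12)
  # doubling T halves x exactly; doubling lambda_max likewise
  x1 <- barrier_ratio(500, 300)
  expect_identical(barrier_ratio(500, 600), x1 / 2)
  expect_equal(barrier_ratio(1000, 300), x1 / 2, tolerance = 1e-15)
  # limit case: x -> 0 as lambda_max -> infinity
  expect_lt(barrier_ratio(1e12, 310.5), 1e-7)
  expect_error(barrier_ratio(-1, 300), "positive")
  expect_error(barrier_ratio(500, 0), "positive")
})

test_that("hinshelwood_sum agrees with the 50-digit oracle grid", {
  oracle <- rbind(
    c(0.5, 5, 1.6484375000000000),
    c(0.5, 45, 1.6487212707001281),
    c(2, 20, 7.3890560989301741),
    c(2, 45, 7.3890560989306502),
    c(10, 20, 21950.378849431941),
    c(10, 45, 22026.465794806706),
    c(40, 20, 41499104628332.742),
    c(40, 45, 1.8023095561262812e17),
    c(40, 60, 2.3494282996483498e17),
    c(80, 20, 1.5461506519788309e19),
    c(80, 45, 4.4165134367617100e29),
    c(80, 60, 4.7635707382505632e32),
    c(120, 45, 1.7971082562680267e37),
    c(120, 60, 6.5626464121204216e42),
    c(200, 45, 8.4694242371721908e46),
    c(200, 60, 5.8788863741274045e55)
  )
  for (i in seq_len(nrow(oracle))) {
    x <- oracle[i, 1]; m <- oracle[i, 2]; want <- oracle[i, 3]
    expect_equal(hinshelwood_sum(x, m), want, tolerance = 1e-8,
                 info = sprintf("x=%g m=%d", x, m))
    expect_equal(exp(hinshelwood_sum(x, m, log = TRUE)), want,
                 tolerance = 1e-8, info = sprintf("log path x=%g m=%d", x, m))
  }
  # the partial sum at x = 81, m = 45 matches the oracle barrier case
  expect_equal(hinshelwood_sum(80.9218969540312, 45), 7.22127049329557e29,
               tolerance = 1e-10)
})

test_that("hinshelwood_sum trivial cases and errors", {
  expect_identical(hinshelwood_sum(0, 10), 1)
  expect_identical(hinshelwood_sum(5, 1), 1)
  expect_identical(hinshelwood_sum(2, 3), 5) # 1 + 2 + 2
  expect_identical(hinshelwood_sum(0, 1, log = TRUE), 0)
  expect_error(hinshelwood_sum(2, 0), "m")
  expect_error(hinshelwood_sum(-1, 3), "non-negative")
})

test_that("hinshelwood_sum converges to e^x with many modes", {
  # (the Poisson tail beyond 10x terms is only negligible once x >~ 2)
  for (x in c(2, 5, 10)) {
    m <- ceiling(10 * x)
    expect_equal(hinshelwood_sum(x, m) / exp(x), 1, tolerance = 1e-6,
                 info = paste("x =", x))
  }
})

test_that("rate prediction reproduces the oracle and its bounds", {
  pred <- predict_rate_constant(pigment_params(481))
  expect_equal(pred$k_molecular, 3.72742738106e-11, tolerance = 1e-9)
  pred_o <- predict_rate_constant(pigment_params(481, pocket = "open"))
  expect_equal(pred_o$k_molecular, 9.74626352766e-10, tolerance = 1e-9)
  # longer lambda_max lowers the barrier, raises the rate
  expect_equal(predict_rate_constant(pigment_params(500))$k_molecular,
               1.53240359283e-10, tolerance = 1e-9)
  expect_gt(predict_rate_constant(pigment_params(500))$k_molecular,
            pred$k_molecular)
  # k <= A always; k = A * e^-x for m = 1
  expect_lte(pred$k_molecular, pred$params$A)
  p1 <- pigment_params(481, m = 1)
  k1 <- predict_rate_constant(p1)
  expect_equal(k1$k_molecular, p1$A * exp(-k1$x), tolerance = 1e-12)
  # x = 0 limit: k = A exactly (Arrhenius with no barrier)
  expect_equal(
    predict_rate_constant(pigment_params(481, m = 1),
                          barrier_fraction = 0)$k_molecular,
    7.19e-6, tolerance = 1e-15)
})

test_that("k increases monotonically in lambda_max and temperature", {
  k_l <- vapply(seq(420, 620, by = 20), function(l)
    predict_rate_constant(pigment_params(l))$k_molecular, 0)
  expect_true(all(diff(k_l) > 0))
  k_T <- vapply(seq(280, 320, by = 5), function(Tk)
    predict_rate_constant(pigment_params(500, T = Tk))$k_molecular, 0)
  expect_true(all(diff(k_T) > 0))
})

test_that("printed rounded constants shift the prediction ~10-15%", {
  k_pre <- predict_rate_constant(pigment_params(481))$k_molecular
  k_prt <- predict_rate_constant(pigment_params(481),
                                 physical_constants("printed"))$k_molecular
  expect_equal(k_prt, 4.181245966e-11, tolerance = 1e-8) # frozen oracle value
  expect_gt(k_prt / k_pre, 1.05)
  expect_lt(k_prt / k_pre, 1.20)
})

test_that("cellular and molecular rates are exact inverses", {
  expect_identical(cellular_rate_from_molecular(0, 123), 0)
  expect_equal(cellular_rate_from_molecular(3.69e-11, 6.5e7), 0.0023985)
  for (k in c(1e-11, 3.7e-11, 2.3e-10))
    expect_equal(molecular_rate(cellular_rate_from_molecular(k)), k,
                 tolerance = 1e-15)
  expect_error(molecular_rate(0.01, n_pigments = 0), "positive")
})

test_that("pigment parameter validation and pocket defaults", {
  expect_equal(pigment_params(500)$A, 7.19e-6)
  expect_equal(pigment_params(500, pocket = "open")$A, 1.88e-4)
  expect_equal(pigment_params(500, A = 1e-5)$A, 1e-5)
  expect_error(pigment_params(-5), "positive")
  expect_error(pigment_params(500, m = 0), "integer")
  expect_error(pigment_params(500, T = -1), "positive")
})
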