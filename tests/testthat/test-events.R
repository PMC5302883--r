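test_that("no events are found in sub-threshold noise", {
  spr <- fast_spr()
  sim <- simulate_dark_trace(duration = 120, event_rate = 0, seed = 4)
  ev <- detect_events(sim$trace, spr)
  expect_identical(nrow(ev), 0L)
  expect_equal(attr(ev, "duration"), 120)
})

test_that("amplitude criterion separates full from 20% events", {
  spr <- fast_spr() # 2 pA peak
  times <- c(10, 25, 40, 55, 70, 85, 100)
  amps <- c(1, 1, 1, 1, 1, 0.2, 0.2) # last two at 20% amplitude
  tr <- trace_with_events(times, duration = 120, spr = spr,
                          amplitudes = amps, noise_sd = 0.3, seed = 2)
  ev <- detect_events(tr, spr)
  expect_identical(nrow(ev), 5L)
  expect_equal(ev$time, times[1:5], tolerance = 0.3)
  # detected amplitudes are near the filtered template peak
  expect_true(all(ev$amplitude > 1))
})

test_that("kinetics criterion rejects slow drift", {
  spr <- fast_spr()
  fs <- 1000
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  # smooth bump with integration time ~3x the template's: right amplitude,
  # wrong kinetics
  ti3 <- 3 * spr$integration_time
  drift <- 2 * exp(-(t - 60)^2 / (2 * (ti3 / sqrt(2 * pi))^2 * 2))
  bump_ti <- sum(drift) / fs / max(drift)
  expect_gt(bump_ti, 2 * spr$integration_time) # confirm it violates the window
  tr <- current_trace(drift + rnorm(length(t), sd = 0.05), fs)
  expect_identical(nrow(detect_events(tr, spr)), 0L)
})

test_that("counting rate recovers simulated rates without bias", {
  spr <- fast_spr()
  # 9 events / 600 s = 0.015 s^-1: plain arithmetic
  ev9 <- event_list(seq(30, 590, length.out = 9), duration = 600)
  expect_equal(counting_rate(ev9)$rate, 0.015)
  expect_equal(counting_rate(event_list(numeric(0), 600))$rate, 0)

  # Monte Carlo: mean recovered rate within 3 SE of truth
  r <- 0.015
  n_seeds <- 12
  dur <- 300
  est <- vapply(seq_len(n_seeds), function(s) {
    sim <- simulate_dark_trace(duration = dur, event_rate = r, seed = 100 + s)
    counting_rate(detect_events(sim$trace, spr))$rate
  }, 0)
  se <- sqrt(r / (dur * n_seeds))
  expect_lt(abs(mean(est) - r), 3 * se)
})

test_that("epoch counting conserves events and drops partial epochs", {
  ev <- event_list(c(50, 150, 155, 420), duration = 650)
  ec <- epoch_counts(ev, epoch_length = 100)
  expect_identical(length(ec), 6L) # 650 s -> 6 complete epochs
  expect_identical(as.integer(ec), c(1L, 2L, 0L, 0L, 1L, 0L))
  expect_identical(sum(ec), 4L)
  # event in the dropped partial epoch is not counted
  ev2 <- event_list(c(50, 620), duration = 650)
  expect_identical(sum(epoch_counts(ev2, epoch_length = 100)), 1L)
  expect_error(epoch_counts(ev, duration = 50), "epoch")
})

test_that("Poisson fit is the sample-mean MLE", {
  ec <- structure(c(1L, 1L, 1L), epoch_length = 100, class = "epoch_counts")
  pf <- poisson_fit(ec)
  expect_identical(pf$w, 1)
  expect_equal(pf$rate$rate, 0.01)
  expect_identical(poisson_fit(structure(c(0L, 0L), epoch_length = 100,
                                         class = "epoch_counts"))$w, 0)
  expect_error(poisson_fit(integer(0), epoch_length = 100), "epoch")
})

test_that("epoch counts from simulated traces are Poisson distributed", {
  # chi-square goodness of fit of pooled epoch counts against p(u) = w^u e^-w/u!
  spr <- fast_spr()
  counts <- unlist(lapply(1:10, function(s) {
    sim <- simulate_dark_trace(duration = 400, event_rate = 0.02,
                               seed = 500 + s)
    as.integer(epoch_counts(detect_events(sim$trace, spr),
                            duration = 400, epoch_length = 100))
  }))
  w <- mean(counts)
  u_max <- max(counts, 2)
  obs <- tabulate(counts + 1L, nbins = u_max + 1L)
  p <- poisson_pmf(0:u_max, w)
  p[u_max + 1L] <- p[u_max + 1L] + (1 - sum(p)) # fold the tail in
  gof <- suppressWarnings(stats::chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("poisson_pmf matches the closed form and normalizes", {
  expect_identical(poisson_pmf(0, 0), 1)
  expect_equal(poisson_pmf(1, 0.23), 0.23 * exp(-0.23), tolerance = 1e-12)
  w <- 1.7
  u <- 0:(10 + ceiling(10 * w))
  expect_equal(sum(poisson_pmf(u, w)), 1, tolerance = 1e-12)
  expect_error(poisson_pmf(-1, 1), "non-negative")
  expect_error(poisson_pmf(2, -1), ">= 0")
})

test_that("collecting area inverts photon-capture probability", {
  expect_identical(collecting_area(0, 5), 0)
  expect_equal(collecting_area(1 - exp(-1), 1), 1, tolerance = 1e-12)
  for (a in c(0.1, 0.44, 2))
    expect_equal(collecting_area(success_probability(a, 3), 3), a,
                 tolerance = 1e-12)
  expect_error(collecting_area(1, 1), "infinite")
  expect_error(collecting_area(0.5, 0), "positive")

  # Monte Carlo at the scale of a mouse rod: A_e = 0.44 um^2
  set.seed(9)
  A_e <- 0.44; I <- 2; n <- 400
  hits <- rbinom(1, n, success_probability(A_e, I))
  p_hat <- hits / n
  ci <- p_hat + c(-1, 1) * 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  a_ci <- collecting_area(ci, I)
  expect_gt(A_e, a_ci[1])
  expect_lt(A_e, a_ci[2])
})
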