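# Connection classifier: averaging, the three criteria, latency, rise time,
# reversal, and derived trace measurements.

test_that("averaging returns the trial mean and 50 ms baseline statistics", {
  sw <- make_planted_sweeps(present = rep(TRUE, 10), noise_sd_pA = 0)
  avg <- average_sweeps(sw)
  expect_equal(avg$mean_trace, sw$traces[1, ])
  expect_equal(avg$baseline_mean_pA, 0)

  # baseline SD shrinks as 1/sqrt(n) (CLT oracle on regenerated noise)
  sd_for_n <- function(n, seed) {
    set.seed(seed)
    traces <- matrix(rnorm(n * 4000, 0, 2), nrow = n)
    avg <- average_sweeps(sweep_set(traces, 20000, paired_protocol()))
    avg$baseline_sd_pA
  }
  r <- mean(vapply(1:20, function(s) sd_for_n(4, s), 1)) /
    mean(vapply(1:20, function(s) sd_for_n(64, s), 1))
  expect_equal(r, 4, tolerance = 0.2)

  # a protocol without 50 ms of pre-stimulus samples is refused
  short <- sweep_set(matrix(rnorm(2000), nrow = 1), 20000,
                     stimulus_protocol(30, 200, -70, 20, 30))
  expect_error(average_sweeps(short), "baseline")
})

test_that("a planted compliant PSC is deemed connected", {
  res <- detect_connection(make_planted_pair(seed = 1))
  expect_true(res$verdict)
  expect_true(all(res$criteria))
  expect_equal(res$peak_pA, 15, tolerance = 0.15 * 15)
  expect_equal(res$latency_ms, 7, tolerance = 0.5)
  expect_lt(res$rise_10_90_ms, 4)
  expect_equal(res$trial_fraction, 1.0)
})

test_that("flat traces are not connected and fail the peak criterion", {
  sw <- sweep_set(matrix(0.1, nrow = 5, ncol = 8000), 20000,
                  paired_protocol())
  rec <- pair_recording("a", "b", 50, "Pcdhg22", "juvenile", sw)
  res <- detect_connection(rec)
  expect_false(res$verdict)
  expect_false(res$criteria[["peak_2sd"]])
})

test_that("each criterion is individually falsifiable", {
  # latency 13 ms, otherwise identical -> only the latency/rise criterion
  r_lat <- detect_connection(make_planted_pair(latency_ms = 13, seed = 2))
  expect_false(r_lat$verdict)
  expect_false(r_lat$criteria[["latency_rise"]])
  expect_true(r_lat$criteria[["peak_2sd"]])
  expect_true(r_lat$criteria[["presence_80pct"]])
  expect_gte(r_lat$latency_ms, 12)

  # slow kinetics -> rise time beyond 4 ms
  r_rise <- detect_connection(make_planted_pair(tau_rise_ms = 5, seed = 2))
  expect_false(r_rise$verdict)
  expect_false(r_rise$criteria[["latency_rise"]])
  expect_gte(r_rise$rise_10_90_ms, 4)

  # present in 7 of 10 trials -> presence criterion fails at the 80% bar
  pres <- c(rep(TRUE, 7), rep(FALSE, 3))
  r_pres <- detect_connection(pair_recording(
    "a", "b", 50, "Pcdhg22", "juvenile",
    make_planted_sweeps(present = pres, seed = 2)))
  expect_false(r_pres$verdict)
  expect_false(r_pres$criteria[["presence_80pct"]])
  expect_equal(r_pres$trial_fraction, 0.7, tolerance = 0.11)
  expect_true(r_pres$criteria[["peak_2sd"]])

  # a ~1.5-SD averaged peak fails the 2-SD criterion
  r_small <- detect_connection(make_planted_pair(amplitude_pA = 0.9,
                                                 seed = 2))
  expect_false(r_small$verdict)
  expect_false(r_small$criteria[["peak_2sd"]])
})

test_that("trial presence matches planted trial structure", {
  pres6 <- c(rep(TRUE, 6), rep(FALSE, 4))
  sw <- make_planted_sweeps(present = pres6, amplitude_pA = 30, seed = 3)
  expect_equal(trial_presence_fraction(sw, 1), 0.6, tolerance = 0.101)
  swall <- make_planted_sweeps(present = rep(TRUE, 10), amplitude_pA = 30,
                               seed = 3)
  expect_equal(trial_presence_fraction(swall, 1), 1.0)
  # pure noise stays low
  fracs <- vapply(1:40, function(s) {
    sw0 <- make_planted_sweeps(present = rep(FALSE, 10), seed = 100 + s)
    trial_presence_fraction(sw0, 1)
  }, numeric(1))
  expect_gte(mean(fracs <= 0.2), 0.95)
  # degenerate zero-variance baseline is an explicit error
  flat <- sweep_set(matrix(0, nrow = 2, ncol = 8000), 20000,
                    paired_protocol())
  expect_error(trial_presence_fraction(flat, 1), "zero-variance")
})

test_that("verdicts are monotone in amplitude at fixed noise", {
  for (seed in 1:5) {
    verdicts <- vapply(c(4, 8, 15, 30), function(a)
      detect_connection(make_planted_pair(amplitude_pA = a,
                                          seed = seed))$verdict,
      logical(1))
    expect_true(all(diff(as.integer(verdicts)) >= 0))
  }
})

test_that("detection is invariant to a constant offset", {
  rec <- make_planted_pair(seed = 4)
  res1 <- detect_connection(rec)
  rec$sweeps$traces <- rec$sweeps$traces + 123.4
  res2 <- detect_connection(rec)
  expect_identical(res1$verdict, res2$verdict)
  expect_equal(res1$latency_ms, res2$latency_ms, tolerance = 1e-8)
  expect_equal(res1$rise_10_90_ms, res2$rise_10_90_ms, tolerance = 1e-8)
  expect_equal(res1$trial_fraction, res2$trial_fraction)
})

test_that("Boltzmann latency matches the tangent-intercept closed form", {
  t <- seq(0, 200, by = 0.05)
  tr <- 10 / (1 + exp((108 - t) / 0.5))
  expect_equal(as.numeric(measure_latency(tr, t, onset_ms = 100)), 7.0,
               tolerance = 0.01)
  # step-like rise: latency collapses to the step time
  stp <- ifelse(t >= 110, 10, 0)
  expect_equal(as.numeric(measure_latency(stp, t, onset_ms = 100)), 10,
               tolerance = 0.1)
  # undetectable rise (flat window, noisy baseline) is NA with a warning
  set.seed(1)
  flatwin <- ifelse(t < 100, rnorm(length(t), 0, 1), 0)
  expect_warning(out <- measure_latency(flatwin, t, onset_ms = 100),
                 "rising phase")
  expect_true(is.na(out))
})

test_that("planted-PSC latency is recovered within 0.5 ms at SNR >= 5", {
  lats <- vapply(1:100, function(s) {
    rec <- make_planted_pair(seed = s)  # 15 pA on 2 pA noise, latency 7
    detect_connection(rec)$latency_ms
  }, numeric(1))
  expect_true(all(abs(lats - 7) <= 0.5))
})

test_that("rise time follows its defining arithmetic", {
  t <- seq(0, 200, by = 0.05)
  # linear ramp 0 -> 10 pA over 5 ms: 10-90% rise = 0.8 * 5 = 4 ms
  ramp <- pmin(pmax((t - 105) / 5, 0), 1) * 10
  expect_equal(measure_rise_time(ramp, t, 100), 4.0, tolerance = 0.01)
  # instantaneous step: rise under one sample interval
  stp <- ifelse(t >= 110, 10, 0)
  expect_lte(measure_rise_time(stp, t, 100), 0.05)
  # difference of exponentials vs dense numerical oracle
  w <- simulate_psc_waveform(psc_params(failure_prob = 0), 100, 20000, 400)
  tw <- (seq_along(w) - 1) / 20
  td <- seq(0, 50, by = 1e-4)
  shape <- exp(-td / 20) - exp(-td / 1)
  pk <- max(shape)
  oracle <- td[which(shape >= 0.9 * pk)[1]] - td[which(shape >= 0.1 * pk)[1]]
  expect_equal(measure_rise_time(w, tw, 100), oracle, tolerance = 0.06)
})

test_that("reversal estimation interpolates, extrapolates and errors", {
  v <- seq(-70, 30, by = 20)
  expect_equal(estimate_reversal(v, 0.2 * (v + 70)), -70)
  expect_equal(estimate_reversal(c(-40, 0), c(-8, 8)), -20)
  expect_error(estimate_reversal(v, rep(0, 6)), "zero")
  expect_warning(r <- estimate_reversal(c(0, 20, 40), c(5, 7, 9)),
                 "extrapolated")
  expect_equal(as.numeric(r), -50)
  # noisy linear I-V: unbiased within 3 SE over 100 seeds
  revs <- vapply(1:100, function(s) {
    set.seed(s)
    suppressWarnings(
      as.numeric(estimate_reversal(v, 0.2 * (v + 70) + rnorm(6, 0, 0.3))))
  }, numeric(1))
  expect_lt(abs(mean(revs) + 70), 3 * sd(revs) / 10)
})

test_that("onset differences and peak ratios behave by definition", {
  fs <- 20000
  w1 <- simulate_psc_waveform(psc_params(failure_prob = 0), 100, fs, 500)
  w2 <- simulate_psc_waveform(psc_params(latency_ms = 9, failure_prob = 0),
                              100, fs, 500)
  t <- (seq_along(w1) - 1) / fs * 1000
  expect_equal(ei_onset_difference(w1, w1, t, 100), 0, tolerance = 1e-9)
  d <- ei_onset_difference(w1, w2, t, 100)
  expect_equal(d, 2, tolerance = 0.3)
  expect_equal(ei_onset_difference(w2, w1, t, 100), -d, tolerance = 1e-9)

  expect_equal(peak_ratio(w1, w1, t, 100), 1.0)
  expect_equal(peak_ratio(2 * w1, w1, t, 100), 2.0)
  # planted 15 vs 30 pA under noise: ratio 0.5 within 10% over seeds
  ratios <- vapply(1:50, function(s) {
    a <- average_sweeps(make_planted_sweeps(amplitude_pA = 15, seed = s))
    b <- average_sweeps(make_planted_sweeps(amplitude_pA = 30,
                                            seed = 1000 + s))
    peak_ratio(a$mean_trace, b$mean_trace, a$time_ms, 100)
  }, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.05)
  expect_error(peak_ratio(w1, 0 * w1, t, 100), "zero peak")
})

test_that("detector benchmark: high sensitivity, low false-positive rate", {
  verdicts_pos <- vapply(1:50, function(s)
    detect_connection(simulate_paired_recording(
      TRUE, psc = psc_params(failure_prob = 0), seed = s))$verdict,
    logical(1))
  verdicts_neg <- vapply(1:50, function(s)
    detect_connection(simulate_paired_recording(
      FALSE, seed = 2000 + s))$verdict, logical(1))
  expect_gte(mean(verdicts_pos), 0.95)
  expect_lte(mean(verdicts_neg), 0.05)
})
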