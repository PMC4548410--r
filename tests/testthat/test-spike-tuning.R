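# Spike detection, peristimulus histograms, and vector-sum direction
# selectivity.

test_that("threshold spike detection finds planted events", {
  fs <- 20000
  t <- (0:(2 * fs - 1)) / fs * 1000
  spike_shape <- function(t0) 50 * exp(-((t - t0) / 0.4)^2)
  trace <- spike_shape(300) + spike_shape(700) + spike_shape(1500)
  set.seed(1)
  trace <- trace + rnorm(length(t), 0, 1)
  got <- detect_spikes(trace, t, threshold = 25)
  expect_equal(length(got), 3L)
  expect_true(all(abs(got - c(300, 700, 1500)) < 1))

  expect_equal(length(detect_spikes(rep(0, 100), 1:100)), 0L)

  # MAD policy with planted Poisson spikes: recall and precision
  stats <- vapply(1:25, function(s) {
    set.seed(s)
    planted <- sort(runif(30, 10, 1990))
    planted <- planted[c(TRUE, diff(planted) > 5)]  # resolvable events
    tr <- rowSums(vapply(planted, spike_shape, numeric(length(t)))) +
      rnorm(length(t), 0, 2)
    got <- detect_spikes(tr, t)
    hit <- vapply(planted, function(p) any(abs(got - p) < 2), logical(1))
    matched <- vapply(got, function(g) any(abs(planted - g) < 2), logical(1))
    c(recall = mean(hit), precision = mean(matched))
  }, numeric(2))
  expect_gte(mean(stats["recall", ]), 0.99)
  expect_gte(mean(stats["precision", ]), 0.99)

  # a threshold inside the noise warns with an estimated false-event rate
  set.seed(2)
  expect_warning(detect_spikes(rnorm(2000), seq_len(2000) / 20,
                               threshold = 1), "false-event")
})

test_that("spike histograms are correctly normalised rates", {
  h <- spike_histogram(list(c(10, 20, 30, 40, 49)), bin_ms = 50, t_end = 100)
  expect_equal(h$rate_Hz, c(100, 0))
  # doubling trials with identical spikes leaves rates unchanged
  h2 <- spike_histogram(list(c(10, 20, 30, 40, 49), c(10, 20, 30, 40, 49)),
                        bin_ms = 50, t_end = 100)
  expect_equal(h2$rate_Hz, h$rate_Hz)
  # partial trailing bin dropped
  h3 <- spike_histogram(list(numeric(0)), bin_ms = 50, t_end = 120)
  expect_equal(nrow(h3), 2L)
  # homogeneous Poisson at rate r: bin mean within 3 SE
  r <- 40
  set.seed(3)
  trials <- lapply(1:200, function(i)
    sort(runif(rpois(1, r * 2), 0, 2000)))
  hp <- spike_histogram(trials, bin_ms = 50, t_end = 2000)
  se_overall <- sqrt(r / (200 * 2))  # 200 trials x 2 s of observation
  expect_lt(abs(mean(hp$rate_Hz) - r), 3 * se_overall)
  expect_error(spike_histogram(list()), "non-empty")
})

test_that("peak rates pick the maximal bin within each epoch", {
  h <- data.frame(bin_start_ms = seq(0, 950, 50),
                  bin_end_ms = seq(50, 1000, 50),
                  rate_Hz = rep(0, 20))
  h$rate_Hz[7] <- 80  # bin [300, 350)
  expect_equal(peak_rate_in_epoch(h, c(250, 500)), 80)
  expect_equal(peak_rate_in_epoch(h, c(500, 800)), 0)
  expect_error(peak_rate_in_epoch(h, c(300, 320)), "shorter than one")
})

test_that("DSI vector sum matches symmetry, limits, and the discrete oracle", {
  expect_error(compute_dsi(rep(0, 8), directions8), "zero")
  u <- compute_dsi(rep(7, 8), directions8)
  expect_lt(u$dsi_magnitude, 1e-12)
  s <- compute_dsi(c(0, 0, 0, 0, 0, 0, 12, 0), directions8)
  expect_equal(s$dsi_magnitude, 1)
  expect_equal(s$preferred_angle_deg, 270)
  # discrete von-Mises rates, kappa = 1, mu = 90: direct-summation oracle
  rates <- exp(cos((directions8 - 90) * pi / 180))
  z <- sum(rates * exp(1i * directions8 * pi / 180))
  oracle_mag <- Mod(z) / sum(rates)
  res <- compute_dsi(rates, directions8)
  expect_equal(res$dsi_magnitude, oracle_mag, tolerance = 1e-12)
  expect_equal(res$dsi_magnitude, 0.446, tolerance = 1e-3)
  expect_equal(res$preferred_angle_deg, 90)
})

test_that("DSI is scale invariant, rotation equivariant, and bounded", {
  set.seed(7)
  for (i in 1:200) {
    r <- runif(8, 0, 50)
    base <- compute_dsi(r, directions8)
    expect_true(base$dsi_magnitude >= 0 && base$dsi_magnitude <= 1)
    sc <- compute_dsi(r * runif(1, 0.1, 10), directions8)
    expect_equal(sc$dsi_magnitude, base$dsi_magnitude, tolerance = 1e-9)
    expect_equal(sc$preferred_angle_deg, base$preferred_angle_deg,
                 tolerance = 1e-6)
    delta <- sample(c(45, 90, 135), 1)
    rot <- compute_dsi(r, (directions8 + delta) %% 360)
    expect_equal(rot$dsi_magnitude, base$dsi_magnitude, tolerance = 1e-9)
    expect_equal(rot$preferred_angle_deg %% 360,
                 (base$preferred_angle_deg + delta) %% 360,
                 tolerance = 1e-6)
  }
})

test_that("angular summaries respect circular geometry", {
  expect_equal(deviation_from_ventral(270), 0)
  expect_equal(deviation_from_ventral(90), 180)
  expect_equal(deviation_from_ventral(240), 30)
  expect_equal(deviation_from_ventral(300), 30)
  on <- list(dsi_magnitude = 0.5, preferred_angle_deg = 90)
  off <- list(dsi_magnitude = 0.3, preferred_angle_deg = 270)
  d <- on_off_angle_difference(on, off)
  expect_equal(d$angle_difference_deg, 180)
  expect_equal(d$dsi_difference, 0.2)
  expect_equal(on_off_angle_difference(on, on)$angle_difference_deg, 0)
})

test_that("ventral projection is the signed alignment of the summed vector", {
  vent <- c(0, 0, 0, 0, 0, 0, 10, 0)  # all mass at 270
  expect_equal(ventral_projection(vent, vent, directions8), 1)
  dors <- c(0, 0, 10, 0, 0, 0, 0, 0)  # 90
  expect_equal(ventral_projection(dors, dors, directions8), -1)
  orth <- c(10, 0, 0, 0, 0, 0, 0, 0)  # 0 degrees, orthogonal to ventral
  expect_lt(abs(ventral_projection(orth, orth, directions8)), 1e-12)
})

test_that("programmed tuning is recovered from simulated spike trains", {
  res <- lapply(1:60, function(s)
    analyze_tuning(simulate_direction_response(
      tuning_params(preferred_angle_deg = 180, kappa = 2),
      n_reps = 50, seed = 6000 + s)))
  angles <- vapply(res, function(r) r$preferred_angle_deg, numeric(1))
  mags <- vapply(res, function(r) r$dsi_magnitude, numeric(1))
  circ_mean <- (Arg(mean(exp(1i * angles * pi / 180))) * 180 / pi) %% 360
  expect_lt(circular_diff(circ_mean, 180), 5)
  # discrete-sum oracle for the programmed tuning curve
  rates <- 2 + 60 * exp(2 * (cos((directions8 - 180) * pi / 180) - 1))
  oracle <- compute_dsi(rates, directions8)$dsi_magnitude
  expect_lt(abs(mean(mags) - oracle), 0.05)
  # the programmed direction attains the maximal peak rate on average
  peak_dirs <- vapply(res, function(r)
    r$peak_rates$direction_deg[which.max(r$peak_rates$on_peak_Hz)],
    numeric(1))
  expect_gte(mean(peak_dirs == 180), 0.8)
})
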