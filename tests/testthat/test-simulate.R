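# Synthetic-data generators: waveform shape, planted ground truth,
# determinism, and the statistical structure downstream stages assume.

test_that("PSC waveform peaks at its amplitude at the closed-form time", {
  fs <- 20000
  w <- simulate_psc_waveform(psc_params(), t0_ms = 100,
                             sampling_rate_Hz = fs, duration_ms = 400)
  t <- (seq_along(w) - 1) / fs * 1000
  expect_equal(max(w), 15, tolerance = 0.005)
  # closed-form argmax of the difference of exponentials:
  # t_peak = log(tau_d / tau_r) * tau_d * tau_r / (tau_d - tau_r)
  tp <- log(20 / 1) * 20 * 1 / (20 - 1)
  dense <- seq(0, 100, by = 1e-4)
  tp_num <- dense[which.max(exp(-dense / 20) - exp(-dense / 1))]
  expect_equal(tp, tp_num, tolerance = 1e-3)
  expect_equal(t[which.max(w)], 100 + 7 + tp, tolerance = 0.06)
  # onset: first sample above 1% of peak within one sample of t0 + latency
  onset <- t[which(w > 0.15)[1]]
  expect_lte(abs(onset - 107), 0.05 + 1e-9)
})

test_that("degenerate PSC inputs are handled", {
  w0 <- simulate_psc_waveform(psc_params(amplitude_pA = 0), 0, 20000, 150)
  expect_true(all(w0 == 0))
  expect_error(simulate_psc_waveform(psc_params(), 0, 20000, 50), "duration")
  expect_error(psc_params(tau_rise_ms = 5, tau_decay_ms = 2), "tau")
})

test_that("generators are pure functions of parameters and seed", {
  a <- simulate_paired_recording(TRUE, seed = 11)
  b <- simulate_paired_recording(TRUE, seed = 11)
  expect_identical(a, b)
  expect_false(identical(
    a$sweeps$traces, simulate_paired_recording(TRUE, seed = 12)$sweeps$traces))
  expect_identical(simulate_direction_response(n_reps = 4, seed = 3),
                   simulate_direction_response(n_reps = 4, seed = 3))
  expect_identical(simulate_mosaic(200, 20, seed = 5),
                   simulate_mosaic(200, 20, seed = 5))
  # the caller's RNG stream is untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(simulate_paired_recording(TRUE, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("connected recordings carry events matching their ground truth", {
  rec <- simulate_paired_recording(TRUE, noise_sd_pA = 2, n_trials = 10,
                                   seed = 2)
  truth <- rec$sweeps$meta$truth
  avg <- average_sweeps(rec$sweeps)
  pk <- max(avg$mean_trace) - avg$baseline_mean_pA
  # oracle: mean of the planted amplitudes (failures contribute zero)
  expected <- sum(truth$amplitude_pA[truth$present]) / 10
  expect_equal(pk, expected, tolerance = 0.15)
  expect_gte(pk, 12)
  expect_lte(pk, 18)
})

test_that("unconnected recordings show no event-sized averaged peak", {
  # Gaussian extreme-value oracle: the max over ~600 averaged noise samples
  # sits near sqrt(2 log 1200) ~ 3.8 SD, so excursions beyond 4.5 SD should
  # occur in only a fraction of a percent of windows -- and planted-event
  # peaks (>20 SD here) are far beyond either.
  n_exceed <- sum(vapply(1:100, function(s) {
    rec <- simulate_paired_recording(FALSE, seed = 3000 + s)
    avg <- average_sweeps(rec$sweeps)
    t <- avg$time_ms
    onset <- rec$sweeps$protocol$step_onset_ms
    win <- t >= onset & t <= onset + 30
    max(abs(avg$mean_trace[win] - avg$baseline_mean_pA)) >
      4.5 * avg$baseline_sd_pA
  }, logical(1)))
  expect_lte(n_exceed, 5)
})

test_that("autapse recordings are transient plus event plus noise", {
  # noiseless, no autapse: exactly the double exponential
  sw0 <- simulate_autapse_recording(FALSE, noise_sd_pA = 0, n_trials = 2,
                                    seed = 1)
  t <- (seq_len(ncol(sw0$traces)) - 1) / sw0$sampling_rate_Hz * 1000
  t_ret <- sw0$protocol$step_onset_ms + sw0$protocol$step_duration_ms
  ip <- intrinsic_params()
  s <- t - t_ret
  expected <- ifelse(s >= 0, ip$A1_pA * exp(-s / ip$tau1_ms) +
                       ip$A2_pA * exp(-s / ip$tau2_ms), 0)
  expect_equal(sw0$traces[1, ], expected, tolerance = 1e-12)

  # residual after subtracting known ground truth has the programmed SD
  sds <- vapply(1:50, function(seed) {
    sw <- simulate_autapse_recording(FALSE, noise_sd_pA = 2, n_trials = 1,
                                     seed = seed)
    sd(sw$traces[1, ] - expected)
  }, numeric(1))
  expect_equal(mean(sds), 2, tolerance = 0.02)
  expect_true(all(abs(sds - 2) / 2 < 0.10))

  # planted autapse: ~20 pA event on top of the transient
  sw1 <- simulate_autapse_recording(TRUE, noise_sd_pA = 0, n_trials = 1,
                                    seed = 1)
  extra <- sw1$traces[1, ] - expected
  expect_equal(max(extra), 20, tolerance = 0.005)
  expect_equal(sw1$meta$truth$amplitude_pA, 20)

  # an intrinsic transient violating the <100 ms decay bound is rejected
  expect_error(intrinsic_params(A2_pA = 50, tau2_ms = 80), "100 ms")
})

test_that("direction responses follow the programmed tuning", {
  # kappa = 0: all directions share one expected rate
  sts <- simulate_direction_response(tuning_params(kappa = 0,
                                                   peak_rate_Hz = 40,
                                                   baseline_rate_Hz = 0),
                                     n_reps = 40, seed = 2)
  counts <- vapply(sts$spikes, function(trials)
    mean(lengths(trials)), numeric(1))
  expect_lt(diff(range(counts)) / mean(counts), 0.35)

  # strong tuning: spikes concentrate near the preferred direction
  stk <- simulate_direction_response(tuning_params(kappa = 20,
                                                   peak_rate_Hz = 100,
                                                   baseline_rate_Hz = 0,
                                                   preferred_angle_deg = 90),
                                     n_reps = 5, seed = 3)
  n_by_dir <- vapply(stk$spikes, function(trials)
    sum(lengths(trials)), numeric(1))
  expect_gt(n_by_dir[["90"]], 0)
  expect_equal(sum(n_by_dir[setdiff(names(n_by_dir),
                                    c("45", "90", "135"))]), 0)

  # empirical per-direction ON rates within 3 SE of the programmed intensity
  tp <- tuning_params(preferred_angle_deg = 270, kappa = 2,
                      peak_rate_Hz = 60, baseline_rate_Hz = 2)
  n_reps <- 50
  stn <- simulate_direction_response(tp, n_reps = n_reps, seed = 4)
  on_dur_s <- diff(stn$epochs$on) / 1000
  for (i in seq_along(stn$directions_deg)) {
    th <- stn$directions_deg[i]
    lambda <- (tp$baseline_rate_Hz + tp$peak_rate_Hz *
                 exp(tp$kappa * (cos((th - 270) * pi / 180) - 1))) *
      on_dur_s * n_reps
    got <- sum(vapply(stn$spikes[[i]], function(tr)
      sum(tr >= stn$epochs$on[1] & tr < stn$epochs$on[2]), numeric(1)))
    expect_lt(abs(got - lambda), 3 * sqrt(lambda) + 1e-9)
  }

  expect_error(simulate_direction_response(directions_deg = numeric(0)),
               "non-empty")
})

test_that("mosaic sampler respects the hard-core constraint", {
  mos <- simulate_mosaic(400, exclusion_radius_um = 30,
                         field_um = c(1200, 1200), seed = 1)
  expect_gte(min(dist(mos$points)), 30)
  expect_lt(abs(mos$density_per_mm2 - 400) / 400, 0.10)

  # no-inhibition limit: the target count is placed
  mos0 <- simulate_mosaic(400, 0, c(1200, 1200), seed = 2)
  expect_equal(nrow(mos0$points), round(400 * 1.44))

  # mean nearest-neighbour distance exceeds the Poisson expectation
  # 1 / (2 sqrt(lambda)) when an exclusion zone is present
  nn <- function(p) {
    d <- as.matrix(dist(p)); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  lambda_um2 <- 400 / 1e6
  expect_gt(nn(mos$points), 1 / (2 * sqrt(lambda_um2)))

  # infeasible packing is reported, not silently truncated
  expect_error(simulate_mosaic(5000, 30, c(500, 500), seed = 3,
                               max_attempts_per_point = 200), "infeasible")
})

test_that("population connectivity tables reflect programmed probabilities", {
  m1 <- population_model(p_connect = within(default_p_connect(), p <- 1))
  t1 <- simulate_population_connectivity(m1, 50, seed = 1)
  expect_true(all(t1$connected_AB & t1$connected_BA))

  m0 <- population_model(p_connect = within(default_p_connect(), p <- 0))
  t0 <- simulate_population_connectivity(m0, 50, seed = 1)
  expect_false(any(t0$connected_AB | t0$connected_BA))

  # missing table cell is a structured error
  part <- default_p_connect()
  part <- part[!(part$bin == "near" & part$genotype == "Pcdhg22" &
                   part$age_group == "juvenile"), ]
  expect_error(
    simulate_population_connectivity(population_model(p_connect = part),
                                     50, seed = 1),
    "missing cell")
})

test_that("planted-event statistics match programmed distributions", {
  # amplitudes over many trials: mean 15, cv 0.2 (3 SE band)
  amps <- unlist(lapply(1:100, function(s) {
    tr <- simulate_paired_recording(TRUE, n_trials = 10, seed = 500 + s)
    tr$sweeps$meta$truth$amplitude_pA
  }))
  amps <- amps[!is.na(amps)]
  se <- 0.2 * 15 / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 15), 3 * se)
  # failure rate ~0.1
  pres <- unlist(lapply(1:100, function(s)
    simulate_paired_recording(TRUE, seed = 500 + s)$sweeps$meta$truth$present))
  expect_lt(abs(mean(!pres) - 0.1), 3 * sqrt(0.1 * 0.9 / length(pres)))
})
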