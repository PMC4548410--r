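# Helpers to build small, fully controlled sweep sets for detector tests.

# Sweep set with a PSC planted in an explicit subset of trials (no failures
# drawn at random), plus Gaussian noise. Defaults follow the paired
# protocol.
make_planted_sweeps <- function(present = rep(TRUE, 10), amplitude_pA = 15,
                                latency_ms = 7, tau_rise_ms = 1,
                                tau_decay_ms = 20, noise_sd_pA = 2,
                                protocol = paired_protocol(),
                                duration_ms = 400, seed = 1) {
  fs <- 20000
  n <- floor(duration_ms / 1000 * fs)
  psc <- psc_params(amplitude_pA = amplitude_pA, latency_ms = latency_ms,
                    tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                    failure_prob = 0, amp_cv = 0)
  wave <- simulate_psc_waveform(psc, protocol$step_onset_ms, fs, duration_ms)
  set.seed(seed)
  traces <- matrix(rnorm(length(present) * n, 0, noise_sd_pA),
                   nrow = length(present))
  for (i in which(present)) traces[i, ] <- traces[i, ] + wave
  sweep_set(traces, fs, protocol,
            meta = list(truth = list(present = present)))
}

make_planted_pair <- function(...) {
  pair_recording("pre", "post", 70, "Pcdhg22", "juvenile",
                 make_planted_sweeps(...))
}

directions8 <- seq(0, 315, by = 45)

circular_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}
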