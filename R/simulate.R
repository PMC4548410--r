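# Seeded generators for synthetic recordings, spike trains, mosaics and
# connectivity tables. Every generator is a pure function of (parameters,
# seed), and planted ground truth is always recorded in metadata so that
# downstream estimators can be tested against known values.

#' Postsynaptic-current waveform parameters
#'
#' Defaults describe the GABAergic currents evoked in paired starburst
#' amacrine cell recordings: ~15 pA peak, ~7 ms onset latency after the
#' presynaptic step, difference-of-exponentials kinetics with a sub-4-ms
#' 10-90% rise time.
#'
#' @param amplitude_pA peak amplitude in pA (outward positive), >= 0.
#' @param latency_ms onset latency after step onset (ms).
#' @param tau_rise_ms,tau_decay_ms kinetics of the difference-of-exponentials
#'   waveform; `tau_decay_ms > tau_rise_ms > 0`.
#' @param failure_prob per-trial probability that no event occurs.
#' @param amp_cv trial-to-trial coefficient of variation of the amplitude.
#' @return An object of class `psc_params`.
#' @export
psc_params <- function(amplitude_pA = 15, latency_ms = 7,
                       tau_rise_ms = 1, tau_decay_ms = 20,
                       failure_prob = 0.1, amp_cv = 0.2) {
  check_number(amplitude_pA, "amplitude_pA", lower = 0)
  check_number(latency_ms, "latency_ms", lower = 0)
  check_number(tau_rise_ms, "tau_rise_ms")
  check_number(tau_decay_ms, "tau_decay_ms")
  if (!(tau_decay_ms > tau_rise_ms && tau_rise_ms > 0))
    stop("kinetics must satisfy tau_decay_ms > tau_rise_ms > 0")
  check_number(failure_prob, "failure_prob", lower = 0, upper = 1)
  check_number(amp_cv, "amp_cv", lower = 0)
  structure(list(amplitude_pA = amplitude_pA, latency_ms = latency_ms,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms,
                 failure_prob = failure_prob, amp_cv = amp_cv),
            class = "psc_params")
}

#' Intrinsic depolarisation-evoked transient parameters
#'
#' The brief step to +60 mV used in autapse testing activates intrinsic
#' currents that decay within 100 ms of the return to -20 mV; they are
#' modelled as a sum of two decaying exponentials. The constructor rejects
#' parameter sets whose transient has not decayed below 5% of its peak by
#' 100 ms.
#'
#' @param A1_pA,tau1_ms fast component amplitude (pA) and time constant (ms).
#' @param A2_pA,tau2_ms slow component amplitude (pA) and time constant (ms).
#' @return An object of class `intrinsic_params`.
#' @export
intrinsic_params <- function(A1_pA = 200, tau1_ms = 5,
                             A2_pA = 50, tau2_ms = 30) {
  check_number(A1_pA, "A1_pA")
  check_number(A2_pA, "A2_pA")
  check_number(tau1_ms, "tau1_ms")
  check_number(tau2_ms, "tau2_ms")
  if (tau1_ms <= 0 || tau2_ms <= 0) stop("time constants must be > 0")
  peak <- A1_pA + A2_pA
  at100 <- A1_pA * exp(-100 / tau1_ms) + A2_pA * exp(-100 / tau2_ms)
  if (peak <= 0 || abs(at100) >= 0.05 * abs(peak))
    stop("intrinsic transient must decay below 5% of its peak within 100 ms")
  structure(list(A1_pA = A1_pA, tau1_ms = tau1_ms,
                 A2_pA = A2_pA, tau2_ms = tau2_ms),
            class = "intrinsic_params")
}

#' Direction-tuning parameters for simulated ganglion-cell responses
#'
#' Firing-rate modulation across motion directions follows a von Mises
#' shape: `rate(theta) = baseline + peak * exp(kappa * (cos(theta - mu) - 1))`.
#'
#' @param preferred_angle_deg preferred direction mu (degrees).
#' @param kappa concentration of the tuning curve, >= 0 (0 = untuned).
#' @param peak_rate_Hz tuned rate increment at the preferred direction.
#' @param baseline_rate_Hz direction-independent rate.
#' @param on_off_gain OFF-response rate relative to ON (1 = equal).
#' @return An object of class `tuning_params`.
#' @export
tuning_params <- function(preferred_angle_deg = 270, kappa = 2,
                          peak_rate_Hz = 60, baseline_rate_Hz = 2,
                          on_off_gain = 1) {
  check_number(preferred_angle_deg, "preferred_angle_deg")
  check_number(kappa, "kappa", lower = 0)
  check_number(peak_rate_Hz, "peak_rate_Hz", lower = 0)
  check_number(baseline_rate_Hz, "baseline_rate_Hz", lower = 0)
  check_number(on_off_gain, "on_off_gain", lower = 0)
  structure(list(preferred_angle_deg = preferred_angle_deg, kappa = kappa,
                 peak_rate_Hz = peak_rate_Hz,
                 baseline_rate_Hz = baseline_rate_Hz,
                 on_off_gain = on_off_gain),
            class = "tuning_params")
}

#' Population connectivity model
#'
#' Distance-, genotype- and age-dependent directed connection probabilities
#' plus per-genotype autapse probabilities. The default table encodes the
#' qualitative population structure of starburst amacrine cell pairs:
#' juveniles are more than twice as likely to be connected at 35-100 um than
#' at 100-175 um, adults lose the proximal connections, and autapses appear
#' in ~75% of Pcdhg0 cells but never in Pcdhg22 cells.
#'
#' @param p_connect data frame with columns `bin` (`"near"` = 35-100 um,
#'   `"far"` = 100-175 um), `genotype`, `age_group`, `p`.
#' @param distance_range_um range from which pair distances are drawn.
#' @param autapse_prob named vector of per-genotype autapse probabilities.
#' @param dendritic_radius_um dendritic field radius R (um); default 100.
#' @return An object of class `population_model`.
#' @export
population_model <- function(p_connect = default_p_connect(),
                             distance_range_um = c(35, 175),
                             autapse_prob = c(Pcdhg22 = 0, Pcdhg0 = 0.75,
                                              Pcdhg1 = 0),
                             dendritic_radius_um = 100) {
  req <- c("bin", "genotype", "age_group", "p")
  if (!is.data.frame(p_connect) || !all(req %in% names(p_connect)))
    stop("'p_connect' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (any(p_connect$p < 0 | p_connect$p > 1))
    stop("all connection probabilities must be in [0, 1]")
  if (any(autapse_prob < 0 | autapse_prob > 1))
    stop("all autapse probabilities must be in [0, 1]")
  check_number(dendritic_radius_um, "dendritic_radius_um")
  if (length(distance_range_um) != 2L ||
      distance_range_um[1] < 0 || diff(distance_range_um) <= 0)
    stop("'distance_range_um' must be an increasing nonnegative range")
  if (distance_range_um[2] > 2 * dendritic_radius_um)
    warning("distance range extends beyond 2R; such pairs have no ",
            "dendritic overlap")
  structure(list(p_connect = p_connect,
                 distance_range_um = distance_range_um,
                 autapse_prob = autapse_prob,
                 dendritic_radius_um = dendritic_radius_um),
            class = "population_model")
}

#' @describeIn population_model Default connection-probability table.
#'   Illustrative values consistent with the qualitative contrasts above;
#'   near = \[35, 100) um, far = \[100, 175\] um.
#' @export
default_p_connect <- function() {
  tbl <- expand.grid(bin = c("near", "far"),
                     genotype = GENOTYPES,
                     age_group = AGE_GROUPS,
                     stringsAsFactors = FALSE)
  p <- c(near_juv = 0.60, far_juv = 0.25, near_adult = 0.10,
         far_adult = 0.30)
  tbl$p <- ifelse(tbl$age_group == "juvenile",
                  ifelse(tbl$bin == "near", p[["near_juv"]], p[["far_juv"]]),
                  ifelse(tbl$bin == "near", p[["near_adult"]],
                         p[["far_adult"]]))
  # Single-isoform retinas connect at ~20% of control frequency.
  sel <- tbl$genotype == "Pcdhg1"
  tbl$p[sel] <- tbl$p[sel] * 0.2
  tbl
}

#' Noiseless postsynaptic-current waveform
#'
#' Difference-of-exponentials waveform
#' `A * (exp(-s/tau_d) - exp(-s/tau_r))`, `s = t - t0 - latency`, normalised
#' so that the continuous-time peak equals `amplitude_pA`.
#'
#' @param params a [psc_params()].
#' @param t0_ms event reference time (typically the step onset), ms.
#' @param sampling_rate_Hz sampling rate.
#' @param duration_ms sweep duration; must cover
#'   `t0 + latency + 5 * tau_decay`.
#' @return Numeric vector of current samples (pA).
#' @export
#' @examples
#' w <- simulate_psc_waveform(psc_params(), t0_ms = 0,
#'                            sampling_rate_Hz = 20000, duration_ms = 150)
#' max(w)  # ~15 pA
simulate_psc_waveform <- function(params, t0_ms, sampling_rate_Hz,
                                  duration_ms) {
  stopifnot(inherits(params, "psc_params"))
  check_number(t0_ms, "t0_ms", lower = 0)
  if (duration_ms < t0_ms + params$latency_ms + 5 * params$tau_decay_ms)
    stop("'duration_ms' must cover t0 + latency + 5 * tau_decay")
  n <- floor(duration_ms / 1000 * sampling_rate_Hz)
  t <- (seq_len(n) - 1L) / sampling_rate_Hz * 1000
  s <- t - t0_ms - params$latency_ms
  tr <- params$tau_rise_ms
  td <- params$tau_decay_ms
  # Peak of the unnormalised kernel, attained at s = log(td/tr)*td*tr/(td-tr).
  tp <- log(td / tr) * td * tr / (td - tr)
  norm <- exp(-tp / td) - exp(-tp / tr)
  w <- numeric(n)
  on <- s >= 0
  w[on] <- params$amplitude_pA * (exp(-s[on] / td) - exp(-s[on] / tr)) / norm
  w
}

#' Simulate a paired recording with an optional planted connection
#'
#' Each trial is Gaussian baseline noise; in connected recordings every
#' non-failure trial additionally carries one postsynaptic current
#' time-locked to the presynaptic step onset, with i.i.d. amplitude jitter
#' (normal with CV `psc$amp_cv`, truncated at 0). Ground truth (planted
#' amplitudes, per-trial event presence) is stored in `sweeps$meta$truth`.
#'
#' @param connected logical; plant events or not.
#' @param psc a [psc_params()].
#' @param noise_sd_pA Gaussian baseline noise SD, >= 0 (default 2 pA).
#' @param n_trials number of voltage-step repetitions (default 10).
#' @param protocol a [stimulus_protocol()]; default [paired_protocol()].
#' @param duration_ms sweep duration (ms).
#' @param distance_um,genotype,age_group pair annotations.
#' @param seed RNG seed.
#' @return A [pair_recording()].
#' @export
simulate_paired_recording <- function(connected, psc = psc_params(),
                                      noise_sd_pA = 2, n_trials = 10,
                                      protocol = paired_protocol(),
                                      duration_ms = 400,
                                      distance_um = 70,
                                      genotype = "Pcdhg22",
                                      age_group = "juvenile",
                                      seed = NULL) {
  check_flag(connected, "connected")
  check_number(noise_sd_pA, "noise_sd_pA", lower = 0)
  check_number(n_trials, "n_trials", lower = 1)
  with_seed(seed, {
    fs <- 20000  # acquisition rate of the recordings being emulated
    n <- floor(duration_ms / 1000 * fs)
    traces <- matrix(stats::rnorm(n_trials * n, 0, noise_sd_pA),
                     nrow = n_trials)
    present <- rep(FALSE, n_trials)
    amplitudes <- rep(NA_real_, n_trials)
    if (connected) {
      present <- stats::runif(n_trials) >= psc$failure_prob
      for (i in which(present)) {
        a <- stats::rnorm(1, psc$amplitude_pA,
                          psc$amp_cv * psc$amplitude_pA)
        a <- max(a, 0)
        amplitudes[i] <- a
        p_i <- psc
        p_i$amplitude_pA <- a
        traces[i, ] <- traces[i, ] +
          simulate_psc_waveform(p_i, protocol$step_onset_ms, fs, duration_ms)
      }
    }
    truth <- list(connected = connected, present = present,
                  amplitude_pA = amplitudes, latency_ms = psc$latency_ms,
                  noise_sd_pA = noise_sd_pA, seed = seed)
    sw <- sweep_set(traces, fs, protocol,
                    meta = list(truth = truth, genotype = genotype,
                                age_group = age_group))
    pair_recording("pre", "post", distance_um, genotype, age_group, sw)
  })
}

#' Simulate an autapse-protocol recording
#'
#' Each trial carries the intrinsic double-exponential transient starting at
#' the return to -20 mV, plus (when `has_autapse`) an outward postsynaptic
#' current whose latency is referenced to the start of the depolarising step
#' to +60 mV, plus Gaussian noise. Ground truth is stored in `meta$truth`.
#'
#' @param has_autapse logical; plant an autaptic event or not.
#' @param intrinsic an [intrinsic_params()].
#' @param psc a [psc_params()]; default 20 pA amplitude, the typical autaptic
#'   current size.
#' @param noise_sd_pA Gaussian noise SD (default 2 pA).
#' @param n_trials repetitions (default 10).
#' @param protocol an [autaptic_protocol()].
#' @param duration_ms sweep duration (ms).
#' @param genotype,age_group cell annotations stored in metadata.
#' @param seed RNG seed.
#' @return A [sweep_set()].
#' @export
simulate_autapse_recording <- function(has_autapse,
                                       intrinsic = intrinsic_params(),
                                       psc = psc_params(amplitude_pA = 20),
                                       noise_sd_pA = 2, n_trials = 10,
                                       protocol = autaptic_protocol(),
                                       duration_ms = 300,
                                       genotype = "Pcdhg0",
                                       age_group = "juvenile",
                                       seed = NULL) {
  check_flag(has_autapse, "has_autapse")
  check_number(noise_sd_pA, "noise_sd_pA", lower = 0)
  stopifnot(inherits(intrinsic, "intrinsic_params"))
  with_seed(seed, {
    fs <- 20000
    n <- floor(duration_ms / 1000 * fs)
    t <- (seq_len(n) - 1L) / fs * 1000
    t_ret <- protocol$step_onset_ms + protocol$step_duration_ms
    base <- numeric(n)
    s <- t - t_ret
    on <- s >= 0
    base[on] <- intrinsic$A1_pA * exp(-s[on] / intrinsic$tau1_ms) +
      intrinsic$A2_pA * exp(-s[on] / intrinsic$tau2_ms)
    if (has_autapse)
      base <- base + simulate_psc_waveform(psc, protocol$step_onset_ms, fs,
                                           duration_ms)
    traces <- matrix(stats::rnorm(n_trials * n, 0, noise_sd_pA),
                     nrow = n_trials)
    traces <- sweep(traces, 2L, base, `+`)
    truth <- list(has_autapse = has_autapse, intrinsic = unclass(intrinsic),
                  amplitude_pA = if (has_autapse) psc$amplitude_pA else 0,
                  latency_ms = psc$latency_ms, noise_sd_pA = noise_sd_pA,
                  seed = seed)
    sweep_set(traces, fs, protocol,
              meta = list(truth = truth, genotype = genotype,
                          age_group = age_group))
  })
}

#' Simulate direction-tuned spike trains for a moving-bar stimulus
#'
#' A bright bar sweeps over the receptive field at `bar_speed_um_s` in each
#' of the listed directions. The leading edge crossing a
#' `rf_width_um`-wide window centred on the soma defines the ON epoch; the
#' trailing edge crossing defines the OFF epoch. Spikes are drawn from an
#' inhomogeneous Poisson process whose ON-epoch rate is
#' `baseline + peak * exp(kappa * (cos(theta - mu) - 1))` and whose
#' OFF-epoch rate is the same scaled by `on_off_gain`.
#'
#' @param tuning a [tuning_params()].
#' @param directions_deg motion directions; default the 8 cardinal and
#'   oblique directions 0, 45, ..., 315.
#' @param n_reps repetitions per direction, >= 1 (default 4).
#' @param bar_speed_um_s bar speed (default 1000 um/s).
#' @param bar_length_um bar length along the motion axis (default 1000 um).
#' @param rf_width_um receptive-field window width (default 300 um).
#' @param seed RNG seed.
#' @return A `spike_train_set` (see [spike_train_set()]), with the
#'   programmed tuning in `meta$truth`.
#' @export
simulate_direction_response <- function(tuning = tuning_params(),
                                        directions_deg = seq(0, 315, by = 45),
                                        n_reps = 4,
                                        bar_speed_um_s = 1000,
                                        bar_length_um = 1000,
                                        rf_width_um = 300,
                                        seed = NULL) {
  stopifnot(inherits(tuning, "tuning_params"))
  if (length(directions_deg) == 0L) stop("'directions_deg' must be non-empty")
  check_number(n_reps, "n_reps", lower = 1)
  lead_in_ms <- 500
  on_dur <- rf_width_um / bar_speed_um_s * 1000
  off_start <- lead_in_ms + bar_length_um / bar_speed_um_s * 1000
  sweep_ms <- off_start + on_dur + 200
  epochs <- list(on = c(lead_in_ms, lead_in_ms + on_dur),
                 off = c(off_start, off_start + on_dur))
  with_seed(seed, {
    spikes <- lapply(directions_deg, function(theta) {
      mod <- exp(tuning$kappa *
                   (cos((theta - tuning$preferred_angle_deg) * pi / 180) - 1))
      on_rate <- tuning$baseline_rate_Hz + tuning$peak_rate_Hz * mod
      off_rate <- tuning$baseline_rate_Hz +
        tuning$on_off_gain * tuning$peak_rate_Hz * mod
      lapply(seq_len(n_reps), function(rep) {
        # piecewise-constant intensity: baseline outside epochs, elevated in
        # the ON and OFF windows
        segs <- rbind(c(0, epochs$on[1], tuning$baseline_rate_Hz),
                      c(epochs$on[1], epochs$on[2], on_rate),
                      c(epochs$on[2], epochs$off[1], tuning$baseline_rate_Hz),
                      c(epochs$off[1], epochs$off[2], off_rate),
                      c(epochs$off[2], sweep_ms, tuning$baseline_rate_Hz))
        ts <- unlist(lapply(seq_len(nrow(segs)), function(k) {
          dur_s <- (segs[k, 2] - segs[k, 1]) / 1000
          m <- stats::rpois(1, segs[k, 3] * dur_s)
          if (m == 0) return(numeric(0))
          segs[k, 1] + sort(stats::runif(m, 0, segs[k, 2] - segs[k, 1]))
        }))
        unique(sort(ts))
      })
    })
    names(spikes) <- as.character(directions_deg)
    spike_train_set(spikes, directions_deg = directions_deg,
                    epochs = epochs, sweep_ms = sweep_ms,
                    axis_convention = c(ventral = 270),
                    meta = list(truth = c(unclass(tuning),
                                          list(seed = seed))))
  })
}

#' Simulate a hard-core cell mosaic
#'
#' Random sequential adsorption: points are drawn uniformly over the field
#' and rejected if they fall within `exclusion_radius_um` of an accepted
#' point. With `exclusion_radius_um = 0` this is a homogeneous Poisson
#' sample of the target count.
#'
#' @param density_per_mm2 target density (cells per mm^2).
#' @param exclusion_radius_um hard-core exclusion radius (um), >= 0.
#' @param field_um field side lengths, length-2 vector (um).
#' @param seed RNG seed.
#' @param max_attempts_per_point rejection cap per point before the target
#'   is declared infeasible.
#' @return An object of class `mosaic`: list with `points` (n x 2 matrix,
#'   um), `field_extent_um`, `density_per_mm2` (achieved).
#' @export
simulate_mosaic <- function(density_per_mm2, exclusion_radius_um = 0,
                            field_um = c(1000, 1000), seed = NULL,
                            max_attempts_per_point = 1e4) {
  check_number(density_per_mm2, "density_per_mm2", lower = 0)
  check_number(exclusion_radius_um, "exclusion_radius_um", lower = 0)
  area_mm2 <- prod(field_um) / 1e6
  n_target <- round(density_per_mm2 * area_mm2)
  with_seed(seed, {
    pts <- matrix(numeric(0), ncol = 2)
    r2 <- exclusion_radius_um^2
    for (i in seq_len(n_target)) {
      placed <- FALSE
      for (a in seq_len(max_attempts_per_point)) {
        cand <- stats::runif(2) * field_um
        if (nrow(pts) == 0L ||
            min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r2) {
          pts <- rbind(pts, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0("infeasible mosaic: placed %d of %d points at ",
                            "exclusion radius %g um"),
                     nrow(pts), n_target, exclusion_radius_um))
    }
    achieved <- nrow(pts) / area_mm2
    structure(list(points = unname(pts), field_extent_um = field_um,
                   cell_type_label = "synthetic",
                   density_per_mm2 = achieved,
                   target_density_per_mm2 = density_per_mm2,
                   exclusion_radius_um = exclusion_radius_um),
              class = "mosaic")
  })
}

#' Simulate a population connectivity table
#'
#' For each pair a soma-to-soma distance is drawn uniformly from the model's
#' distance range, and the two directed connections are independent
#' Bernoulli draws at the probability for that (distance bin, genotype, age)
#' cell. Connected directions get a peak amplitude drawn as in
#' [simulate_paired_recording()]. The programmed probability is recorded per
#' row.
#'
#' @param model a [population_model()].
#' @param n_pairs number of pairs, >= 1.
#' @param genotype,age_group cohort labels.
#' @param amp_mean_pA,amp_cv amplitude distribution for connected directions.
#' @param seed RNG seed.
#' @return A `connectivity_table` data frame (see [connectivity_table()]).
#' @export
simulate_population_connectivity <- function(model = population_model(),
                                             n_pairs,
                                             genotype = "Pcdhg22",
                                             age_group = "juvenile",
                                             amp_mean_pA = 15, amp_cv = 0.2,
                                             seed = NULL) {
  stopifnot(inherits(model, "population_model"))
  check_number(n_pairs, "n_pairs", lower = 1)
  check_choice(genotype, "genotype", GENOTYPES)
  check_choice(age_group, "age_group", AGE_GROUPS)
  with_seed(seed, {
    d <- stats::runif(n_pairs, model$distance_range_um[1],
                      model$distance_range_um[2])
    bin <- ifelse(d < 100, "near", "far")
    p <- vapply(bin, function(b) {
      row <- model$p_connect$p[model$p_connect$bin == b &
                                 model$p_connect$genotype == genotype &
                                 model$p_connect$age_group == age_group]
      if (length(row) != 1L)
        stop(sprintf("p_connect table is missing cell (%s, %s, %s)",
                     b, genotype, age_group))
      row
    }, 1)
    con_ab <- stats::runif(n_pairs) < p
    con_ba <- stats::runif(n_pairs) < p
    amp <- function(sel) {
      a <- rep(NA_real_, n_pairs)
      a[sel] <- pmax(stats::rnorm(sum(sel), amp_mean_pA,
                                  amp_cv * amp_mean_pA), 0)
      a
    }
    tbl <- connectivity_table(data.frame(
      pair_id = sprintf("pair%05d", seq_len(n_pairs)),
      distance_um = d,
      genotype = genotype,
      age_group = age_group,
      tested_AB = TRUE, connected_AB = con_ab,
      tested_BA = TRUE, connected_BA = con_ba,
      peak_pA_AB = amp(con_ab), peak_pA_BA = amp(con_ba),
      p_true = p,
      stringsAsFactors = FALSE))
    attr(tbl, "truth") <- list(model = model, seed = seed)
    tbl
  })
}
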