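# Spike detection, peristimulus histograms and vector-sum direction
# selectivity for 8-direction moving-bar responses.

#' Spike trains across motion directions
#'
#' @param spikes named list (one element per direction, names = degrees) of
#'   lists of numeric vectors (spike times in ms, one vector per trial,
#'   strictly increasing).
#' @param directions_deg motion directions in degrees.
#' @param epochs list with `on` and `off`, each a length-2 ms interval.
#' @param sweep_ms sweep duration (ms).
#' @param axis_convention named numeric vector mapping retinal axes to
#'   angles; must contain `ventral` (default 270 degrees).
#' @param meta optional metadata list.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, directions_deg, epochs, sweep_ms,
                            axis_convention = c(ventral = 270),
                            meta = list()) {
  if (length(spikes) != length(directions_deg))
    stop("'spikes' must have one element per direction")
  if (!("ventral" %in% names(axis_convention)))
    stop("'axis_convention' must map 'ventral' to an angle")
  for (d in seq_along(spikes)) {
    for (trial in spikes[[d]]) {
      if (length(trial) && (any(trial < 0) || any(trial > sweep_ms)))
        stop("spike times must lie within [0, sweep_ms]")
      if (length(trial) > 1L && any(diff(trial) <= 0))
        stop("spike times must be strictly increasing within a trial")
    }
  }
  structure(list(spikes = spikes, directions_deg = directions_deg,
                 epochs = epochs, sweep_ms = sweep_ms,
                 axis_convention = axis_convention, meta = meta),
            class = "spike_train_set")
}

#' Detect spikes by thresholding
#'
#' Upward threshold crossings with a 1 ms refractory period. The default
#' threshold policy is `median + 5 * MAD` of the trace; an absolute
#' threshold may be given instead.
#'
#' @param trace loose-patch-style voltage or current trace.
#' @param time_ms sample times (ms).
#' @param threshold absolute threshold, or `NULL` to use the MAD policy.
#' @param mad_mult multiplier for the MAD policy (default 5).
#' @param refractory_ms minimum inter-spike interval (default 1 ms).
#' @return Numeric vector of spike times (ms). If the threshold sits below
#'   the estimated noise ceiling a warning reports the expected false-event
#'   rate.
#' @export
detect_spikes <- function(trace, time_ms, threshold = NULL, mad_mult = 5,
                          refractory_ms = 1) {
  if (is.null(threshold))
    threshold <- stats::median(trace) + mad_mult * stats::mad(trace)
  noise_sd <- stats::mad(trace)
  if (noise_sd > 0) {
    z <- (threshold - stats::median(trace)) / noise_sd
    if (z < 3) {
      dt_s <- mean(diff(time_ms)) / 1000
      rate <- stats::pnorm(z, lower.tail = FALSE) / dt_s
      warning(sprintf(paste0("threshold is only %.1f noise SD above the ",
                             "median; expected false-event rate ~%.1f Hz"),
                      z, rate))
    }
  }
  up <- which(trace[-1] >= threshold & trace[-length(trace)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- time_ms[up]
  keep <- times[1]
  for (tm in times[-1])
    if (tm - keep[length(keep)] >= refractory_ms) keep <- c(keep, tm)
  keep
}

#' Peristimulus spike histogram
#'
#' Counts per bin divided by bin width and trial count, in Hz. Bins are
#' anchored at `t_start` (stimulus onset); a partial trailing bin is
#' dropped.
#'
#' @param spikes list of spike-time vectors (ms), one per trial.
#' @param bin_ms bin width (default 50 ms).
#' @param t_start,t_end histogram range (ms).
#' @return Data frame with `bin_start_ms`, `bin_end_ms`, `rate_Hz`.
#' @export
#' @examples
#' spike_histogram(list(c(10, 20, 30, 40, 49)), bin_ms = 50, t_end = 100)
spike_histogram <- function(spikes, bin_ms = 50, t_start = 0, t_end) {
  if (!is.list(spikes) || length(spikes) == 0L)
    stop("'spikes' must be a non-empty list of per-trial spike times")
  check_number(bin_ms, "bin_ms")
  n_bins <- floor((t_end - t_start) / bin_ms)
  if (n_bins < 1L) stop("histogram range shorter than one bin")
  edges <- t_start + bin_ms * (0:n_bins)
  counts <- numeric(n_bins)
  for (trial in spikes) {
    tr <- trial[trial >= t_start & trial < edges[n_bins + 1L]]
    if (length(tr))
      counts <- counts + tabulate(findInterval(tr, edges,
                                               rightmost.closed = FALSE),
                                  nbins = n_bins)
  }
  data.frame(bin_start_ms = edges[-(n_bins + 1L)],
             bin_end_ms = edges[-1L],
             rate_Hz = counts / (bin_ms / 1000) / length(spikes))
}

#' Peak firing rate within an epoch
#'
#' Maximum histogram bin rate among bins lying entirely inside the epoch.
#'
#' @param hist a histogram from [spike_histogram()].
#' @param epoch length-2 interval (ms).
#' @return Peak rate in Hz (0 for an empty epoch).
#' @export
peak_rate_in_epoch <- function(hist, epoch) {
  inside <- hist$bin_start_ms >= epoch[1] & hist$bin_end_ms <= epoch[2]
  if (!any(inside))
    stop("epoch shorter than one histogram bin")
  max(hist$rate_Hz[inside])
}

#' Per-direction ON and OFF peak firing rates
#'
#' @param sts a [spike_train_set()].
#' @param bin_ms histogram bin width (default 50 ms).
#' @return Data frame with `direction_deg`, `on_peak_Hz`, `off_peak_Hz`.
#' @export
peak_rates <- function(sts, bin_ms = 50) {
  stopifnot(inherits(sts, "spike_train_set"))
  rows <- lapply(seq_along(sts$directions_deg), function(i) {
    h <- spike_histogram(sts$spikes[[i]], bin_ms = bin_ms,
                         t_start = 0, t_end = sts$sweep_ms)
    data.frame(direction_deg = sts$directions_deg[i],
               on_peak_Hz = peak_rate_in_epoch(h, sts$epochs$on),
               off_peak_Hz = peak_rate_in_epoch(h, sts$epochs$off))
  })
  do.call(rbind, rows)
}

#' Vector-sum direction-selectivity index
#'
#' `DSI = |sum_i r_i exp(i theta_i)| / sum_i r_i`; the argument of the sum
#' is the preferred direction. Bounded in [0, 1] for nonnegative rates.
#'
#' @param rates_Hz nonnegative peak firing rates, one per direction.
#' @param directions_deg matching motion directions (degrees).
#' @return List with `dsi_magnitude` and `preferred_angle_deg` (in
#'   [0, 360)).
#' @export
#' @examples
#' compute_dsi(c(0, 0, 0, 0, 0, 0, 10, 0), seq(0, 315, by = 45))
compute_dsi <- function(rates_Hz, directions_deg) {
  if (length(rates_Hz) != length(directions_deg))
    stop("'rates_Hz' and 'directions_deg' must have equal length")
  if (any(rates_Hz < 0)) stop("rates must be nonnegative")
  total <- sum(rates_Hz)
  if (total == 0) stop("all rates are zero; DSI undefined")
  th <- directions_deg * pi / 180
  vx <- sum(rates_Hz * cos(th))
  vy <- sum(rates_Hz * sin(th))
  list(dsi_magnitude = sqrt(vx^2 + vy^2) / total,
       preferred_angle_deg = (atan2(vy, vx) * 180 / pi) %% 360)
}

#' Angular deviation of a preferred direction from ventral
#'
#' Minimal absolute circular difference, in \[0, 180\] degrees.
#'
#' @param preferred_angle_deg preferred direction (degrees).
#' @param axis_convention named vector with a `ventral` angle (default 270).
#' @return Deviation in degrees.
#' @export
deviation_from_ventral <- function(preferred_angle_deg,
                                   axis_convention = c(ventral = 270)) {
  if (!("ventral" %in% names(axis_convention)))
    stop("'axis_convention' must map 'ventral' to an angle")
  circular_diff_deg(preferred_angle_deg, axis_convention[["ventral"]])
}

#' Difference between ON and OFF tuning
#'
#' @param on,off `tuning_result` objects (see [analyze_tuning()]).
#' @return List with `angle_difference_deg` (minimal circular difference of
#'   preferred angles) and `dsi_difference` (absolute DSI-magnitude
#'   difference).
#' @export
on_off_angle_difference <- function(on, off) {
  if (is.na(on$preferred_angle_deg) || is.na(off$preferred_angle_deg))
    stop("tuning undefined on one side")
  list(angle_difference_deg = circular_diff_deg(on$preferred_angle_deg,
                                                off$preferred_angle_deg),
       dsi_difference = abs(on$dsi_magnitude - off$dsi_magnitude))
}

#' Ventral projection of the combined ON+OFF DSI vector
#'
#' Maximal ON and OFF rates in each direction are summed, a single DSI
#' vector is computed from the sums, and its projection (dot product) onto
#' the unit ventral vector is returned. Positive values indicate ventral
#' preference.
#'
#' @param on_rates_Hz,off_rates_Hz per-direction peak rates.
#' @param directions_deg matching directions (degrees).
#' @param axis_convention named vector with a `ventral` angle.
#' @return Signed scalar in [-1, 1].
#' @export
ventral_projection <- function(on_rates_Hz, off_rates_Hz, directions_deg,
                               axis_convention = c(ventral = 270)) {
  summed <- on_rates_Hz + off_rates_Hz
  dsi <- compute_dsi(summed, directions_deg)
  phi <- (dsi$preferred_angle_deg - axis_convention[["ventral"]]) * pi / 180
  dsi$dsi_magnitude * cos(phi)
}

#' Full direction-tuning summary of a spike-train set
#'
#' Computes per-direction ON and OFF peak rates, ON and OFF vector-sum DSIs,
#' the deviation of the ON preferred angle from ventral, ON-OFF differences,
#' and the ventral projection of the combined DSI vector.
#'
#' @param sts a [spike_train_set()].
#' @param bin_ms histogram bin width (default 50 ms).
#' @return An object of class `tuning_result`.
#' @export
#' @examples
#' sts <- simulate_direction_response(n_reps = 8, seed = 1)
#' analyze_tuning(sts)
analyze_tuning <- function(sts, bin_ms = 50) {
  pr <- peak_rates(sts, bin_ms = bin_ms)
  on <- compute_dsi(pr$on_peak_Hz, pr$direction_deg)
  off <- compute_dsi(pr$off_peak_Hz, pr$direction_deg)
  both <- on_off_angle_difference(on, off)
  structure(
    list(peak_rates = pr,
         dsi_magnitude = on$dsi_magnitude,
         preferred_angle_deg = on$preferred_angle_deg,
         off_dsi_magnitude = off$dsi_magnitude,
         off_preferred_angle_deg = off$preferred_angle_deg,
         deviation_from_ventral_deg =
           deviation_from_ventral(on$preferred_angle_deg,
                                  sts$axis_convention),
         on_off_angle_difference_deg = both$angle_difference_deg,
         on_off_dsi_difference = both$dsi_difference,
         ventral_projection = ventral_projection(pr$on_peak_Hz,
                                                 pr$off_peak_Hz,
                                                 pr$direction_deg,
                                                 sts$axis_convention)),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf(paste0("<tuning_result> ON DSI %.3f @ %.0f deg ",
                     "(%.0f deg off ventral); OFF DSI %.3f @ %.0f deg\n"),
              x$dsi_magnitude, x$preferred_angle_deg,
              x$deviation_from_ventral_deg, x$off_dsi_magnitude,
              x$off_preferred_angle_deg))
  invisible(x)
}

#' @export
as.data.frame.tuning_result <- function(x, ...) {
  data.frame(dsi_magnitude = x$dsi_magnitude,
             preferred_angle_deg = x$preferred_angle_deg,
             off_dsi_magnitude = x$off_dsi_magnitude,
             off_preferred_angle_deg = x$off_preferred_angle_deg,
             deviation_from_ventral_deg = x$deviation_from_ventral_deg,
             on_off_angle_difference_deg = x$on_off_angle_difference_deg,
             on_off_dsi_difference = x$on_off_dsi_difference,
             ventral_projection = x$ventral_projection)
}
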