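# Domain containers for voltage-clamp sweep data and their on-disk format.
#
# Unit conventions, enforced at construction: currents in pA with outward
# current positive (IPSCs recorded at depolarised holding potentials are
# positive deflections), times in ms, potentials in mV, distances in um.

GENOTYPES <- c("Pcdhg22", "Pcdhg0", "Pcdhg1")
AGE_GROUPS <- c("juvenile", "adult")

#' Voltage-step stimulus protocol
#'
#' Describes the presynaptic voltage-step protocol of a sweep set: when the
#' step starts, how long it lasts, the holding and step potentials, and the
#' window blanked around each step transition to exclude stimulus artifacts.
#'
#' @param step_onset_ms time of step onset from sweep start (ms), >= 0.
#' @param step_duration_ms duration of the depolarising step (ms), > 0.
#' @param v_hold_pre_mV presynaptic holding potential (mV).
#' @param v_step_mV step target potential (mV).
#' @param v_hold_post_mV postsynaptic holding potential (mV).
#' @param artifact_blank_ms window excluded after each step transition (ms),
#'   >= 0. Default 1 ms: shorter than the 12 ms latency criterion, longer
#'   than typical capacitive transients.
#'
#' @return An object of class `stimulus_protocol`.
#' @export
#' @examples
#' paired_protocol()
stimulus_protocol <- function(step_onset_ms, step_duration_ms,
                              v_hold_pre_mV, v_step_mV, v_hold_post_mV,
                              artifact_blank_ms = 1.0) {
  check_number(step_onset_ms, "step_onset_ms", lower = 0)
  check_number(step_duration_ms, "step_duration_ms")
  if (step_duration_ms <= 0) stop("'step_duration_ms' must be > 0")
  check_number(v_hold_pre_mV, "v_hold_pre_mV")
  check_number(v_step_mV, "v_step_mV")
  check_number(v_hold_post_mV, "v_hold_post_mV")
  check_number(artifact_blank_ms, "artifact_blank_ms", lower = 0)
  structure(
    list(step_onset_ms = step_onset_ms,
         step_duration_ms = step_duration_ms,
         v_hold_pre_mV = v_hold_pre_mV,
         v_step_mV = v_step_mV,
         v_hold_post_mV = v_hold_post_mV,
         artifact_blank_ms = artifact_blank_ms),
    class = "stimulus_protocol")
}

#' @describeIn stimulus_protocol Paired-recording protocol: 200 ms step from
#'   -70 to +20 mV in the presynaptic cell, postsynaptic cell held at +30 mV.
#' @export
paired_protocol <- function(step_onset_ms = 100, artifact_blank_ms = 1.0) {
  stimulus_protocol(step_onset_ms = step_onset_ms, step_duration_ms = 200,
                    v_hold_pre_mV = -70, v_step_mV = 20, v_hold_post_mV = 30,
                    artifact_blank_ms = artifact_blank_ms)
}

#' @describeIn stimulus_protocol Autaptic protocol: brief (2-4 ms) step from
#'   -70 to +60 mV followed by a return to -20 mV in the same cell.
#' @param step_ms step duration for the autaptic protocol (ms), in [2, 4].
#' @export
autaptic_protocol <- function(step_onset_ms = 100, step_ms = 2,
                              artifact_blank_ms = 1.0) {
  check_number(step_ms, "step_ms", lower = 2, upper = 4)
  stimulus_protocol(step_onset_ms = step_onset_ms, step_duration_ms = step_ms,
                    v_hold_pre_mV = -70, v_step_mV = 60, v_hold_post_mV = -20,
                    artifact_blank_ms = artifact_blank_ms)
}

#' Sweep set: a trial-by-sample matrix of membrane current
#'
#' @param traces numeric matrix, trials in rows, samples in columns, membrane
#'   current in pA (outward positive). All values must be finite.
#' @param sampling_rate_Hz samples per second, > 0.
#' @param protocol a [stimulus_protocol()].
#' @param meta optional named list of metadata (genotype, age group, planted
#'   ground truth from the simulators, ...).
#'
#' @return An object of class `sweep_set` with elements `traces`,
#'   `sampling_rate_Hz`, `protocol`, `n_trials` and `meta`.
#' @export
sweep_set <- function(traces, sampling_rate_Hz, protocol, meta = list()) {
  if (!is.matrix(traces) || !is.numeric(traces))
    stop("'traces' must be a numeric matrix (trials x samples)")
  if (nrow(traces) < 1L) stop("'traces' must contain at least one trial")
  if (!all(is.finite(traces)))
    stop("'traces' must contain finite values only (current in pA)")
  check_number(sampling_rate_Hz, "sampling_rate_Hz")
  if (sampling_rate_Hz <= 0) stop("'sampling_rate_Hz' must be > 0")
  if (!inherits(protocol, "stimulus_protocol"))
    stop("'protocol' must be a stimulus_protocol object")
  if (!is.list(meta)) stop("'meta' must be a list")
  structure(
    list(traces = traces,
         sampling_rate_Hz = sampling_rate_Hz,
         protocol = protocol,
         n_trials = nrow(traces),
         meta = meta),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d trials x %d samples @ %g kHz (%.1f ms)\n",
              x$n_trials, ncol(x$traces), x$sampling_rate_Hz / 1000,
              ncol(x$traces) / x$sampling_rate_Hz * 1000))
  cat(sprintf("  step: %g ms after sweep start, %g ms, %g -> %g mV\n",
              x$protocol$step_onset_ms, x$protocol$step_duration_ms,
              x$protocol$v_hold_pre_mV, x$protocol$v_step_mV))
  invisible(x)
}

# Time axis of a sweep set, in ms from sweep start.
sweep_time_ms <- function(sweeps) {
  (seq_len(ncol(sweeps$traces)) - 1L) / sweeps$sampling_rate_Hz * 1000
}

#' Paired recording between two cells
#'
#' Bundles the postsynaptic sweep set of one directed test between two cells
#' with pair-level annotations.
#'
#' @param pre_cell_id,post_cell_id cell identifiers (character).
#' @param distance_um soma-to-soma distance in um, >= 0.
#' @param genotype one of `"Pcdhg22"`, `"Pcdhg0"`, `"Pcdhg1"`.
#' @param age_group `"juvenile"` (P15-24) or `"adult"` (P40-100).
#' @param sweeps a [sweep_set()] of postsynaptic current traces.
#'
#' @return An object of class `pair_recording`.
#' @export
pair_recording <- function(pre_cell_id, post_cell_id, distance_um,
                           genotype, age_group, sweeps) {
  check_number(distance_um, "distance_um", lower = 0)
  check_choice(genotype, "genotype", GENOTYPES)
  check_choice(age_group, "age_group", AGE_GROUPS)
  if (!inherits(sweeps, "sweep_set")) stop("'sweeps' must be a sweep_set")
  structure(
    list(pre_cell_id = as.character(pre_cell_id),
         post_cell_id = as.character(post_cell_id),
         distance_um = distance_um,
         genotype = genotype,
         age_group = age_group,
         sweeps = sweeps),
    class = "pair_recording")
}

#' Detection result for a connection or autapse test
#'
#' Constructed by [detect_connection()] and [detect_autapse()]; users rarely
#' build one directly.
#'
#' @param verdict logical; `TRUE` only if every criterion passed.
#' @param peak_pA signed peak of the averaged (or residual) trace relative to
#'   baseline within the search window.
#' @param latency_ms Boltzmann-fit onset latency (ms), `NA` if no peak.
#' @param rise_10_90_ms 10-90% rise time (ms), `NA` if no peak.
#' @param trial_fraction fraction of trials with a deflection, in [0, 1].
#' @param criteria named logical vector of per-criterion outcomes.
#' @param baseline_sd_pA SD of the averaged-trace baseline.
#' @param anomaly logical; post-hoc flag for large baseline deviations.
#'
#' @return An object of class `detection_result`.
#' @export
detection_result <- function(verdict, peak_pA, latency_ms, rise_10_90_ms,
                             trial_fraction, criteria, baseline_sd_pA,
                             anomaly = FALSE) {
  check_flag(verdict, "verdict")
  check_number(trial_fraction, "trial_fraction", lower = 0, upper = 1)
  if (verdict && !all(criteria))
    stop("verdict TRUE requires all criteria to pass")
  structure(
    list(verdict = verdict,
         peak_pA = peak_pA,
         latency_ms = latency_ms,
         rise_10_90_ms = rise_10_90_ms,
         trial_fraction = trial_fraction,
         criteria = criteria,
         baseline_sd_pA = baseline_sd_pA,
         anomaly = anomaly),
    class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s\n",
              if (x$verdict) "CONNECTED" else "not connected"))
  cat(sprintf("  peak %.2f pA, latency %s ms, rise %s ms, trials %.0f%%\n",
              x$peak_pA,
              if (is.na(x$latency_ms)) "NA" else sprintf("%.2f", x$latency_ms),
              if (is.na(x$rise_10_90_ms)) "NA" else
                sprintf("%.2f", x$rise_10_90_ms),
              100 * x$trial_fraction))
  cat("  criteria:", paste(names(x$criteria),
                           ifelse(x$criteria, "pass", "FAIL"),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Current-voltage relationship of a connection
#'
#' @param holding_potentials_mV strictly increasing holding potentials (mV),
#'   length >= 2.
#' @param peak_currents_pA peak current at each potential (pA).
#'
#' @return An object of class `iv_result` with the interpolated zero-current
#'   crossing in `reversal_mV` (see [estimate_reversal()]).
#' @export
iv_result <- function(holding_potentials_mV, peak_currents_pA) {
  if (length(holding_potentials_mV) < 2L)
    stop("at least 2 holding potentials are required")
  if (length(holding_potentials_mV) != length(peak_currents_pA))
    stop("potentials and currents must have equal length")
  if (any(diff(holding_potentials_mV) <= 0))
    stop("'holding_potentials_mV' must be strictly increasing")
  rev <- estimate_reversal(holding_potentials_mV, peak_currents_pA)
  structure(
    list(holding_potentials_mV = holding_potentials_mV,
         peak_currents_pA = peak_currents_pA,
         reversal_mV = as.numeric(rev),
         extrapolated = isTRUE(attr(rev, "extrapolated"))),
    class = "iv_result")
}

# ---------------------------------------------------------------------------
# On-disk container. One JSON document per recording with top-level groups
# "traces", "protocol" and "meta" (plus "format"/"version" headers); numeric
# values are written at full precision so that write -> read round-trips
# bit-exactly. JSON keeps the container self-describing and text-based.

SWEEPSET_FORMAT <- "sacphys-sweepset"
SWEEPSET_VERSION <- 1L

#' Write a sweep set to a self-describing container file
#'
#' The container is a single JSON document with groups `traces` (trial x
#' sample matrix, pA), `protocol` (ms/mV fields) and `meta`. Values are
#' serialised at full precision: `read_sweepset(write_sweepset(x))` returns
#' bit-identical traces.
#'
#' @param sweeps a [sweep_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_sweepset()]
#' @export
write_sweepset <- function(sweeps, path) {
  if (!inherits(sweeps, "sweep_set")) stop("'sweeps' must be a sweep_set")
  doc <- list(
    format = SWEEPSET_FORMAT,
    version = SWEEPSET_VERSION,
    units = list(current = "pA", time = "ms", potential = "mV"),
    sampling_rate_Hz = sweeps$sampling_rate_Hz,
    n_trials = sweeps$n_trials,
    n_samples = ncol(sweeps$traces),
    protocol = unclass(sweeps$protocol),
    meta = sweeps$meta,
    traces = unname(apply(sweeps$traces, 1L, identity, simplify = FALSE))
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  tryCatch(writeLines(json, path),
           error = function(e) stop("cannot write sweep set to '", path,
                                    "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a sweep set container file
#'
#' Inverse of [write_sweepset()]. Missing required fields raise an error that
#' names the absent field; a legacy container without `artifact_blank_ms`
#' gets the documented default of 1 ms and is flagged in
#' `meta$artifact_blank_defaulted`.
#'
#' @param path path to a container written by [write_sweepset()].
#' @return A [sweep_set()].
#' @export
read_sweepset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE),
    error = function(e) stop("corrupt sweep-set container '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, SWEEPSET_FORMAT))
    stop("not a sweep-set container (missing or wrong 'format'): ", path,
         call. = FALSE)
  for (field in c("sampling_rate_Hz", "protocol", "traces"))
    if (is.null(doc[[field]]))
      stop("sweep-set container is missing required field '", field, "'",
           call. = FALSE)
  pr <- doc$protocol
  for (field in c("step_onset_ms", "step_duration_ms", "v_hold_pre_mV",
                  "v_step_mV", "v_hold_post_mV"))
    if (is.null(pr[[field]]))
      stop("sweep-set container is missing required field 'protocol$",
           field, "'", call. = FALSE)
  meta <- doc$meta %||% list()
  if (is.null(pr$artifact_blank_ms)) {
    pr$artifact_blank_ms <- 1.0
    meta$artifact_blank_defaulted <- TRUE
  }
  protocol <- stimulus_protocol(as.numeric(pr$step_onset_ms),
                                as.numeric(pr$step_duration_ms),
                                as.numeric(pr$v_hold_pre_mV),
                                as.numeric(pr$v_step_mV),
                                as.numeric(pr$v_hold_post_mV),
                                as.numeric(pr$artifact_blank_ms))
  traces <- do.call(rbind, doc$traces)
  if (!is.null(doc$n_samples) && ncol(traces) != doc$n_samples)
    stop("corrupt sweep-set container: trace length does not match ",
         "'n_samples'", call. = FALSE)
  sweep_set(traces, as.numeric(doc$sampling_rate_Hz), protocol, meta)
}

#' Export a homogeneous list of results to a delimited table
#'
#' Writes one row per result to a CSV file with a documented header. Numeric
#' formatting is fixed (full precision, `.` decimal mark) so re-exporting
#' identical input yields a byte-identical file.
#'
#' @param results list of [detection_result()] or `tuning_result` objects
#'   (one kind per call).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_results_table <- function(results, path) {
  if (!is.list(results)) stop("'results' must be a list of result objects")
  kinds <- unique(vapply(results, function(r) class(r)[1L], character(1)))
  if (length(kinds) > 1L)
    stop("mixed result kinds in 'results': ", paste(kinds, collapse = ", "))
  if (length(results) == 0L || kinds == "detection_result") {
    df <- data.frame(
      verdict = vapply(results, function(r) r$verdict, logical(1)),
      peak_pA = vapply(results, function(r) as.numeric(r$peak_pA), 1),
      latency_ms = vapply(results, function(r) as.numeric(r$latency_ms), 1),
      rise_10_90_ms = vapply(results,
                             function(r) as.numeric(r$rise_10_90_ms), 1),
      trial_fraction = vapply(results, function(r) r$trial_fraction, 1),
      baseline_sd_pA = vapply(results,
                              function(r) as.numeric(r$baseline_sd_pA), 1),
      anomaly = vapply(results, function(r) isTRUE(r$anomaly), logical(1)))
  } else if (kinds == "tuning_result") {
    df <- do.call(rbind, lapply(results, as.data.frame))
  } else {
    stop("unsupported result kind: ", kinds)
  }
  con <- file(path, open = "wb")  # fixed EOL so exports are byte-stable
  on.exit(close(con))
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
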