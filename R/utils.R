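# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so seeded generators are pure functions of their
#' arguments.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Argument checks with informative messages; all quantities in the package
# carry fixed units (pA, ms, mV, um) enforced at construction time.
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop(sprintf("'%s' is required", name), call. = FALSE)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop(sprintf("'%s' must be one of: %s", name,
                 paste(choices, collapse = ", ")), call. = FALSE)
  invisible(x)
}

# Circular difference of two angles in degrees, result in [0, 180].
circular_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Centered boxcar smoother used before per-trial excursion tests; at 20 kHz
# a 0.5 ms window suppresses single-sample noise without distorting
# millisecond-scale synaptic deflections. Edges (half-window) are NA.
boxcar_smooth <- function(x, width_samples) {
  if (width_samples <= 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / width_samples, width_samples),
                           sides = 2))
}
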