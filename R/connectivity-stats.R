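# Distance-binned connection probability with binomial errors, and the
# Monte-Carlo null for reciprocal connectivity. The unit of analysis is the
# directed test: a bidirectionally tested pair contributes two tests.

#' Directed connectivity table
#'
#' Validates a data frame of directed connection tests between cell pairs.
#'
#' @param df data frame with columns `pair_id`, `distance_um`, `genotype`,
#'   `age_group`, `tested_AB`, `connected_AB`, `tested_BA`, `connected_BA`,
#'   `peak_pA_AB`, `peak_pA_BA`.
#' @return The validated data frame with class `connectivity_table`.
#' @export
connectivity_table <- function(df) {
  req <- c("pair_id", "distance_um", "genotype", "age_group",
           "tested_AB", "connected_AB", "tested_BA", "connected_BA",
           "peak_pA_AB", "peak_pA_BA")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("connectivity table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(df$distance_um < 0)) stop("distances must be >= 0")
  if (any(df$connected_AB & !df$tested_AB) ||
      any(df$connected_BA & !df$tested_BA))
    stop("a connection cannot be recorded for an untested direction")
  class(df) <- c("connectivity_table", class(df))
  df
}

# Long format: one row per directed test.
directed_tests <- function(table) {
  ab <- table[table$tested_AB, c("pair_id", "distance_um", "genotype",
                                 "age_group", "connected_AB", "peak_pA_AB")]
  ba <- table[table$tested_BA, c("pair_id", "distance_um", "genotype",
                                 "age_group", "connected_BA", "peak_pA_BA")]
  names(ab)[5:6] <- names(ba)[5:6] <- c("connected", "peak_pA")
  rbind(ab, ba)
}

#' Connection probability by distance bin
#'
#' Per-bin estimate over directed tests, `p_hat = connected / tested`, with
#' the binomial standard error `sqrt(p_hat * (1 - p_hat) / n)`. Bins are
#' closed on the left and open on the right except the last, so 100 um
#' falls in the far bin.
#'
#' @param table a [connectivity_table()].
#' @param bin_edges_um bin edges in um; default `c(35, 100, 175)` giving a
#'   near (35-100 um) and a far (100-175 um) bin.
#' @return Data frame with `bin`, `n_tested`, `n_connected`, `p_hat`, `se`
#'   (all `NA` for empty bins).
#' @export
#' @examples
#' tbl <- simulate_population_connectivity(n_pairs = 200, seed = 1)
#' connection_probability_by_distance(tbl)
connection_probability_by_distance <- function(table,
                                               bin_edges_um = c(35, 100,
                                                                175)) {
  stopifnot(inherits(table, "connectivity_table"))
  if (length(bin_edges_um) < 2L || any(diff(bin_edges_um) <= 0))
    stop("'bin_edges_um' must be strictly increasing with >= 2 edges")
  tests <- directed_tests(table)
  bins <- cut(tests$distance_um, bin_edges_um, right = FALSE,
              include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bins), function(b) {
    sel <- !is.na(bins) & bins == b
    n <- sum(sel)
    if (n == 0)
      return(data.frame(bin = b, n_tested = 0L, n_connected = NA_integer_,
                        p_hat = NA_real_, se = NA_real_))
    k <- sum(tests$connected[sel])
    p <- k / n
    data.frame(bin = b, n_tested = n, n_connected = k, p_hat = p,
               se = sqrt(p * (1 - p) / n))
  }))
  rownames(out) <- NULL
  out
}

#' Expected reciprocity counts under independence
#'
#' With two independent directed Bernoulli(p) connections per pair, the
#' expected counts over `n_pairs` pairs are
#' `(n p^2, 2 n p (1 - p), n (1 - p)^2)` for bidirectional, unidirectional
#' and unconnected pairs.
#'
#' @param p directed connection probability in [0, 1].
#' @param n_pairs number of bidirectionally tested pairs.
#' @return Named numeric vector `c(bidirectional, unidirectional,
#'   unconnected)`.
#' @export
analytic_reciprocity <- function(p, n_pairs) {
  check_number(p, "p", lower = 0, upper = 1)
  check_number(n_pairs, "n_pairs", lower = 0)
  c(bidirectional = n_pairs * p^2,
    unidirectional = n_pairs * 2 * p * (1 - p),
    unconnected = n_pairs * (1 - p)^2)
}

#' Monte-Carlo null for reciprocal connectivity
#'
#' Pools a directed connection probability `p_hat` over all directed tests,
#' then simulates `n_sim` datasets in which the two directed connections of
#' every bidirectionally tested pair are independent Bernoulli(`p_hat`)
#' draws. Returns the null histograms of the (bidirectional, unidirectional,
#' unconnected) counts and two-sided percentile p-values for the observed
#' counts with add-one smoothing, `p = 2 * min(Pr(X <= obs), Pr(X >= obs))`
#' computed as `(r + 1) / (n_sim + 1)`.
#'
#' @param table a [connectivity_table()].
#' @param n_sim number of simulations (default 1e5).
#' @param seed RNG seed.
#' @param stratify_by_genotype if `TRUE`, `p_hat` is estimated and simulated
#'   within genotype and the counts are summed across strata.
#' @return An object of class `reciprocity_null`.
#' @export
reciprocity_null <- function(table, n_sim = 1e5, seed = NULL,
                             stratify_by_genotype = FALSE) {
  stopifnot(inherits(table, "connectivity_table"))
  check_number(n_sim, "n_sim", lower = 1)
  bidir <- table$tested_AB & table$tested_BA
  if (!any(bidir)) stop("no bidirectionally tested pairs")

  strata <- if (stratify_by_genotype) split(seq_len(nrow(table)),
                                            table$genotype)
            else list(all = seq_len(nrow(table)))

  observed <- c(bidirectional = sum(bidir & table$connected_AB &
                                      table$connected_BA),
                unidirectional = sum(bidir & xor(table$connected_AB,
                                                 table$connected_BA)),
                unconnected = sum(bidir & !table$connected_AB &
                                    !table$connected_BA))

  tests <- directed_tests(table)
  p_hat <- mean(tests$connected)
  degenerate <- p_hat %in% c(0, 1)
  if (degenerate)
    warning("pooled connection probability is ", p_hat,
            "; the null distribution is degenerate")

  sims <- with_seed(seed, {
    total <- matrix(0L, nrow = 3L, ncol = n_sim)
    for (s in names(strata)) {
      idx <- strata[[s]]
      nb <- sum(bidir[idx])
      if (nb == 0) next
      ps <- if (stratify_by_genotype)
        mean(directed_tests(table[idx, , drop = FALSE])$connected)
      else p_hat
      # Two independent Bernoulli(ps) draws per pair classify each pair
      # into one of three categories; the per-simulation counts are a
      # multinomial draw over (ps^2, 2ps(1-ps), (1-ps)^2).
      probs <- c(ps^2, 2 * ps * (1 - ps), (1 - ps)^2)
      total <- total + stats::rmultinom(n_sim, nb, probs)
    }
    total
  })
  rownames(sims) <- names(observed)

  p_values <- vapply(names(observed), function(k) {
    lo <- (sum(sims[k, ] <= observed[[k]]) + 1) / (n_sim + 1)
    hi <- (sum(sims[k, ] >= observed[[k]]) + 1) / (n_sim + 1)
    min(1, 2 * min(lo, hi))
  }, 1)

  structure(
    list(n_sim = n_sim,
         n_bidirectional_pairs = sum(bidir),
         p_hat = p_hat,
         counts_observed = observed,
         null_means = rowMeans(sims),
         null_histograms = apply(sims, 1L, tabulate,
                                 nbins = sum(bidir) + 1L, simplify = FALSE),
         null_draws = sims,
         p_values = p_values,
         degenerate = degenerate,
         stratified = stratify_by_genotype),
    class = "reciprocity_null")
}

#' @export
print.reciprocity_null <- function(x, ...) {
  cat(sprintf("<reciprocity_null> %d pairs, p_hat = %.3f, %d simulations\n",
              x$n_bidirectional_pairs, x$p_hat, x$n_sim))
  m <- rbind(observed = x$counts_observed, `null mean` = x$null_means,
             `p` = x$p_values)
  print(round(m, 3))
  invisible(x)
}

#' Mean peak amplitude of connected pairs by group
#'
#' @param table a [connectivity_table()].
#' @param bin_edges_um distance-bin edges, or `NULL` to skip distance
#'   grouping.
#' @return Data frame of group means and standard errors of the connected
#'   directed-test peak amplitudes (`se` is `NA` for singleton groups).
#' @export
amplitude_summary <- function(table, bin_edges_um = NULL) {
  stopifnot(inherits(table, "connectivity_table"))
  tests <- directed_tests(table)
  tests <- tests[tests$connected & !is.na(tests$peak_pA), , drop = FALSE]
  if (!nrow(tests)) stop("no connected pairs with amplitudes")
  key <- paste(tests$genotype, tests$age_group,
               if (!is.null(bin_edges_um))
                 cut(tests$distance_um, bin_edges_um, right = FALSE,
                     include.lowest = TRUE)
               else "all",
               sep = " / ")
  out <- do.call(rbind, lapply(split(tests$peak_pA, key), function(a) {
    data.frame(n = length(a), mean_pA = mean(a),
               se_pA = if (length(a) > 1) stats::sd(a) / sqrt(length(a))
                       else NA_real_)
  }))
  out <- cbind(group = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Relative connection strength of a manipulated group
#'
#' Combined relative strength = relative connection frequency x relative
#' current amplitude, each expressed as a fraction of the control group.
#' With the frequency (~0.2) and amplitude (~0.4) ratios observed when all
#' starburst cells express a single gamma-protocadherin isoform, the
#' product is 0.08: connection strength below 10% of controls.
#'
#' @param frequency_ratio connection frequency relative to control.
#' @param amplitude_ratio mean current amplitude relative to control.
#' @return The product, as a fraction of control strength.
#' @export
#' @examples
#' relative_connection_strength(0.2, 0.4)  # 0.08
relative_connection_strength <- function(frequency_ratio, amplitude_ratio) {
  check_number(frequency_ratio, "frequency_ratio", lower = 0)
  check_number(amplitude_ratio, "amplitude_ratio", lower = 0)
  frequency_ratio * amplitude_ratio
}
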