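# End-to-end orchestration: generate synthetic cohorts per genotype and age
# group, run the detectors and statistics, and write a consolidated report
# bundle. The bundle is a pure function of (config, seed, package version).

#' Validate a pipeline configuration
#'
#' @param config named list (typically parsed from YAML). Recognised fields:
#'   `seed` (integer), `cohorts` (list of lists with `genotype`,
#'   `age_group`, `n_pairs`), `n_detect_pairs`, `n_autapse_cells`,
#'   `n_tuning_cells`, `n_sim_reciprocity`, `mosaic` (list with `density_per_mm2`,
#'   `exclusion_radius_um`), `p_connect` (optional probability table rows).
#' @return The config with defaults filled in; errors name the offending
#'   field path.
#' @export
validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list")
  config$seed <- config$seed %||% 1L
  check_number(config$seed, "seed")
  config$n_detect_pairs <- config$n_detect_pairs %||% 20L
  config$n_autapse_cells <- config$n_autapse_cells %||% 20L
  config$n_tuning_cells <- config$n_tuning_cells %||% 10L
  config$n_sim_reciprocity <- config$n_sim_reciprocity %||% 1e4
  config$mosaic <- config$mosaic %||% list(density_per_mm2 = 300,
                                           exclusion_radius_um = 30)
  if (is.null(config$cohorts))
    config$cohorts <- list(
      list(genotype = "Pcdhg22", age_group = "juvenile", n_pairs = 50),
      list(genotype = "Pcdhg0", age_group = "juvenile", n_pairs = 50),
      list(genotype = "Pcdhg1", age_group = "juvenile", n_pairs = 50))
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    path <- sprintf("cohorts[[%d]]", i)
    check_choice(co$genotype %||% stop(path, "$genotype is required"),
                 paste0(path, "$genotype"), GENOTYPES)
    check_choice(co$age_group %||% stop(path, "$age_group is required"),
                 paste0(path, "$age_group"), AGE_GROUPS)
    check_number(co$n_pairs %||% stop(path, "$n_pairs is required"),
                 paste0(path, "$n_pairs"), lower = 1)
  }
  if (!is.null(config$p_connect)) {
    pc <- as.data.frame(do.call(rbind, lapply(config$p_connect, as.data.frame)))
    for (j in seq_len(nrow(pc)))
      check_number(pc$p[j], sprintf("p_connect[[%d]]$p", j),
                   lower = 0, upper = 1)
    config$p_connect_df <- pc
  }
  config
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Stages: (1) simulate per-cohort connectivity tables and summarise
#' connection probability by distance and amplitude; (2) simulate paired
#' recordings and run the connection detector; (3) simulate autapse
#' recordings per genotype and classify; (4) simulate tuned spike trains
#' and compute direction-selectivity summaries; (5) reciprocity null on the
#' pooled control table; (6) mosaic and density recovery profile. Each
#' stage is isolated: a failure is recorded in the log and later stages
#' still run.
#'
#' @param config a YAML file path or a config list (see
#'   [validate_pipeline_config()]).
#' @param out_dir output directory for the report bundle.
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.jsonl")
  unlink(log_path)
  log_line <- function(stage, status, detail = NULL) {
    rec <- list(stage = stage, status = status, detail = detail,
                package_version = as.character(utils::packageVersion("sacphys")),
                seed = config$seed)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch({
      out <- force(expr)
      log_line(stage, "ok")
      out
    }, error = function(e) {
      log_line(stage, "error", conditionMessage(e))
      NULL
    })
  }
  summary <- list(seed = config$seed, cohorts = list())
  model <- if (!is.null(config$p_connect_df))
    population_model(p_connect = config$p_connect_df)
  else population_model()

  # stage 1: connectivity cohorts
  tables <- list()
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    key <- paste(co$genotype, co$age_group, sep = "_")
    tables[[key]] <- run_stage(paste0("connectivity_", key), {
      tbl <- simulate_population_connectivity(
        model, co$n_pairs, genotype = co$genotype, age_group = co$age_group,
        seed = config$seed + i)
      utils::write.csv(as.data.frame(tbl),
                       file.path(out_dir, paste0("connectivity_", key,
                                                 ".csv")),
                       row.names = FALSE)
      pb <- connection_probability_by_distance(tbl)
      summary$cohorts[[key]] <- list(
        genotype = co$genotype, age_group = co$age_group,
        n_pairs = co$n_pairs,
        p_by_bin = pb,
        amplitudes = tryCatch(amplitude_summary(tbl), error = function(e)
          NULL))
      tbl
    })
  }

  # stage 2: connection detection benchmark sample
  summary$detection <- run_stage("detection", {
    n <- config$n_detect_pairs
    recs <- lapply(seq_len(n), function(i)
      simulate_paired_recording(i <= n / 2, seed = config$seed * 1000 + i))
    res <- lapply(recs, detect_connection)
    export_results_table(res, file.path(out_dir, "detection.csv"))
    truth <- vapply(recs, function(r) r$sweeps$meta$truth$connected,
                    logical(1))
    verdict <- vapply(res, function(r) r$verdict, logical(1))
    list(n = n, sensitivity = mean(verdict[truth]),
         false_positive_rate = mean(verdict[!truth]))
  })

  # stage 3: autapse classification per genotype
  summary$autapses <- run_stage("autapses", {
    cells <- list()
    k <- 0
    for (g in GENOTYPES) {
      p_aut <- population_model()$autapse_prob[[g]]
      for (i in seq_len(config$n_autapse_cells)) {
        k <- k + 1
        planted <- with_seed(config$seed * 2000 + k,
                             stats::runif(1) < p_aut)
        cells[[k]] <- simulate_autapse_recording(
          planted, genotype = g, seed = config$seed * 2000 + k)
      }
    }
    freq <- classify_population(cells)
    utils::write.csv(freq, file.path(out_dir, "autapse_frequency.csv"),
                     row.names = FALSE)
    freq
  })

  # stage 4: direction tuning cohort
  summary$tuning <- run_stage("tuning", {
    res <- lapply(seq_len(config$n_tuning_cells), function(i) {
      sts <- simulate_direction_response(n_reps = 6,
                                         seed = config$seed * 3000 + i)
      analyze_tuning(sts)
    })
    export_results_table(res, file.path(out_dir, "tuning.csv"))
    list(n = length(res),
         mean_dsi = mean(vapply(res, function(r) r$dsi_magnitude, 1)),
         mean_deviation_deg = mean(vapply(res, function(r)
           r$deviation_from_ventral_deg, 1)))
  })

  # stage 5: reciprocity null on the pooled juvenile control cohort
  summary$reciprocity <- run_stage("reciprocity", {
    key <- names(tables)[!vapply(tables, is.null, logical(1))][1]
    rn <- reciprocity_null(tables[[key]], n_sim = config$n_sim_reciprocity,
                           seed = config$seed + 99)
    out <- list(table = key, p_hat = rn$p_hat,
                counts_observed = as.list(rn$counts_observed),
                null_means = as.list(rn$null_means),
                p_values = as.list(rn$p_values))
    jsonlite::write_json(out, file.path(out_dir, "reciprocity.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  # stage 6: mosaic geometry
  summary$mosaic <- run_stage("mosaic", {
    mos <- simulate_mosaic(config$mosaic$density_per_mm2,
                           config$mosaic$exclusion_radius_um,
                           seed = config$seed + 7)
    drp <- density_recovery_profile(mos)
    out <- list(density_per_mm2 = mos$density_per_mm2,
                effective_radius_um = drp$effective_radius_um,
                densities_per_mm2 = drp$densities_per_mm2,
                annulus_edges_um = drp$annulus_edges_um)
    jsonlite::write_json(out, file.path(out_dir, "drp.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows", null = "null")
  invisible(summary)
}

#' Compare a metric between two groups with a stock two-sample test
#'
#' Descriptive comparison using `t.test` (Welch); not a re-derivation of any
#' test statistic.
#'
#' @param values_a,values_b numeric metric values for the two groups, each
#'   of length >= 2.
#' @param label_a,label_b group labels for the output.
#' @return List with group means, difference (a - b), and the t-test
#'   p-value.
#' @export
compare_groups <- function(values_a, values_b, label_a = "A", label_b = "B") {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(values_a, values_b)
  list(groups = c(label_a, label_b),
       mean_a = mean(values_a), mean_b = mean(values_b),
       difference = mean(values_a) - mean(values_b),
       p_value = tt$p.value,
       note = "descriptive Welch two-sample t-test")
}
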