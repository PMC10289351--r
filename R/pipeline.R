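#' Default run configuration
#'
#' A full analysis run is determined by this nested list: `cohort`
#' (subjects, task shape, generative parameters, `delta_w`, seed), `fitting`
#' (prior hyperparameters, restarts, seed) and `analysis` (valence threshold
#' for the stay split, regression method).
#'
#' @return A named list of defaults (class `run_config`).
#' @export
default_run_config <- function() {
  structure(list(
    cohort = list(
      n_subjects = 36L, delta_w = 0, order_counterbalance = TRUE, seed = 1L,
      task = list(trials_per_condition = 126L, blocks = 3L, miss_rate = 0,
                  walk_sigma = 0.2)
    ),
    fitting = list(beta_shape = 4.82, beta_scale = 0.88, stick_mean = 0.15,
                   stick_sd = 1.42, n_restarts = 10L, seed = 1L),
    analysis = list(valence_threshold = 1, regression_method = "two_stage")
  ), class = "run_config")
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop_invalid("unknown configuration key: `", full, "`")
    }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]])) {
        stop_invalid("configuration key `", full, "` must be a mapping")
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

check_config <- function(config) {
  co <- config$cohort
  if (!is.numeric(co$n_subjects) || co$n_subjects < 2) {
    stop_invalid("configuration key `cohort.n_subjects` must be >= 2")
  }
  if (!is.numeric(config$fitting$n_restarts) ||
      config$fitting$n_restarts < 1) {
    stop_invalid("configuration key `fitting.n_restarts` must be >= 1")
  }
  if (!config$analysis$regression_method %in% c("two_stage", "joint")) {
    stop_invalid("configuration key `analysis.regression_method` must be ",
                 "\"two_stage\" or \"joint\"")
  }
  config
}

#' Validate a run-configuration file
#'
#' Reads a YAML (or JSON) file, fills defaults from
#' [default_run_config()], and rejects unknown keys by name.
#'
#' @param path Path to the configuration file.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- yaml::read_yaml(path)
  config <- merge_config(default_run_config(), user %||% list())
  check_config(config)
}

as_cohort_config <- function(config) {
  task <- do.call(task_config, config$cohort$task)
  cohort_config(
    n_subjects = config$cohort$n_subjects, task = task,
    delta_w = config$cohort$delta_w,
    order_counterbalance = config$cohort$order_counterbalance,
    seed = config$cohort$seed
  )
}

as_prior_spec <- function(config) {
  f <- config$fitting
  prior_spec(beta_shape = f$beta_shape, beta_scale = f$beta_scale,
             stick_mean = f$stick_mean, stick_sd = f$stick_sd)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' simulate -> exclude -> fit -> analyse -> report. Writes trial logs, the
#' exclusion report, per-session MAP fits, stay statistics and ANOVA, the
#' stay regression with MB/MF indices, paired self-vs-other tests on
#' accuracy, relative performance, the fitted `w` and both indices,
#' correlation tables, and a manifest. Byte-identical outputs under an
#' identical configuration.
#'
#' @param config A `run_config` list ([default_run_config()] /
#'   [validate_config()]).
#' @param output_dir Directory for the report bundle (created if needed).
#' @param stages Which stages to run; earlier stage outputs must already be
#'   in `output_dir` when a stage is re-run in isolation.
#' @return Invisibly, a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(config = default_run_config(), output_dir,
                         stages = c("simulate", "fit", "analyse")) {
  config <- check_config(merge_config(default_run_config(), config))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = config)

  trials_path <- file.path(output_dir, "trials.csv")
  truth_path <- file.path(output_dir, "ground_truth.json")
  fits_path <- file.path(output_dir, "fits.csv")

  if ("simulate" %in% stages) {
    cohort <- generate_cohort(as_cohort_config(config))
    cohort <- apply_exclusions(cohort)
    write_trial_log(cohort$trials, trials_path)
    write_json_report(cohort$truth, truth_path)
    write_json_report(cohort$exclusions,
                      file.path(output_dir, "exclusions.json"))
    res$cohort <- cohort
  } else {
    if (!file.exists(trials_path)) {
      stop_invalid("stage `simulate` outputs missing from ", output_dir)
    }
    cohort <- list(trials = read_trial_log(trials_path))
    if (file.exists(truth_path)) {
      cohort$truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    }
    res$cohort <- cohort
  }

  if ("fit" %in% stages) {
    fits <- fit_cohort(cohort, priors = as_prior_spec(config),
                       n_restarts = config$fitting$n_restarts,
                       seed = config$fitting$seed)
    write.csv(fits, fits_path, row.names = FALSE, quote = FALSE)
    res$fits <- fits
  } else if ("analyse" %in% stages) {
    if (!file.exists(fits_path)) {
      stop_invalid("stage `fit` outputs missing from ", output_dir)
    }
    res$fits <- read.csv(fits_path, stringsAsFactors = FALSE)
  }

  if ("analyse" %in% stages) {
    res <- c(res, analyse_stage(cohort$trials, res$fits, config, output_dir))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("twostepr")),
    stages = stages, config = unclass(config)
  )
  cfg_file <- file.path(output_dir, "config.json")
  write_json_report(unclass(config), cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  write_json_report(manifest, file.path(output_dir, "manifest.json"))
  invisible(res)
}

analyse_stage <- function(trials, fits, config, output_dir) {
  out <- list()

  stays <- stay_table(trials,
                      valence_threshold = config$analysis$valence_threshold)
  write.csv(stays$per_subject, file.path(output_dir, "stay_stats.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(stays$group, file.path(output_dir, "stay_group.csv"),
            row.names = FALSE, quote = FALSE)
  out$stay <- stays

  anova <- rm_anova_2x2x2(stays)
  write_json_report(anova, file.path(output_dir, "anova.json"))
  out$anova <- anova

  metrics <- metric_table(trials)
  write.csv(metrics, file.path(output_dir, "metrics.csv"),
            row.names = FALSE, quote = FALSE)
  out$metrics <- metrics

  # per-condition stay regression and MB/MF indices
  design <- build_design(trials)
  fixed <- list()
  indices <- list()
  for (cond in sort(unique(design$condition))) {
    fit <- fit_multilevel_logistic(design[design$condition == cond, ],
                                   method = config$analysis$regression_method)
    fx <- fit$fixed
    fx$condition <- cond
    fixed[[cond]] <- fx
    ix <- mb_mf_indices(fit)
    ix$condition <- cond
    indices[[cond]] <- ix
  }
  fixed <- do.call(rbind, fixed)
  indices <- do.call(rbind, indices)
  write.csv(fixed, file.path(output_dir, "regression_fixed.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(indices, file.path(output_dir, "indices.csv"),
            row.names = FALSE, quote = FALSE)
  out$regression_fixed <- fixed
  out$indices <- indices

  # paired self-vs-other comparisons on subjects present in both conditions
  wide <- function(df, col) {
    s <- df[df$condition == "self", c("subject_id", col)]
    o <- df[df$condition == "other", c("subject_id", col)]
    mg <- merge(s, o, by = "subject_id", suffixes = c("_self", "_other"))
    mg[order(mg$subject_id), ]
  }
  paired <- list()
  for (spec in list(list(metrics, "accuracy"),
                    list(metrics, "relative_performance"),
                    list(fits, "w"),
                    list(indices, "mb_index"),
                    list(indices, "mf_index"))) {
    mg <- wide(spec[[1]], spec[[2]])
    paired[[spec[[2]]]] <- paired_comparison(mg[[2]], mg[[3]])
  }
  write_json_report(paired, file.path(output_dir, "paired_tests.json"))
  out$paired_tests <- paired

  # correlations: fitted w vs corrected reward rate, indices vs accuracy
  corr <- list()
  for (cond in c("self", "other")) {
    fw <- fits[fits$condition == cond, c("subject_id", "w")]
    mt <- metrics[metrics$condition == cond, ]
    ix <- indices[indices$condition == cond, ]
    mg <- merge(fw, mt, by = "subject_id")
    mg <- merge(mg, ix, by = "subject_id")
    corr[[cond]] <- list(
      w_vs_corrected_reward_rate =
        pearson_corr(mg$w, mg$corrected_reward_rate),
      mb_index_vs_accuracy = pearson_corr(mg$mb_index, mg$accuracy),
      mf_index_vs_accuracy = pearson_corr(mg$mf_index, mg$accuracy),
      w_vs_mb_index = pearson_corr(mg$w, mg$mb_index)
    )
  }
  write_json_report(corr, file.path(output_dir, "correlations.json"))
  out$correlations <- corr
  out
}
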