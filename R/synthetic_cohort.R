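#' Default generative distributions for agent parameters
#'
#' Mirrors the fitting priors: `beta ~ Gamma(shape 4.82, scale 0.88)`,
#' `pi, rho ~ Normal(0.15, SD 1.42)`, and `alpha, lam, w ~ Uniform(0, 1)`.
#' Each entry is a list with a `dist` field (`"gamma"`, `"normal"`,
#' `"uniform"` or `"point"`) and its parameters; draws outside a parameter's
#' legal range are resampled.
#'
#' @return Named list of per-parameter distribution specs.
#' @export
default_param_spec <- function() {
  list(
    alpha = list(dist = "uniform", min = 0, max = 1),
    lam = list(dist = "uniform", min = 0, max = 1),
    beta = list(dist = "gamma", shape = 4.82, scale = 0.88),
    pi = list(dist = "normal", mean = 0.15, sd = 1.42),
    rho = list(dist = "normal", mean = 0.15, sd = 1.42),
    w = list(dist = "uniform", min = 0, max = 1)
  )
}

param_bounds <- list(
  alpha = c(0, 1), lam = c(0, 1), beta = c(0, Inf),
  pi = c(-Inf, Inf), rho = c(-Inf, Inf), w = c(0, 1)
)

draw_one <- function(spec) {
  switch(spec$dist,
    point = spec$value,
    uniform = runif(1, spec$min, spec$max),
    normal = rnorm(1, spec$mean, spec$sd),
    gamma = rgamma(1, shape = spec$shape, scale = spec$scale),
    stop_invalid("unknown distribution: ", spec$dist)
  )
}

#' Sample one set of agent parameters
#'
#' @param param_spec Per-parameter distribution specs as in
#'   [default_param_spec()].
#' @param seed Optional seed for a deterministic draw.
#' @return An [agent_params()] object.
#' @export
sample_agent_params <- function(param_spec = default_param_spec(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- lapply(names(param_bounds), function(nm) {
    spec <- param_spec[[nm]]
    if (is.null(spec)) stop_invalid("param_spec is missing `", nm, "`")
    b <- param_bounds[[nm]]
    for (i in 1:1000) {
      x <- draw_one(spec)
      if (x >= b[1] && x <= b[2]) return(x)
    }
    stop_invalid("could not draw `", nm, "` within its legal range ",
                 "(distribution mass outside bounds?)")
  })
  names(draws) <- names(param_bounds)
  do.call(agent_params, draws)
}

#' Cohort configuration
#'
#' Describes a synthetic study with the shape of the experiment: `n_subjects`
#' agents each playing two conditions (`self`, `other`) of
#' `task$trials_per_condition` trials, with fresh reward walks per condition
#' and counterbalanced condition order. `delta_w` shifts each subject's
#' model-based weight additively in the `other` condition (clipped to
#' `[0, 1]`); 0 is the no-difference null.
#'
#' @param n_subjects Number of subjects (even when counterbalancing).
#' @param task A [task_config()].
#' @param param_spec Generative parameter distributions
#'   ([default_param_spec()]).
#' @param delta_w Additive self-to-other shift in `w`.
#' @param order_counterbalance If `TRUE`, half the cohort plays `self` first.
#' @param seed Base seed; all randomness in the cohort derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 36L, task = task_config(),
                          param_spec = default_param_spec(), delta_w = 0,
                          order_counterbalance = TRUE, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop_invalid("`n_subjects` must be >= 2")
  if (order_counterbalance && n_subjects %% 2L != 0L) {
    stop_invalid("`n_subjects` must be even when `order_counterbalance` is on")
  }
  structure(
    list(n_subjects = n_subjects, task = task, param_spec = param_spec,
         delta_w = delta_w, order_counterbalance = order_counterbalance,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' For each subject one parameter draw is taken; the `other` condition uses
#' `w + delta_w` (clipped to `[0, 1]`) while all other parameters are shared
#' across conditions. Each condition gets fresh reward walks (the task rules
#' are identical across conditions; only surface features differ), and the
#' condition order is counterbalanced across the cohort. Bit-identical given
#' the config.
#'
#' @param config A [cohort_config()].
#' @param structure A [transition_structure()].
#' @return An object of class `twostep_cohort`: list with `trials` (stacked
#'   trial logs), `truth` (per-subject true parameters, condition-specific
#'   `w`, session seeds, order) and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            structure = transition_structure()) {
  n <- config$n_subjects
  logs <- vector("list", 2L * n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("subj%03d", i)
    params <- sample_agent_params(config$param_spec,
                                  seed = derive_seed(config$seed, i, 0))
    w_cond <- c(self = params$w, other = clip01(params$w + config$delta_w))
    self_first <- if (config$order_counterbalance) i %% 2L == 1L else TRUE
    order <- if (self_first) c("self", "other") else c("other", "self")
    seeds <- c(self = derive_seed(config$seed, i, 1),
               other = derive_seed(config$seed, i, 2))
    for (k in 1:2) {
      cond <- order[k]
      p <- params
      p$w <- unname(w_cond[cond])
      logs[[2L * (i - 1L) + k]] <- simulate_session(
        p, task = config$task, structure = structure, seed = seeds[cond],
        subject_id = sid, condition = cond
      )
    }
    truth[[i]] <- data.frame(
      subject_id = sid, alpha = params$alpha, lam = params$lam,
      beta = params$beta, pi = params$pi, rho = params$rho,
      w_self = w_cond["self"], w_other = w_cond["other"],
      first_condition = order[1], seed_self = seeds["self"],
      seed_other = seeds["other"], row.names = NULL,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(trials = do.call(rbind, logs), truth = do.call(rbind, truth),
         config = config),
    class = "twostep_cohort"
  )
}

#' Apply the study's exclusion criteria
#'
#' Removes subjects who missed more than 20% of trials in either condition,
#' or who chose one ship of a pair on 100% of that pair's non-missed trials
#' in a condition (same-option responders). Idempotent.
#'
#' @param cohort A `twostep_cohort` (or any list with `trials` and optionally
#'   `truth`).
#' @param miss_threshold Maximum tolerated miss fraction.
#' @return The filtered cohort; the exclusion report (a `data.frame` with
#'   `subject_id`, `condition`, `reason`) is attached as element
#'   `exclusions`.
#' @export
apply_exclusions <- function(cohort, miss_threshold = 0.2) {
  trials <- cohort$trials
  if (is.null(trials) || nrow(trials) == 0L) {
    stop_invalid("cohort has no trials")
  }
  report <- list()
  for (sid in unique(trials$subject_id)) {
    for (cond in unique(trials$condition[trials$subject_id == sid])) {
      s <- trials[trials$subject_id == sid & trials$condition == cond, ]
      miss <- mean(s$chosen_ship == "MISSED")
      if (miss > miss_threshold) {
        report[[length(report) + 1L]] <- data.frame(
          subject_id = sid, condition = cond,
          reason = sprintf("missed %.1f%% of trials", 100 * miss),
          stringsAsFactors = FALSE
        )
        next
      }
      ok <- s[s$chosen_ship != "MISSED", ]
      for (p in unique(ok$pair_shown)) {
        ch <- ok$chosen_ship[ok$pair_shown == p]
        if (length(ch) > 0L && length(unique(ch)) == 1L) {
          report[[length(report) + 1L]] <- data.frame(
            subject_id = sid, condition = cond,
            reason = sprintf("always chose %s for pair %s", ch[1], p),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  report <- if (length(report)) unique(do.call(rbind, report)) else
    data.frame(subject_id = character(0), condition = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  drop <- unique(report$subject_id)
  cohort$trials <- trials[!(trials$subject_id %in% drop), , drop = FALSE]
  if (!is.null(cohort$truth)) {
    cohort$truth <- cohort$truth[!(cohort$truth$subject_id %in% drop), ,
                                 drop = FALSE]
  }
  cohort$exclusions <- report
  cohort
}

#' Read / write trial logs
#'
#' Trial logs are exchanged as UTF-8 CSV with a header row and the exact
#' column set of [simulate_session()]; missing values are empty fields.
#'
#' @param trials A trial-log `data.frame`.
#' @param path File path.
#' @return `read_trial_log` returns the trial-log `data.frame`;
#'   `write_trial_log` returns `path` invisibly.
#' @export
write_trial_log <- function(trials, path) {
  stopifnot(identical(names(trials), trial_log_columns))
  write.csv(trials, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 fileEncoding = "UTF-8")
  if (!identical(names(df), trial_log_columns)) {
    stop_invalid("trial log must have columns: ",
                 paste(trial_log_columns, collapse = ", "))
  }
  df$chosen_ship[is.na(df$chosen_ship)] <- "MISSED"
  df$key[is.na(df$key)] <- "none"
  df
}
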