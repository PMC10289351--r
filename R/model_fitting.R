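#' Empirical prior specification for MAP fitting
#'
#' `beta ~ Gamma(shape, scale)`, `pi, rho ~ Normal(mean, SD)`, and flat
#' priors on `[0, 1]` for `alpha`, `lam` and `w` (contributing a constant 0
#' to the log posterior).
#'
#' @param beta_shape,beta_scale Gamma shape and scale for the inverse
#'   temperature (defaults 4.82, 0.88, read as shape-scale).
#' @param stick_mean,stick_sd Normal mean and SD shared by the two stickiness
#'   parameters (defaults 0.15, 1.42).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_shape = 4.82, beta_scale = 0.88,
                       stick_mean = 0.15, stick_sd = 1.42) {
  structure(list(beta_shape = beta_shape, beta_scale = beta_scale,
                 stick_mean = stick_mean, stick_sd = stick_sd),
            class = "prior_spec")
}

log_prior <- function(par, priors) {
  dgamma(par[3], shape = priors$beta_shape, scale = priors$beta_scale,
         log = TRUE) +
    dnorm(par[4], priors$stick_mean, priors$stick_sd, log = TRUE) +
    dnorm(par[5], priors$stick_mean, priors$stick_sd, log = TRUE)
}

in_support <- function(par) {
  all(is.finite(par)) &&
    par[1] >= 0 && par[1] <= 1 &&   # alpha
    par[2] >= 0 && par[2] <= 1 &&   # lam
    par[3] > 0 &&                   # beta
    par[6] >= 0 && par[6] <= 1      # w
}

# Encode a single-session trial log into the integer arrays the C++ replay
# consumes. Validates ordering and single-session preconditions.
encode_session <- function(trial_log, structure = transition_structure()) {
  if (nrow(trial_log) > 0L) {
    if (length(unique(trial_log$subject_id)) > 1L ||
        length(unique(trial_log$condition)) > 1L) {
      stop_invalid("trial log must hold a single subject-condition session")
    }
    if (is.unsorted(trial_log$trial_index, strictly = TRUE)) {
      stop_invalid("trial log must be in chronological order")
    }
  }
  ship_ids <- names(structure$destination)
  chosen <- match(trial_log$chosen_ship, ship_ids)
  chosen[trial_log$chosen_ship == "MISSED"] <- 0L
  if (any(is.na(chosen))) stop_invalid("unknown ship id in `chosen_ship`")
  key <- match(trial_log$key, c("left", "right"))
  key[is.na(key)] <- 0L
  reward <- (ifelse(is.na(trial_log$payoff), 0, trial_log$payoff) + 4) / 9
  list(
    block = as.integer(trial_log$block),
    left = match(trial_log$left_ship, ship_ids),
    right = match(trial_log$right_ship, ship_ids),
    chosen = as.integer(chosen),
    key = as.integer(key),
    reward = as.numeric(reward),
    dest = as.integer(factor(structure$destination, levels = c("P_A", "P_B")))
  )
}

#' Log likelihood of one session under the hybrid model
#'
#' Replays the learner's recursion over the session's observed choices and
#' payoffs (normalised onto `[0, 1]`), summing the log softmax probability of
#' each chosen ship. Missed trials contribute nothing and trigger no update;
#' stickiness referents reset at block starts.
#'
#' @param params An [agent_params()] or named list with the six parameters.
#' @param trial_log A single-session trial log, chronologically ordered.
#' @param structure A [transition_structure()].
#' @return The session log likelihood (scalar).
#' @export
session_log_likelihood <- function(params, trial_log,
                                   structure = transition_structure()) {
  par <- params_vector(params)
  enc <- encode_session(trial_log, structure)
  cpp_session_loglik(par, enc$block, enc$left, enc$right, enc$chosen,
                     enc$key, enc$reward, enc$dest)
}

#' Negative log posterior for MAP estimation
#'
#' `-log L - log p(beta) - log p(pi) - log p(rho)`; the flat `[0, 1]` priors
#' on `alpha`, `lam`, `w` contribute 0. Parameters outside their support
#' return `+Inf` (a penalty, not an error), so optimisers may probe bounds.
#'
#' @inheritParams session_log_likelihood
#' @param priors A [prior_spec()].
#' @return Scalar negative log posterior (`+Inf` outside the support).
#' @export
negative_log_posterior <- function(params, trial_log, priors = prior_spec(),
                                   structure = transition_structure()) {
  par <- if (inherits(params, "agent_params") || is.list(params)) {
    p <- unlist(unclass(params)[c("alpha", "lam", "beta", "pi", "rho", "w")])
    unname(p)
  } else as.numeric(params)
  if (length(par) != 6L || any(is.na(par))) {
    stop_invalid("params must supply alpha, lam, beta, pi, rho, w")
  }
  if (!in_support(par)) return(Inf)
  enc <- encode_session(trial_log, structure)
  nlp_encoded(par, enc, priors)
}

nlp_encoded <- function(par, enc, priors) {
  if (!in_support(par)) return(Inf)
  ll <- cpp_session_loglik(par, enc$block, enc$left, enc$right, enc$chosen,
                           enc$key, enc$reward, enc$dest)
  -ll - log_prior(par, priors)
}

map_lower <- c(0, 0, 1e-4, -20, -20, 0)
map_upper <- c(1, 1, 50, 20, 20, 1)

map_starts <- function(n_restarts, priors) {
  starts <- matrix(NA_real_, n_restarts, 6)
  starts[1, ] <- c(0.5, 0.5, priors$beta_shape * priors$beta_scale,
                   priors$stick_mean, priors$stick_mean, 0.5)
  if (n_restarts > 1L) {
    for (i in 2:n_restarts) {
      starts[i, ] <- c(
        runif(1), runif(1),
        min(max(rgamma(1, shape = priors$beta_shape,
                       scale = priors$beta_scale), 0.1), 20),
        min(max(rnorm(1, priors$stick_mean, priors$stick_sd), -5), 5),
        min(max(rnorm(1, priors$stick_mean, priors$stick_sd), -5), 5),
        runif(1)
      )
    }
  }
  starts
}

#' MAP fit of the hybrid model to one session
#'
#' Bounded multi-start local optimisation (L-BFGS-B) of
#' [negative_log_posterior()]. The first start sits at the prior means; the
#' remaining starts are drawn from the priors (flat parameters uniformly).
#' Deterministic given `seed`.
#'
#' @inheritParams negative_log_posterior
#' @param n_restarts Number of optimisation restarts.
#' @param seed Optional seed controlling the restart draws.
#' @return An object of class `map_fit`: `params_hat` ([agent_params()]),
#'   `log_posterior`, `n_restarts`, `best_restart`, `converged` and `trace`
#'   (final log posterior per restart).
#' @export
fit_map <- function(trial_log, priors = prior_spec(),
                    structure = transition_structure(), n_restarts = 10L,
                    seed = NULL) {
  enc <- encode_session(trial_log, structure)
  if (sum(enc$chosen > 0L) < 1L) {
    stop_invalid("session has no non-missed trials to fit")
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- map_starts(n_restarts, priors)
  # L-BFGS-B's finite-difference probes can step just outside the box;
  # evaluate at the clamped point so gradients at the bounds stay meaningful
  obj <- function(par) {
    par <- pmin(map_upper, pmax(map_lower, par))
    v <- nlp_encoded(par, enc, priors)
    if (!is.finite(v)) 1e10 else v
  }
  fits <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    fits[[i]] <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = map_lower,
            upper = map_upper, control = list(maxit = 200L)),
      error = function(e) list(par = starts[i, ], value = Inf,
                               convergence = 99L)
    )
  }
  values <- vapply(fits, function(f) f$value, numeric(1))
  best <- which.min(values)
  # L-BFGS-B may return a solution a few ulps outside the box
  par <- pmin(map_upper, pmax(map_lower, fits[[best]]$par))
  structure(
    list(
      params_hat = agent_params(par[1], par[2], par[3], par[4], par[5],
                                par[6]),
      log_posterior = -values[best],
      n_restarts = n_restarts,
      best_restart = best,
      converged = identical(fits[[best]]$convergence, 0L),
      trace = -values
    ),
    class = "map_fit"
  )
}

#' Fit every subject-condition session of a cohort
#'
#' Sessions are fitted separately and independently per subject and
#' condition, mirroring per-condition parameter comparisons.
#'
#' @param cohort A `twostep_cohort` (or list with a `trials` element).
#' @inheritParams fit_map
#' @return A `data.frame` with one row per subject x condition: the six MAP
#'   estimates, `log_posterior` and `converged`.
#' @export
fit_cohort <- function(cohort, priors = prior_spec(),
                       structure = transition_structure(), n_restarts = 10L,
                       seed = 1L) {
  trials <- cohort$trials
  keys <- unique(trials[, c("subject_id", "condition")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- trials[trials$subject_id == keys$subject_id[i] &
                  trials$condition == keys$condition[i], ]
    fit <- fit_map(s, priors = priors, structure = structure,
                   n_restarts = n_restarts,
                   seed = derive_seed(seed, i))
    p <- fit$params_hat
    rows[[i]] <- data.frame(
      subject_id = keys$subject_id[i], condition = keys$condition[i],
      alpha = p$alpha, lam = p$lam, beta = p$beta, pi = p$pi, rho = p$rho,
      w = p$w, log_posterior = fit$log_posterior, converged = fit$converged,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
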