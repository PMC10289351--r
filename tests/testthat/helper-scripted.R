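# Build small scripted trial logs by hand for exact-value tests.
# `chosen` may contain "MISSED"; `pair` defaults to the chosen ship's pair
# (and must be given explicitly for missed trials).

scripted_log <- function(chosen, payoff, pair = NULL, block = NULL,
                         subject_id = "s1", condition = "self",
                         latent_chosen = NULL, latent_unchosen = NULL) {
  n <- length(chosen)
  ship_pair <- c(S1 = "a", S2 = "a", S3 = "b", S4 = "b")
  if (is.null(pair)) {
    if (any(chosen == "MISSED")) {
      stop("`pair` must be given when the log contains missed trials")
    }
    pair <- unname(ship_pair[chosen])
  }
  if (is.null(block)) block <- rep(1L, n)
  left <- ifelse(pair == "a", "S1", "S3")
  right <- ifelse(pair == "a", "S2", "S4")
  missed <- chosen == "MISSED"
  key <- ifelse(missed, "none", ifelse(chosen == left, "left", "right"))
  dest <- c(S1 = "P_A", S2 = "P_B", S3 = "P_A", S4 = "P_B")
  planet <- ifelse(missed, NA_character_, dest[chosen])
  payoff[missed] <- NA
  if (is.null(latent_chosen)) {
    latent_chosen <- ifelse(missed, NA_real_, (payoff + 4) / 9)
  }
  if (is.null(latent_unchosen)) {
    latent_unchosen <- ifelse(missed, NA_real_, 0.5)
  }
  correct <- ifelse(latent_chosen > latent_unchosen, TRUE,
                    ifelse(latent_chosen < latent_unchosen, FALSE, NA))
  data.frame(
    subject_id = subject_id, condition = condition, block = as.integer(block),
    trial_index = seq_len(n), pair_shown = pair, left_ship = left,
    right_ship = right, chosen_ship = chosen, key = key,
    planet = unname(planet), payoff = as.integer(payoff),
    latent_chosen = latent_chosen, latent_unchosen = latent_unchosen,
    correct = correct, stringsAsFactors = FALSE
  )
}

# A short random session (possibly with misses) for oracle comparisons.
random_short_session <- function(seed, n_trials = 10L) {
  set.seed(seed)
  params <- agent_params(
    alpha = runif(1), lam = runif(1),
    beta = rgamma(1, shape = 4.82, scale = 0.88),
    pi = rnorm(1, 0.15, 1.42), rho = rnorm(1, 0.15, 1.42), w = runif(1)
  )
  task <- task_config(trials_per_condition = n_trials, blocks = 1L,
                      miss_rate = 0.15)
  list(params = params,
       log = simulate_session(params, task = task,
                              seed = derive_seed(seed, 7)))
}
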