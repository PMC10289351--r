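# Independent step-by-step replay of the hybrid learner, written directly
# from the model definition with naive (non-log-sum-exp) softmax and named
# string indexing. Deliberately shares no code with the package's likelihood
# path so the two implementations can check each other.

oracle_session_loglik <- function(par, trial_log) {
  alpha <- par[1]; lam <- par[2]; beta <- par[3]
  piv <- par[4]; rho <- par[5]; w <- par[6]
  dest <- c(S1 = "P_A", S2 = "P_B", S3 = "P_A", S4 = "P_B")
  q <- c(S1 = 0.5, S2 = 0.5, S3 = 0.5, S4 = 0.5)
  v2 <- c(P_A = 0.5, P_B = 0.5)
  prev_ship <- NA_character_
  prev_key <- NA_character_
  prev_block <- NULL
  ll <- 0
  for (t in seq_len(nrow(trial_log))) {
    row <- trial_log[t, ]
    if (!identical(prev_block, row$block)) {
      prev_ship <- NA_character_
      prev_key <- NA_character_
      prev_block <- row$block
    }
    if (row$chosen_ship == "MISSED") next
    ships <- c(row$left_ship, row$right_ship)
    keys <- c("left", "right")
    qnet <- w * v2[dest[ships]] + (1 - w) * q[ships]
    bonus <- piv * as.numeric(!is.na(prev_ship) & ships == prev_ship) +
      rho * as.numeric(!is.na(prev_key) & keys == prev_key)
    ex <- exp(beta * (qnet + bonus))
    p <- ex / sum(ex)
    ll <- ll + log(p[[which(ships == row$chosen_ship)]])
    r <- (row$payoff + 4) / 9
    pl <- dest[[row$chosen_ship]]
    q[row$chosen_ship] <- q[row$chosen_ship] +
      alpha * (v2[pl] - q[row$chosen_ship])
    d2 <- r - v2[[pl]]
    v2[pl] <- v2[pl] + alpha * d2
    q[row$chosen_ship] <- q[row$chosen_ship] + alpha * lam * d2
    prev_ship <- row$chosen_ship
    prev_key <- row$key
  }
  as.numeric(ll)
}

oracle_negative_log_posterior <- function(par, trial_log,
                                          priors = prior_spec()) {
  -oracle_session_loglik(par, trial_log) -
    dgamma(par[3], shape = priors$beta_shape, scale = priors$beta_scale,
           log = TRUE) -
    dnorm(par[4], priors$stick_mean, priors$stick_sd, log = TRUE) -
    dnorm(par[5], priors$stick_mean, priors$stick_sd, log = TRUE)
}
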