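#' Parameters of the hybrid model-based/model-free learner
#'
#' @param alpha Learning rate in `[0, 1]`, shared by both stages.
#' @param lam Eligibility-trace decay in `[0, 1]`: how much of the
#'   second-stage prediction error propagates back to the first-stage value.
#' @param beta Softmax inverse temperature, `>= 0`; 0 gives uniform choice.
#' @param pi Choice stickiness: bonus for repeating the identical ship chosen
#'   on the previous trial (negative values favour switching).
#' @param rho Response stickiness: bonus for repeating the previously pressed
#'   key side.
#' @param w Model-based weight in `[0, 1]`; `w = 1` is a pure model-based
#'   agent, `w = 0` pure model-free.
#' @return An object of class `agent_params` (named list).
#' @export
agent_params <- function(alpha, lam, beta, pi, rho, w) {
  assert_number(alpha, "alpha", 0, 1)
  assert_number(lam, "lam", 0, 1)
  assert_number(beta, "beta", 0)
  assert_number(pi, "pi")
  assert_number(rho, "rho")
  assert_number(w, "w", 0, 1)
  structure(list(alpha = alpha, lam = lam, beta = beta, pi = pi, rho = rho,
                 w = w),
            class = "agent_params")
}

params_vector <- function(params) {
  if (inherits(params, "agent_params")) params <- unclass(params)
  p <- unlist(params[c("alpha", "lam", "beta", "pi", "rho", "w")])
  if (length(p) != 6L || any(!is.finite(p))) {
    stop_invalid("params must supply finite alpha, lam, beta, pi, rho, w")
  }
  p
}

#' Initial agent state
#'
#' Model-free first-stage values (one per ship) and second-stage planet
#' values shared by the model-based and model-free systems, all initialised
#' to 0.5, the midpoint of the normalised reward scale.
#'
#' @param structure A [transition_structure()].
#' @return An object of class `agent_state` with `q_mf`, `v2`, `prev_ship`,
#'   `prev_key`.
#' @export
agent_state <- function(structure = transition_structure()) {
  ships <- names(structure$destination)
  planets <- unique(unname(structure$destination))
  structure(
    list(q_mf = setNames(rep(0.5, length(ships)), ships),
         v2 = setNames(rep(0.5, length(planets)), planets),
         prev_ship = NA_character_, prev_key = NA_character_),
    class = "agent_state"
  )
}

#' Normalise a displayed payoff onto the learning scale
#'
#' Learning operates on the `[0, 1]` scale of the latent walks; displayed
#' integers are mapped back as `(payoff + 4) / 9`.
#'
#' @param payoff Integer payoff(s) in `[-4, +5]`.
#' @return Normalised reward(s) in `[0, 1]`.
#' @export
normalize_payoff <- function(payoff) {
  if (any(!is.finite(payoff)) || any(payoff < -4 | payoff > 5)) {
    stop_invalid("payoff must lie in [-4, +5]")
  }
  (payoff + 4) / 9
}

#' Model-based action values
#'
#' With deterministic transitions, Bellman backup of the second-stage values
#' reduces to a lookup: `Q_MB(ship) = v2(destination(ship))`. Equivalent
#' ships therefore always share the same model-based value — the signature
#' that lets reward generalise across pairs.
#'
#' @param state An [agent_state()].
#' @param structure A [transition_structure()].
#' @return Named numeric vector of values, one per ship.
#' @export
mb_q_values <- function(state, structure = transition_structure()) {
  setNames(state$v2[structure$destination], names(structure$destination))
}

#' SARSA(lambda) model-free update
#'
#' After choosing `chosen_ship` and observing normalised `reward` at its
#' destination planet `p`: the first-stage value is first backed up towards
#' the current second-stage value, `q_mf(c) += alpha (v2(p) - q_mf(c))`; the
#' second-stage prediction error `d2 = reward - v2(p)` then updates
#' `v2(p) += alpha d2` and, scaled by the eligibility trace, the first stage
#' again: `q_mf(c) += alpha lam d2`. Only the chosen ship and visited planet
#' change — model-free values never generalise across pairs.
#'
#' @param state An [agent_state()].
#' @param chosen_ship Ship id chosen at the first stage.
#' @param reward Normalised reward in `[0, 1]`.
#' @param alpha,lam Learning rate and trace decay.
#' @param structure A [transition_structure()].
#' @return The updated `agent_state`.
#' @export
mf_update <- function(state, chosen_ship, reward, alpha, lam,
                      structure = transition_structure()) {
  assert_number(reward, "reward", 0, 1)
  p <- resolve_transition(chosen_ship, structure)
  q <- state$q_mf
  v2 <- state$v2
  q[chosen_ship] <- q[chosen_ship] + alpha * (v2[p] - q[chosen_ship])
  d2 <- reward - v2[p]
  v2[p] <- v2[p] + alpha * d2
  q[chosen_ship] <- q[chosen_ship] + alpha * lam * d2
  state$q_mf <- q
  state$v2 <- v2
  state
}

#' Net action values of the hybrid learner
#'
#' `Q_net(s) = w Q_MB(s) + (1 - w) q_mf(s)` for the two ships of the shown
#' pair.
#'
#' @param state An [agent_state()].
#' @param params An [agent_params()] (only `w` is used).
#' @param pair `"a"` or `"b"`.
#' @param structure A [transition_structure()].
#' @return Named numeric vector of two values.
#' @export
q_net <- function(state, params, pair, structure = transition_structure()) {
  ships <- structure$pairs[[pair]]
  if (is.null(ships)) stop_invalid("`pair` must be \"a\" or \"b\"")
  qmb <- mb_q_values(state, structure)[ships]
  w <- params$w
  w * qmb + (1 - w) * state$q_mf[ships]
}

#' Softmax choice probabilities with perseveration
#'
#' `P(a)` is proportional to
#' `exp(beta [Q_net(a) + pi rep(a) + rho resp(a)])`, normalised over the two
#' shown ships. `rep(a) = 1` only if `a` is the identical ship chosen on the
#' previous trial (never its equivalent in the other pair); `resp(a) = 1` if
#' `a`'s key side matches the previously pressed key.
#'
#' @param q_net_pair Numeric vector of two net values.
#' @param prev_ship Previous chosen ship id, or `NA` if none.
#' @param prev_key Previous key side (`"left"`/`"right"`), or `NA`.
#' @param ships Character vector of the two shown ship ids.
#' @param keys Character vector of the two key sides, aligned with `ships`.
#' @param params An [agent_params()].
#' @return Numeric vector of two probabilities summing to one.
#' @export
choice_probabilities <- function(q_net_pair, prev_ship, prev_key, ships, keys,
                                 params) {
  if (length(q_net_pair) != 2L || any(!is.finite(q_net_pair))) {
    stop_invalid("`q_net_pair` must be two finite values")
  }
  rep_a <- as.numeric(!is.na(prev_ship) & ships == prev_ship)
  resp_a <- as.numeric(!is.na(prev_key) & keys == prev_key)
  x <- params$beta * (q_net_pair + params$pi * rep_a + params$rho * resp_a)
  x <- x - max(x)
  p <- exp(x) / sum(exp(x))
  setNames(p, ships)
}

trial_log_columns <- c(
  "subject_id", "condition", "block", "trial_index", "pair_shown",
  "left_ship", "right_ship", "chosen_ship", "key", "planet", "payoff",
  "latent_chosen", "latent_unchosen", "correct"
)

#' Simulate one session of the two-step task
#'
#' Forward-runs the hybrid learner over a scheduled session: on each trial
#' the shown pair's net values are computed, a choice is drawn from
#' [choice_probabilities()] (or the trial is missed with probability
#' `task$miss_rate`), the deterministic transition is resolved, the payoff is
#' read off the latent walk through the display mapping, and the model-free
#' values are updated on the normalised reward. Missed trials trigger no
#' learning and leave the stickiness referents at the last non-missed trial;
#' referents reset at each block start. Deterministic given `seed`.
#'
#' @param params An [agent_params()].
#' @param task A [task_config()].
#' @param structure A [transition_structure()].
#' @param seed Seed making the whole session reproducible.
#' @param subject_id,condition Labels written into the log.
#' @param walks Optional [generate_reward_walks()] result; defaults to fresh
#'   walks drawn inside the session's RNG stream.
#' @return A trial-log `data.frame`, one row per trial, with columns
#'   `subject_id, condition, block, trial_index, pair_shown, left_ship,
#'   right_ship, chosen_ship, key, planet, payoff, latent_chosen,
#'   latent_unchosen, correct`. Missed trials carry `chosen_ship = "MISSED"`,
#'   `key = "none"` and `NA` outcome fields; `correct` is `NA` on latent-value
#'   ties.
#' @export
simulate_session <- function(params, task = task_config(),
                             structure = transition_structure(), seed = NULL,
                             subject_id = "sim", condition = "self",
                             walks = NULL) {
  par <- params_vector(params)
  n <- task$trials_per_condition
  if (!is.null(seed)) set.seed(seed)
  if (is.null(walks)) {
    walks <- generate_reward_walks(n, sigma = task$walk_sigma,
                                   init_range = task$walk_init_range)
  }
  if (length(walks$values$P_A) != n) {
    stop_invalid("walk length must equal `trials_per_condition`")
  }
  pair <- schedule_pairs(n, task$blocks)
  per_block <- if (task$blocks > 0L && n > 0L) n %/% task$blocks else 1L
  block <- if (n > 0L) rep(seq_len(task$blocks), each = per_block) else integer(0)
  flip <- runif(n) < 0.5
  missed <- if (task$miss_rate > 0) rbinom(n, 1L, task$miss_rate) else rep(0L, n)

  ships <- structure$pairs
  first <- ifelse(pair == "a", ships$a[1], ships$b[1])
  second <- ifelse(pair == "a", ships$a[2], ships$b[2])
  left <- ifelse(flip, second, first)
  right <- ifelse(flip, first, second)

  ship_ids <- names(structure$destination)
  dest_idx <- as.integer(factor(structure$destination, levels = c("P_A", "P_B")))
  sim <- cpp_simulate_choices(
    par, as.integer(block),
    match(left, ship_ids), match(right, ship_ids),
    as.integer(missed), walks$values$P_A, walks$values$P_B, dest_idx
  )

  chosen <- ifelse(sim$chosen == 0L, "MISSED", ship_ids[pmax(sim$chosen, 1L)])
  key <- c("none", "left", "right")[sim$key + 1L]
  planet <- ifelse(sim$chosen == 0L, NA_character_,
                   structure$destination[ship_ids[pmax(sim$chosen, 1L)]])
  vA <- walks$values$P_A
  vB <- walks$values$P_B
  latent_chosen <- ifelse(planet == "P_A", vA, vB)
  latent_unchosen <- ifelse(planet == "P_A", vB, vA)
  latent_chosen[is.na(planet)] <- NA_real_
  latent_unchosen[is.na(planet)] <- NA_real_
  correct <- ifelse(latent_chosen > latent_unchosen, TRUE,
                    ifelse(latent_chosen < latent_unchosen, FALSE, NA))

  data.frame(
    subject_id = subject_id, condition = condition, block = block,
    trial_index = seq_len(n), pair_shown = pair, left_ship = left,
    right_ship = right, chosen_ship = chosen, key = key,
    planet = unname(planet),
    payoff = ifelse(sim$chosen == 0L, NA_integer_, sim$payoff),
    latent_chosen = latent_chosen, latent_unchosen = latent_unchosen,
    correct = correct, stringsAsFactors = FALSE
  )
}
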