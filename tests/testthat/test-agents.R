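test_that("agent parameters are validated", {
  p <- agent_params(0.3, 0.6, 4, 0.15, -0.2, 0.5)
  expect_s3_class(p, "agent_params")
  expect_error(agent_params(-0.1, 0.5, 1, 0, 0, 0.5), "alpha")
  expect_error(agent_params(0.5, 1.5, 1, 0, 0, 0.5), "lam")
  expect_error(agent_params(0.5, 0.5, -1, 0, 0, 0.5), "beta")
  expect_error(agent_params(0.5, 0.5, 1, 0, 0, 2), "w")
})

test_that("payoff normalisation inverts the display anchors", {
  expect_identical(normalize_payoff(-4L), 0)
  expect_identical(normalize_payoff(5L), 1)
  expect_equal(normalize_payoff(1L), 5 / 9)
  expect_error(normalize_payoff(6), "payoff")
})

test_that("initial state is uniform at the scale midpoint", {
  st <- agent_state()
  expect_identical(unname(st$q_mf), rep(0.5, 4))
  expect_identical(unname(st$v2), rep(0.5, 2))
  expect_true(is.na(st$prev_ship) && is.na(st$prev_key))
})

test_that("model-based values are shared across equivalent ships", {
  st <- agent_state()
  st$v2 <- c(P_A = 0.9, P_B = 0.2)
  q <- mb_q_values(st)
  expect_identical(q[["S1"]], q[["S3"]])
  expect_identical(q[["S2"]], q[["S4"]])
  expect_identical(q[["S1"]], 0.9)
  expect_identical(q[["S2"]], 0.2)
})

test_that("the model-free update matches the hand-worked recursion", {
  st <- agent_state()
  st$q_mf <- c(S1 = 0.4, S2 = 0.5, S3 = 0.6, S4 = 0.5)
  st$v2 <- c(P_A = 0.7, P_B = 0.5)
  alpha <- 0.5; lam <- 0.8; r <- 1
  out <- mf_update(st, "S1", r, alpha, lam)
  # backup: 0.4 + 0.5 (0.7 - 0.4) = 0.55; d2 = 1 - 0.7 = 0.3
  # v2 <- 0.7 + 0.5 * 0.3 = 0.85; q <- 0.55 + 0.5 * 0.8 * 0.3 = 0.67
  expect_equal(out$v2[["P_A"]], 0.85)
  expect_equal(out$q_mf[["S1"]], 0.67)
  # locality: nothing else moves, in particular not the equivalent ship
  expect_identical(out$q_mf[["S3"]], 0.6)
  expect_identical(out$q_mf[["S2"]], 0.5)
  expect_identical(out$q_mf[["S4"]], 0.5)
  expect_identical(out$v2[["P_B"]], 0.5)
})

test_that("net values mix the two systems linearly", {
  st <- agent_state()
  st$q_mf <- c(S1 = 0.2, S2 = 0.8, S3 = 0.5, S4 = 0.5)
  st$v2 <- c(P_A = 1, P_B = 0)
  p <- agent_params(0.5, 0.5, 1, 0, 0, 0.25)
  q <- q_net(st, p, "a")
  expect_equal(q[["S1"]], 0.25 * 1 + 0.75 * 0.2)
  expect_equal(q[["S2"]], 0.25 * 0 + 0.75 * 0.8)
  expect_error(q_net(st, p, "c"), "pair")
})

test_that("choice probabilities respond to value and stickiness", {
  p <- agent_params(0.5, 0.5, 2, 0.4, 0.3, 0.5)
  ships <- c("S1", "S2"); keys <- c("left", "right")
  base <- choice_probabilities(c(0.6, 0.4), NA, NA, ships, keys, p)
  expect_equal(sum(base), 1)
  expect_true(base[["S1"]] > base[["S2"]])
  # identical previous ship gets the pi bonus ...
  rep1 <- choice_probabilities(c(0.6, 0.4), "S1", NA, ships, keys, p)
  expect_true(rep1[["S1"]] > base[["S1"]])
  # ... its cross-pair equivalent does not
  rep3 <- choice_probabilities(c(0.6, 0.4), "S3", NA, ships, keys, p)
  expect_equal(rep3, base)
  # previous key side gets the rho bonus
  resp <- choice_probabilities(c(0.6, 0.4), NA, "right", ships, keys, p)
  expect_true(resp[["S2"]] > base[["S2"]])
  expect_error(choice_probabilities(c(0.6, NA), NA, NA, ships, keys, p),
               "finite")
})

test_that("simulated sessions have the documented shape and determinism", {
  task <- task_config()
  p <- agent_params(0.5, 0.6, 5, 0.2, 0.1, 0.7)
  s1 <- simulate_session(p, task, seed = 42)
  s2 <- simulate_session(p, task, seed = 42)
  expect_identical(s1, s2)
  expect_identical(names(s1), trial_log_columns)
  expect_identical(nrow(s1), 126L)
  expect_identical(s1$block, rep(1:3, each = 42))
  expect_false(identical(s1, simulate_session(p, task, seed = 43)))
})

test_that("simulated outcomes are internally consistent", {
  p <- agent_params(0.5, 0.6, 5, 0.2, 0.1, 0.7)
  s <- simulate_session(p, seed = 9)
  ok <- s$chosen_ship != "MISSED"
  expect_true(all(ok))  # miss_rate 0 by default
  expect_identical(s$payoff, payoff_from_value(s$latent_chosen))
  expect_identical(unname(s$planet),
                   resolve_transition(s$chosen_ship))
  shown <- ifelse(s$key == "left", s$left_ship, s$right_ship)
  expect_identical(shown, s$chosen_ship)
  expect_true(all(s$correct[s$latent_chosen > s$latent_unchosen]))
  expect_false(any(s$correct[s$latent_chosen < s$latent_unchosen]))
  expect_true(all(is.na(s$correct[s$latent_chosen == s$latent_unchosen])))
})

test_that("missed trials carry the documented sentinel values", {
  task <- task_config(miss_rate = 0.5)
  p <- agent_params(0.5, 0.5, 3, 0, 0, 0.5)
  s <- simulate_session(p, task, seed = 12)
  miss <- s$chosen_ship == "MISSED"
  expect_true(any(miss) && any(!miss))
  expect_true(all(s$key[miss] == "none"))
  expect_true(all(is.na(s$payoff[miss])))
  expect_true(all(is.na(s$planet[miss])))
  expect_true(all(is.na(s$latent_chosen[miss])))
})

test_that("an alpha = 0 session's likelihood doubles when replayed twice", {
  # with no learning and referents reset at the block boundary, a session
  # appended to itself as a new block contributes exactly twice the log
  # likelihood
  p <- agent_params(0, 0.5, 3, 0.4, -0.2, 0.5)
  task <- task_config(trials_per_condition = 42L, blocks = 1L)
  s <- simulate_session(p, task, seed = 77)
  s2 <- s
  s2$block <- 2L
  s2$trial_index <- s2$trial_index + 42L
  doubled <- rbind(s, s2)
  expect_equal(session_log_likelihood(p, doubled),
               2 * session_log_likelihood(p, s))
})
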