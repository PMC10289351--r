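test_that("the design matrix encodes the documented predictors", {
  log <- scripted_log(
    chosen = c("S1", "S3", "S2"),
    payoff = c(3, -2, 1),
    latent_chosen = c(7 / 9, 2 / 9, 5 / 9),
    latent_unchosen = c(2 / 9, 6 / 9, 5 / 9))
  d <- build_design(log)
  expect_identical(nrow(d), 2L)
  # row 1: prev payoff 3, prev unchosen latent 2/9 -> displayed -2
  expect_identical(d$stay[1], 1L)       # S1 -> S3 equivalent
  expect_identical(d$same[1], 0L)       # a -> b
  expect_equal(d$reward[1], (3 + 4) / 9 - 0.5)
  expect_equal(d$difference[1], (3 - (-2)) / 9)
  # row 2: prev payoff -2, prev unchosen latent 6/9 -> displayed 2
  expect_identical(d$stay[2], 0L)       # S3 -> S2
  expect_identical(d$same[2], 0L)
  expect_equal(d$reward[2], (-2 + 4) / 9 - 0.5)
  expect_equal(d$difference[2], (-2 - 2) / 9)
})

test_that("a design without latent values is rejected by name", {
  log <- scripted_log(c("S1", "S1"), c(1, 2))
  log$latent_unchosen <- NA_real_
  expect_error(build_design(log), "latent_unchosen")
})

test_that("two-stage estimates recover a known per-subject logistic model", {
  # simulate stay outcomes directly from the regression model, bypassing the
  # agent: group truth b0 = 0.4, same = 0.8, reward = 1.5, same:reward = -1
  set.seed(123)
  n_sub <- 30L
  rows <- lapply(seq_len(n_sub), function(i) {
    b <- c(0.4, 0.8, 0, 1.5, 0, -1, 0, 0) + rnorm(8, 0, 0.2)
    d <- data.frame(
      subject_id = sprintf("s%02d", i), condition = "self",
      same = rbinom(300, 1, 0.5),
      reward = (sample(-4:5, 300, replace = TRUE) + 4) / 9 - 0.5,
      difference = runif(300, -0.5, 0.5)
    )
    X <- model.matrix(~ same * difference * reward, d)
    d$stay <- rbinom(300, 1, plogis(as.numeric(X %*% b)))
    d
  })
  design <- do.call(rbind, rows)
  fit <- fit_multilevel_logistic(design, method = "two_stage")
  expect_s3_class(fit, "stay_regression_fit")
  expect_identical(fit$n_subjects, n_sub)
  est <- setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(est[["(Intercept)"]], 0.4, tolerance = 0.25)
  expect_equal(est[["same"]], 0.8, tolerance = 0.35)
  expect_equal(est[["reward"]], 1.5, tolerance = 0.5)
  expect_equal(est[["same:reward"]], -1, tolerance = 0.7)
  p <- setNames(fit$fixed$p, fit$fixed$term)
  expect_lt(p[["reward"]], 0.01)
  expect_gt(p[["same:difference:reward"]], 0.01)
  # indices are the reward and same:reward columns
  ix <- mb_mf_indices(fit)
  expect_identical(ix$mb_index, fit$subject_coefs[["reward"]])
  expect_identical(ix$mf_index, fit$subject_coefs[["same:reward"]])
})

test_that("joint and two-stage routes agree on signs of strong effects", {
  task <- task_config(trials_per_condition = 84L, blocks = 2L)
  trials <- do.call(rbind, lapply(1:12, function(i) {
    simulate_session(agent_params(0.7, 0.5, 10, 0, 0, 1), task = task,
                     seed = derive_seed(500L, i),
                     subject_id = sprintf("s%02d", i))
  }))
  design <- build_design(trials)
  two <- fit_multilevel_logistic(design, method = "two_stage")
  joint <- fit_multilevel_logistic(design, method = "joint")
  expect_identical(joint$method, "joint")
  expect_identical(joint$fixed$term, two$fixed$term)
  r2 <- two$fixed[two$fixed$term == "reward", ]
  rj <- joint$fixed[joint$fixed$term == "reward", ]
  expect_gt(r2$estimate, 0)
  expect_gt(rj$estimate, 0)
  expect_lt(rj$p, 0.01)
  expect_identical(nrow(mb_mf_indices(joint)), 12L)
})

test_that("separated subjects fall back to ridge estimates and are flagged", {
  set.seed(5)
  d <- data.frame(
    subject_id = "s1", condition = "self",
    same = rbinom(120, 1, 0.5),
    reward = (sample(-4:5, 120, replace = TRUE) + 4) / 9 - 0.5,
    difference = runif(120, -0.5, 0.5)
  )
  d$stay <- as.integer(d$reward > 0)  # perfectly separated on reward
  fit <- twostepr:::fit_subject_logistic(d)
  expect_true(fit$flagged)
  expect_true(all(is.finite(fit$coefs)))
  expect_gt(fit$coefs[["reward"]], 0)
})

test_that("under-sampled subjects are dropped with a message", {
  set.seed(6)
  d_big <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 60), condition = "self",
    same = rbinom(120, 1, 0.5),
    reward = runif(120, -0.5, 0.5), difference = runif(120, -0.5, 0.5),
    stay = rbinom(120, 1, 0.5)
  )
  d_small <- d_big[1:10, ]
  d_small$subject_id <- "s3"
  expect_message(fit <- fit_multilevel_logistic(rbind(d_big, d_small)),
                 "dropping 1 subject")
  expect_identical(fit$n_subjects, 2L)
  expect_error(fit_multilevel_logistic(d_big[d_big$subject_id == "s1", ]),
               ">= 2 subjects")
  d_const <- d_big
  d_const$stay <- 1L
  expect_error(fit_multilevel_logistic(d_const), "constant")
})
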