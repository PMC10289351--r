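test_that("stay indicator handles identical, equivalent, missed and blocks", {
  log <- scripted_log(c("S1", "S1", "S3", "S2", "MISSED", "S4", "S4"),
                      c(2, 2, 2, -1, NA, 0, 3),
                      pair = c("a", "a", "b", "a", "a", "b", "b"),
                      block = c(1, 1, 1, 1, 1, 1, 2))
  expect_true(is.na(stay_indicator(log[1, ], NULL)))
  expect_true(stay_indicator(log[2, ], log[1, ]))          # identical ship
  expect_true(stay_indicator(log[3, ], log[2, ]))          # equivalent ship
  expect_false(stay_indicator(log[4, ], log[3, ]))         # switch
  expect_true(is.na(stay_indicator(log[5, ], log[4, ])))   # current missed
  expect_true(is.na(stay_indicator(log[6, ], log[5, ])))   # previous missed
  expect_true(is.na(stay_indicator(log[7, ], log[6, ])))   # block boundary
  other <- log[2, ]
  other$subject_id <- "s2"
  expect_error(stay_indicator(other, log[1, ]), "same subject-condition")
})

test_that("stay table reproduces exact scripted cell frequencies", {
  # 9 trials, one block: stays and switches with known valence/stimulus
  log <- scripted_log(
    chosen = c("S1", "S1", "S3", "S4", "S1", "S2", "S1", "S3", "S3"),
    payoff = c(3, 2, -2, 1, 0, 4, -1, 2, 2))
  st <- stay_table(log)
  cells <- st$per_subject
  pick <- function(v, s) {
    cells$stay_prob[cells$valence == v & cells$stimulus == s]
  }
  # pairs (prev -> cur): rew/same stay; rew/diff equivalent-ship stay;
  # pun/same switch; rew/diff equivalent-ship switch (S4 -> S1, not S2);
  # pun/same switch; rew/same switch; pun/diff equivalent-ship stay;
  # rew/same stay
  expect_identical(pick("reward", "same"), 2 / 3)
  expect_identical(pick("reward", "different"), 1 / 2)
  expect_identical(pick("punish", "same"), 0)
  expect_identical(pick("punish", "different"), 1)
  expect_identical(sum(cells$n_pairs), 8L)
})

test_that("zero-pair cells are NA and flagged incomplete", {
  log <- scripted_log(c("S1", "S1", "S1"), c(2, 3, 4))  # rewards only
  st <- stay_table(log)
  expect_true(all(is.na(
    st$per_subject$stay_prob[st$per_subject$valence == "punish"])))
  expect_identical(st$incomplete, "s1")
})

test_that("the valence threshold splits payoffs at >= 1 by default", {
  log <- scripted_log(c("S1", "S1", "S1", "S1"), c(1, 0, 1, 0))
  pairs <- twostepr:::stay_pairs(log)
  expect_identical(pairs$valence, c("reward", "punish", "reward"))
})

test_that("the 2x2x2 ANOVA agrees with stats::aov", {
  set.seed(99)
  n <- 14L
  cells <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                       condition = c("self", "other"),
                       valence = c("reward", "punish"),
                       stimulus = c("same", "different"),
                       stringsAsFactors = FALSE)
  cells$stay_prob <- plogis(rnorm(nrow(cells), 0.5, 1))
  res <- rm_anova_2x2x2(cells)
  expect_identical(attr(res, "n_subjects"), n)
  d <- cells
  d$subject_id <- factor(d$subject_id)
  for (f in c("condition", "valence", "stimulus")) d[[f]] <- factor(d[[f]])
  av <- summary(stats::aov(
    stay_prob ~ condition * valence * stimulus +
      Error(subject_id / (condition * valence * stimulus)), data = d))
  for (eff in res$effect) {
    stratum <- av[[sprintf("Error: subject_id:%s", eff)]][[1]]
    expect_equal(res$F[res$effect == eff], stratum[eff, "F value"],
                 tolerance = 1e-8)
    expect_equal(res$p[res$effect == eff], stratum[eff, "Pr(>F)"],
                 tolerance = 1e-8)
  }
})

test_that("constant cells give F = 0 and incomplete subjects are dropped", {
  cells <- expand.grid(subject_id = c("s1", "s2", "s3"),
                       condition = c("self", "other"),
                       valence = c("reward", "punish"),
                       stimulus = c("same", "different"),
                       stringsAsFactors = FALSE)
  cells$stay_prob <- 0.5
  res <- rm_anova_2x2x2(cells)
  expect_identical(res$F, rep(0, 7))
  expect_identical(res$p, rep(1, 7))
  cells$stay_prob[1] <- NA
  expect_identical(attr(rm_anova_2x2x2(cells), "n_subjects"), 2L)
})

test_that("session metrics match hand-computed values", {
  log <- scripted_log(c("S1", "S2", "S1"), c(3, -2, 1),
                      latent_chosen = c(7 / 9, 2 / 9, 5 / 9),
                      latent_unchosen = c(4 / 9, 6 / 9, 5 / 9))
  # correct: TRUE, FALSE, NA(tie) -> accuracy 1/2
  expect_identical(accuracy(log), 0.5)
  # displayed: chosen 3, -2, 1; unchosen 0, 2, 1; best 3, 2, 1
  expect_identical(relative_performance(log), 2 / 6)
  # chance: (3+0)/2, (-2+2)/2, (1+1)/2 = 1.5, 0, 1 -> mean 5/6
  expect_equal(corrected_reward_rate(log), 2 / 3 - 5 / 6)
  mt <- metric_table(log)
  expect_identical(nrow(mt), 1L)
  expect_identical(mt$reward_rate, 2 / 3)
})

test_that("metrics ignore missed trials and degrade gracefully", {
  log <- scripted_log(c("S1", "MISSED", "S2"), c(3, NA, -2),
                      pair = c("a", "a", "a"),
                      latent_chosen = c(7 / 9, NA, 2 / 9),
                      latent_unchosen = c(4 / 9, NA, 6 / 9))
  expect_identical(accuracy(log), 0.5)
  all_missed <- scripted_log(rep("MISSED", 3), rep(NA, 3),
                             pair = rep("a", 3))
  expect_true(is.na(accuracy(all_missed)))
  expect_true(is.na(corrected_reward_rate(all_missed)))
})

test_that("paired comparison matches stats::t.test", {
  set.seed(7)
  x <- rnorm(20)
  y <- rnorm(20, 0.3)
  ours <- paired_comparison(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$ci, as.numeric(ref$conf.int))
  expect_equal(ours$mean_diff, unname(ref$estimate))
  degen <- paired_comparison(x, x)
  expect_true(degen$degenerate)
  expect_identical(degen$t, 0)
  expect_identical(degen$p, 1)
  expect_error(paired_comparison(1, 2), "at least 2")
})

test_that("pearson correlation matches stats::cor.test", {
  set.seed(8)
  x <- rnorm(25)
  y <- x + rnorm(25)
  ours <- pearson_corr(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value)
  expect_equal(ours$ci, as.numeric(ref$conf.int))
  expect_true(pearson_corr(x, rep(1, 25))$degenerate)
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})
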