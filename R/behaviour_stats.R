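#' Did the current trial repeat the previous first-stage choice?
#'
#' A *stay* is repeating the previous choice either literally (same pair,
#' identical ship) or functionally (different pair, the equivalent ship with
#' the same destination planet). Undefined (`NA`) when either trial was
#' missed or the trials fall in different blocks.
#'
#' @param current,previous Consecutive one-row trial records from the same
#'   subject-condition session.
#' @param structure A [transition_structure()].
#' @return `TRUE`, `FALSE`, or `NA` when undefined.
#' @export
stay_indicator <- function(current, previous,
                           structure = transition_structure()) {
  if (is.null(previous)) return(NA)
  if (!identical(current$subject_id, previous$subject_id) ||
      !identical(current$condition, previous$condition)) {
    stop_invalid("trials must come from the same subject-condition session")
  }
  if (current$block != previous$block) return(NA)
  if (current$chosen_ship == "MISSED" || previous$chosen_ship == "MISSED") {
    return(NA)
  }
  current$chosen_ship == previous$chosen_ship ||
    current$chosen_ship == equivalent_ship(previous$chosen_ship, structure)
}

# Vectorised stay/valence/stimulus construction over consecutive trial pairs
# within blocks. Returns one row per eligible pair.
stay_pairs <- function(trials, structure = transition_structure(),
                       valence_threshold = 1) {
  ord <- order(trials$subject_id, trials$condition, trials$trial_index)
  tr <- trials[ord, ]
  n <- nrow(tr)
  if (n < 2L) {
    return(data.frame(subject_id = character(0), condition = character(0),
                      stay = logical(0), valence = character(0),
                      stimulus = character(0), prev_payoff = integer(0),
                      prev_chosen = character(0),
                      prev_latent_unchosen = numeric(0),
                      same = integer(0), stringsAsFactors = FALSE))
  }
  cur <- tr[-1L, ]
  prev <- tr[-n, ]
  eligible <- cur$subject_id == prev$subject_id &
    cur$condition == prev$condition &
    cur$block == prev$block &
    cur$chosen_ship != "MISSED" & prev$chosen_ship != "MISSED"
  cur <- cur[eligible, ]
  prev <- prev[eligible, ]
  stay <- cur$chosen_ship == prev$chosen_ship |
    cur$chosen_ship == structure$equivalent[prev$chosen_ship]
  data.frame(
    subject_id = cur$subject_id, condition = cur$condition,
    stay = stay,
    valence = ifelse(prev$payoff >= valence_threshold, "reward", "punish"),
    stimulus = ifelse(cur$pair_shown == prev$pair_shown, "same", "different"),
    prev_payoff = prev$payoff, prev_chosen = prev$chosen_ship,
    prev_latent_unchosen = prev$latent_unchosen,
    same = as.integer(cur$pair_shown == prev$pair_shown),
    stringsAsFactors = FALSE
  )
}

#' Stay-probability table
#'
#' Stay probabilities by condition x previous-outcome valence x stimulus
#' (same or different pair than the previous trial). The valence split uses
#' the previous displayed payoff: `>= valence_threshold` (default 1, i.e. at
#' least one point) counts as reward, otherwise punishment. Per-subject cell
#' means are computed first, then averaged across subjects.
#'
#' @param trials Stacked trial logs (exclusions applied).
#' @param structure A [transition_structure()].
#' @param valence_threshold Minimum payoff counted as rewarding.
#' @return An object of class `stay_stats`: `per_subject` (one row per
#'   subject x condition x valence x stimulus with `stay_prob` and `n_pairs`)
#'   and `group` (cell means with SE over subjects). Cells with zero pairs
#'   carry `NA` and are flagged in `incomplete`.
#' @export
stay_table <- function(trials, structure = transition_structure(),
                       valence_threshold = 1) {
  pairs <- stay_pairs(trials, structure, valence_threshold)
  cells <- expand.grid(
    subject_id = unique(trials$subject_id),
    condition = unique(trials$condition),
    valence = c("reward", "punish"), stimulus = c("same", "different"),
    stringsAsFactors = FALSE
  )
  key <- function(d) paste(d$subject_id, d$condition, d$valence, d$stimulus)
  agg_mean <- tapply(pairs$stay, key(pairs), mean)
  agg_n <- tapply(pairs$stay, key(pairs), length)
  cells$stay_prob <- as.numeric(agg_mean[key(cells)])
  cells$n_pairs <- as.integer(agg_n[key(cells)])
  cells$n_pairs[is.na(cells$n_pairs)] <- 0L
  grp_key <- paste(cells$condition, cells$valence, cells$stimulus)
  group <- unique(cells[, c("condition", "valence", "stimulus")])
  gk <- paste(group$condition, group$valence, group$stimulus)
  group$stay_prob <- as.numeric(tapply(cells$stay_prob, grp_key,
                                       mean, na.rm = TRUE)[gk])
  group$se <- as.numeric(tapply(cells$stay_prob, grp_key, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  })[gk])
  group$n_subjects <- as.integer(tapply(!is.na(cells$stay_prob), grp_key,
                                        sum)[gk])
  structure(
    list(per_subject = cells, group = group,
         incomplete = unique(cells$subject_id[is.na(cells$stay_prob)]),
         valence_threshold = valence_threshold),
    class = "stay_stats"
  )
}

#' 2x2x2 repeated-measures ANOVA on stay probabilities
#'
#' Fully within-subject factorial ANOVA over valence (reward/punish) x
#' stimulus (same/different) x condition (self/other). With two levels per
#' factor, each effect's F(1, n-1) equals the squared one-sample t of the
#' corresponding within-subject contrast, which is how it is computed here
#' (numerically identical to `stats::aov` with an error stratum per effect).
#' Subjects with any undefined cell are dropped listwise.
#'
#' @param stay_stats A [stay_table()] result (or its `per_subject` frame).
#' @return A `data.frame` with one row per effect: `effect`, `F`, `df1`,
#'   `df2`, `p`, plus attribute `n_subjects`.
#' @export
rm_anova_2x2x2 <- function(stay_stats) {
  cells <- if (inherits(stay_stats, "stay_stats")) stay_stats$per_subject
           else stay_stats
  conds <- sort(unique(cells$condition))
  if (length(conds) != 2L) stop_invalid("exactly two conditions required")
  wide_key <- paste(cells$condition, cells$valence, cells$stimulus)
  subjects <- unique(cells$subject_id)
  m <- matrix(NA_real_, length(subjects), 8,
              dimnames = list(subjects, sort(unique(wide_key))))
  for (i in seq_len(nrow(cells))) {
    m[cells$subject_id[i], wide_key[i]] <- cells$stay_prob[i]
  }
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) stop_invalid("need >= 2 subjects with complete cells")
  lv <- strsplit(colnames(m), " ")
  s_cond <- ifelse(vapply(lv, `[`, "", 1) == conds[1], 1, -1)
  s_val <- ifelse(vapply(lv, `[`, "", 2) == "punish", -1, 1)
  s_stim <- ifelse(vapply(lv, `[`, "", 3) == "same", 1, -1)
  effects <- list(
    condition = s_cond, valence = s_val, stimulus = s_stim,
    `condition:valence` = s_cond * s_val,
    `condition:stimulus` = s_cond * s_stim,
    `valence:stimulus` = s_val * s_stim,
    `condition:valence:stimulus` = s_cond * s_val * s_stim
  )
  n <- nrow(m)
  out <- lapply(names(effects), function(nm) {
    contrast <- as.numeric(m %*% effects[[nm]]) / 8
    mu <- mean(contrast)
    v <- stats::var(contrast)
    f <- if (mu == 0 && v == 0) 0
         else if (v == 0) Inf
         else n * mu^2 / v
    data.frame(effect = nm, F = f, df1 = 1L, df2 = n - 1L,
               p = if (is.finite(f)) stats::pf(f, 1, n - 1, lower.tail = FALSE)
                   else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "n_subjects") <- n
  res
}

session_valid <- function(session) {
  session[session$chosen_ship != "MISSED", , drop = FALSE]
}

#' Choice accuracy of a session
#'
#' Fraction of non-missed trials on which the chosen ship led to the planet
#' with the strictly higher latent value; latent-value ties are excluded.
#'
#' @param session A single-session trial log.
#' @return Accuracy in `[0, 1]`, or `NA` if no valid trials.
#' @export
accuracy <- function(session) {
  ok <- session_valid(session)
  ok <- ok$correct[!is.na(ok$correct)]
  if (length(ok) == 0L) return(NA_real_)
  mean(ok)
}

#' Relative performance of a session
#'
#' Sum of obtained payoffs divided by the maximum attainable payoff (the
#' per-trial maximum of the two planets' displayed payoffs), over non-missed
#' trials.
#'
#' @param session A single-session trial log with latent values.
#' @return A fraction (typically in `[0, 1]`); `NA` with a warning when the
#'   attainable denominator is not positive.
#' @export
relative_performance <- function(session) {
  ok <- session_valid(session)
  if (nrow(ok) == 0L) return(NA_real_)
  best <- pmax(payoff_from_value(ok$latent_chosen),
               payoff_from_value(ok$latent_unchosen))
  denom <- sum(best)
  if (denom <= 0) {
    warning("maximum attainable reward is not positive; relative performance undefined")
    return(NA_real_)
  }
  sum(ok$payoff) / denom
}

#' Corrected reward rate of a session
#'
#' Mean obtained payoff minus the chance baseline: the per-trial average of
#' the two planets' displayed payoffs, i.e. the expected payoff of a uniform
#' random chooser on the same walks. Removes the luck of the reward drift.
#'
#' @inheritParams relative_performance
#' @return A scalar (points per trial above chance), `NA` if no valid trials.
#' @export
corrected_reward_rate <- function(session) {
  ok <- session_valid(session)
  if (nrow(ok) == 0L) return(NA_real_)
  chance <- (payoff_from_value(ok$latent_chosen) +
               payoff_from_value(ok$latent_unchosen)) / 2
  mean(ok$payoff) - mean(chance)
}

#' Per-subject behavioural metrics
#'
#' @param trials Stacked trial logs.
#' @return A `data.frame` keyed by `subject_id` and `condition` with
#'   `accuracy`, `relative_performance`, `corrected_reward_rate` and
#'   `reward_rate` (raw mean payoff).
#' @export
metric_table <- function(trials) {
  keys <- unique(trials[, c("subject_id", "condition")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    s <- trials[trials$subject_id == keys$subject_id[i] &
                  trials$condition == keys$condition[i], ]
    ok <- session_valid(s)
    data.frame(
      subject_id = keys$subject_id[i], condition = keys$condition[i],
      accuracy = accuracy(s),
      relative_performance = relative_performance(s),
      corrected_reward_rate = corrected_reward_rate(s),
      reward_rate = if (nrow(ok)) mean(ok$payoff) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Two-tailed paired t-test
#'
#' Paired t statistic with `df = n - 1` and the 95% confidence interval of
#' the mean difference `x - y`. A zero-variance difference is flagged as
#' degenerate (`t = 0, p = 1` when the difference is identically zero).
#'
#' @param x,y Paired numeric vectors (complete observations).
#' @param conf_level Confidence level of the interval.
#' @return A list: `t`, `df`, `p`, `ci`, `mean_diff`, `degenerate`.
#' @export
paired_comparison <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2L) stop_invalid("need at least 2 complete pairs")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else NA_real_, df = n - 1L,
                p = if (m == 0) 1 else NA_real_, ci = c(m, m),
                mean_diff = m, degenerate = TRUE))
  }
  se <- s / sqrt(n)
  t <- m / se
  crit <- qt(1 - (1 - conf_level) / 2, n - 1)
  list(t = t, df = n - 1L, p = 2 * pt(-abs(t), n - 1),
       ci = c(m - crit * se, m + crit * se), mean_diff = m,
       degenerate = FALSE)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`).
#' @param conf_level Confidence level of the interval.
#' @return A list: `r`, `p` (two-sided), `ci`, `n`, `degenerate` (`TRUE`
#'   when either vector has zero variance, in which case `r` is `NA`).
#' @export
pearson_corr <- function(x, y, conf_level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop_invalid("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                n = length(x), degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = length(x), degenerate = FALSE)
}
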