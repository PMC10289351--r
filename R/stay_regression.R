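regression_terms <- c("(Intercept)", "same", "difference", "reward",
                      "same:difference", "same:reward", "difference:reward",
                      "same:difference:reward")

#' Build the trial-level stay-regression design
#'
#' One row per pair of consecutive non-missed trials within a block. The
#' outcome is `stay` (repeat of the previous choice, identical or equivalent
#' ship). Predictors, all referring to the previous trial and rescaled to
#' roughly `[-0.5, 0.5]` for stable estimation:
#' * `reward` — previous obtained payoff, `(payoff + 4)/9 - 0.5`;
#' * `same` — 1 if the current trial shows the same pair, 0 otherwise;
#' * `difference` — previous chosen-minus-unchosen displayed payoff, divided
#'   by 9. The unchosen payoff is the display mapping of the unchosen
#'   planet's latent value (available to the analyst from the generative
#'   walks, though never shown to the agent).
#'
#' @param trials Stacked trial logs (exclusions applied), with latent values.
#' @param structure A [transition_structure()].
#' @return A `data.frame`: `subject_id`, `condition`, `stay` (0/1), `same`,
#'   `reward`, `difference`.
#' @export
build_design <- function(trials, structure = transition_structure()) {
  if (all(is.na(trials$latent_unchosen[trials$chosen_ship != "MISSED"]))) {
    stop_invalid("column `latent_unchosen` has no values; ",
                 "the design needs the unchosen planet's latent value")
  }
  pairs <- stay_pairs(trials, structure)
  if (any(is.na(pairs$prev_latent_unchosen))) {
    stop_invalid("column `latent_unchosen` is missing for some trials")
  }
  data.frame(
    subject_id = pairs$subject_id, condition = pairs$condition,
    stay = as.integer(pairs$stay), same = pairs$same,
    reward = (pairs$prev_payoff + 4) / 9 - 0.5,
    difference = (pairs$prev_payoff -
                    payoff_from_value(pairs$prev_latent_unchosen)) / 9,
    stringsAsFactors = FALSE
  )
}

ridge_logistic <- function(X, y, lambda = 1e-2) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(log1p(exp(-(2 * y - 1) * eta))) + lambda * sum(b^2)
  }
  grad <- function(b) {
    eta <- as.numeric(X %*% b)
    p <- 1 / (1 + exp(-eta))
    as.numeric(crossprod(X, p - y)) + 2 * lambda * b
  }
  optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
        control = list(maxit = 500L))$par
}

fit_subject_logistic <- function(d, ridge_lambda = 1e-2) {
  X <- model.matrix(~ same * difference * reward, d)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(stay ~ same * difference * reward, family = binomial(), data = d,
        control = glm.control(maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  b <- coef(fit)
  if (sep || !fit$converged || anyNA(b) || any(abs(b) > 15)) {
    b <- ridge_logistic(X, d$stay, ridge_lambda)
    names(b) <- colnames(X)
    flagged <- TRUE
  } else {
    flagged <- FALSE
  }
  list(coefs = b[regression_terms], flagged = flagged)
}

#' Multilevel logistic stay regression
#'
#' Fits the full factorial `stay ~ same * difference * reward` logistic model
#' with per-subject coefficients on all terms, by one of two routes:
#'
#' * `"two_stage"` (default): per-subject maximum-likelihood logistic fits;
#'   group-level fixed effects are the across-subject means with a
#'   one-sample t for inference. Subjects with separation are refitted with
#'   a small ridge penalty and flagged.
#' * `"joint"`: a single [lme4::glmer()] mixed-effects fit with all
#'   coefficients as correlated random effects.
#'
#' The `reward` main effect measures outcome sensitivity that generalises
#' across pairs — the model-based index; the `same:reward` interaction
#' measures the extra sensitivity confined to same-pair trials — the
#' model-free index.
#'
#' @param design A [build_design()] frame (typically one condition).
#' @param method `"two_stage"` or `"joint"`.
#' @param min_rows Minimum design rows per subject; subjects below are
#'   dropped with a message.
#' @param ridge_lambda Ridge penalty used for separated subject fits.
#' @return An object of class `stay_regression_fit`: `method`, `fixed`
#'   (8 rows: `term`, `estimate`, `se`, `z`, `p`), `subject_coefs` (one row
#'   per subject with all 8 coefficients and a `flagged` column) and
#'   `n_subjects`.
#' @export
fit_multilevel_logistic <- function(design,
                                    method = c("two_stage", "joint"),
                                    min_rows = 20L, ridge_lambda = 1e-2) {
  method <- match.arg(method)
  counts <- table(design$subject_id)
  small <- names(counts)[counts < min_rows]
  if (length(small)) {
    message("dropping ", length(small), " subject(s) with < ", min_rows,
            " design rows")
    design <- design[!(design$subject_id %in% small), , drop = FALSE]
  }
  subjects <- unique(design$subject_id)
  if (length(subjects) < 2L) stop_invalid("need >= 2 subjects to fit")
  if (length(unique(design$stay)) < 2L) {
    stop_invalid("outcome is constant; no finite estimate exists")
  }

  if (method == "two_stage") {
    per <- lapply(subjects, function(sid) {
      fit_subject_logistic(design[design$subject_id == sid, ], ridge_lambda)
    })
    cf <- do.call(rbind, lapply(per, function(x) x$coefs))
    n <- nrow(cf)
    est <- colMeans(cf)
    se <- apply(cf, 2, sd) / sqrt(n)
    z <- est / se
    fixed <- data.frame(
      term = regression_terms, estimate = unname(est), se = unname(se),
      z = unname(z), p = unname(2 * pt(-abs(z), n - 1)),
      stringsAsFactors = FALSE
    )
    subject_coefs <- data.frame(subject_id = subjects, cf,
                                flagged = vapply(per, `[[`, TRUE, "flagged"),
                                check.names = FALSE, row.names = NULL,
                                stringsAsFactors = FALSE)
  } else {
    fit <- suppressWarnings(suppressMessages(
      lme4::glmer(stay ~ same * difference * reward +
                    (same * difference * reward | subject_id),
                  data = design, family = binomial(), nAGQ = 0L,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    ))
    sm <- summary(fit)$coefficients
    fixed <- data.frame(
      term = rownames(sm), estimate = sm[, "Estimate"],
      se = sm[, "Std. Error"], z = sm[, "z value"], p = sm[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE
    )
    cc <- coef(fit)$subject_id
    subject_coefs <- data.frame(subject_id = rownames(cc), cc,
                                flagged = FALSE, check.names = FALSE,
                                row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(
    list(method = method, fixed = fixed, subject_coefs = subject_coefs,
         n_subjects = length(subjects), n_rows = nrow(design)),
    class = "stay_regression_fit"
  )
}

#' Per-subject model-based and model-free indices
#'
#' The model-based index is each subject's `reward` coefficient (outcome
#' sensitivity that generalises across pairs); the model-free index is the
#' `same:reward` coefficient (extra sensitivity confined to the same pair).
#'
#' @param fit A [fit_multilevel_logistic()] result.
#' @return A `data.frame`: `subject_id`, `mb_index`, `mf_index`.
#' @export
mb_mf_indices <- function(fit) {
  sc <- fit$subject_coefs
  data.frame(subject_id = sc$subject_id, mb_index = sc[["reward"]],
             mf_index = sc[["same:reward"]], stringsAsFactors = FALSE)
}
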