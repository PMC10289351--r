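---
title: "Methods: the hybrid learner, its fitting, and the behavioural analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the hybrid learner, its fitting, and the behavioural analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
```

## The task

`twostepr` implements a deterministic-transition variant of the two-step
task (Daw et al., 2011; the deterministic variant follows Kool, Cushman &
Gershman, 2016). On every trial one of two spaceship pairs is shown —
pair *a* (S1/S2) or pair *b* (S3/S4) — and the participant picks one ship
within one second. Each ship flies to a fixed, known planet: S1 and S3 go
to planet `P_A`, S2 and S4 to planet `P_B`. The planet pays out an integer
number of points between −4 and +5, read off a latent value that drifts
across trials as a Gaussian random walk (step SD 0.2) reflected into
[0, 1]:

```{r}
walks <- generate_reward_walks(126, sigma = 0.2, seed = 1)
range(walks$values$P_A)
payoff_from_value(c(0, 0.5, 1))
```

The display mapping is the unique monotone affine map from [0, 1] onto
−4..+5 with half-up rounding, `payoff = round(9 v) − 4`; learning operates
on the normalised scale `(payoff + 4) / 9`.

Because S1 and S3 (and S2 and S4) are *equivalent* — same destination,
different pair — reward obtained after choosing S1 is informative about S3
**only** for a learner that uses the transition model. This is the
manipulation that separates model-based from model-free control, and every
analysis in the package leans on it.

A session is 126 scored trials in 3 blocks, each block showing both pairs
equally often in randomised order. Each agent plays two sessions,
labelled `self` and `other`: the task rules are identical, only whom the
payoff benefits differs, so the generative model allows a condition shift
only in the model-based weight (`delta_w`).

## The hybrid learner

The agent carries model-free first-stage values `q_mf(ship)` and
second-stage planet values `v2(planet)`, all initialised at 0.5 (the
midpoint of the normalised payoff scale). The second-stage values are
shared by both systems: since there is no further choice at the planet,
model-based and model-free valuation coincide there.

**Model-based values** are the one-step Bellman backup through the known
deterministic transitions, which reduces to a lookup:
`Q_MB(ship) = v2(destination(ship))`. Equivalent ships therefore always
carry identical model-based values.

**Model-free learning** is SARSA(λ) with a single learning rate α shared
by both stages. After choosing ship *c* and landing on planet *p* with
normalised reward *r*:

1. stage-1 backup at the moment of transition:
   `q_mf(c) += α (v2(p) − q_mf(c))`
2. second-stage prediction error: `δ2 = r − v2(p)`, `v2(p) += α δ2`
3. eligibility-traced propagation: `q_mf(c) += α λ δ2`

Only the chosen ship and the visited planet are updated — model-free
values never generalise across pairs.

**Choice** is a softmax over the two shown ships with two perseveration
bonuses:

`P(a) ∝ exp( β [ Q_net(a) + π · rep(a) + ρ · resp(a) ] )`

where `Q_net = w Q_MB + (1 − w) q_mf`, `rep(a) = 1` only if *a* is the
*identical* ship chosen on the previous trial (never its equivalent), and
`resp(a) = 1` if *a* sits on the previously pressed key side. Two
deliberate conventions:

* the stickiness bonuses sit **inside** the bracket and are therefore
  scaled by β, matching the form in which this model family is usually
  printed; with this convention π and ρ are unitless biases relative to
  the value scale;
* stickiness referents reset at every block start, and missed trials
  (no response within the window) trigger neither learning nor a referent
  update.

The six parameters are `alpha`, `lam`, `beta`, `pi`, `rho`, `w`, with
`w = 1` a pure model-based and `w = 0` a pure model-free agent.

```{r}
p <- agent_params(alpha = 0.7, lam = 0.5, beta = 10, pi = 0, rho = 0,
                  w = 0.8)
session <- simulate_session(p, seed = 1)
head(session[, c("block", "pair_shown", "chosen_ship", "planet", "payoff")])
```

## Fitting

`fit_map()` maximises the per-session log posterior: the replayed choice
log likelihood plus empirical priors `β ~ Gamma(shape 4.82, scale 0.88)`
and `π, ρ ~ Normal(0.15, SD 1.42)`, with flat priors on [0, 1] for α, λ
and w. Outside the support the objective returns `+Inf` (a penalty, not
an error). Optimisation is bounded L-BFGS-B from 10 restarts — the prior
means first, the rest drawn from the priors — and is deterministic given
its `seed`. `fit_cohort()` fits every subject × condition session
independently, mirroring the per-condition comparisons downstream.

## When is `w` identifiable?

A point worth being explicit about, because it shapes how the package's
own validation studies are set up. The mixture weight is only expressed
in behaviour through the *difference* between model-based and model-free
valuations of the shown pair, which is non-zero only transiently after
cross-pair outcome swings. Its visibility is gated by the other
parameters:

* small β (noisy choice) or small α (slow learning) shrink the signal
  toward zero;
* because the softmax scales the stickiness bonuses by β, draws with
  strong |π| can dominate the value signal entirely;
* the shared `v2` feeds the stage-1 backup, so even a pure model-free
  agent indirectly benefits from cross-pair information one choice later,
  further narrowing the gap between the two systems.

If all six parameters are drawn from the wide generative defaults, many
agents are simply uninformative about `w` at a few hundred trials: an
*oracle* that knows the true nuisance parameters and profiles only `w`
correlates with the truth at r ≈ 0.3 over such a cohort — no estimator can
do better. Recovery and power studies in the package therefore use a
*reference cohort*: `w ~ Uniform(0, 1)` with identifiable nuisance values
(α = 0.7, λ = 0.5, β = 10, π = ρ = 0). At 252 trials per session this
yields r(true w, ŵ) ≈ 0.93 with |bias| ≈ 0.02, and a paired self-vs-other
t-test on ŵ is calibrated under `delta_w = 0` and well-powered at
`delta_w = 0.3` with n = 36. The cohort *generator's* defaults remain the
wide distributions — heterogeneous cohorts are the realistic case; the
reference cohort is a measurement instrument for validating the fitting
machinery.

## Behavioural statistics

A **stay** is repeating the previous first-stage choice, either the
identical ship (same pair shown) or the *equivalent* ship (other pair
shown). The equivalence branch is what lets a stay analysis speak to
model-based generalisation at all. `stay_table()` splits stays by the
previous outcome's valence — a displayed payoff ≥ 1, i.e. at least one
point won, counts as reward; ≤ 0 as punishment — and by stimulus
(same/different pair), computing per-subject cell means first.
`rm_anova_2x2x2()` runs the fully within-subject valence × stimulus ×
condition ANOVA; with two levels per factor every effect's F(1, n−1) is
the squared paired t of the corresponding contrast, which is how it is
computed (and it is cross-checked against `stats::aov` in the tests).

Performance metrics, per session: `accuracy` (fraction of choices toward
the planet with the strictly higher latent value), `relative_performance`
(points earned over points attainable), and `corrected_reward_rate` —
mean obtained payoff minus the per-trial average of the two planets'
displayed payoffs. That baseline is exactly the expected payoff of a
uniform random chooser on the same walks, so the correction removes the
luck of the reward drift; a uniform chooser scores 0 in expectation.

## The stay regression

`build_design()` turns consecutive non-missed within-block trial pairs
into rows of `stay ~ same * difference * reward`, all predictors referring
to the previous trial: `reward` is the obtained payoff rescaled to
[−0.5, 0.5]; `same` indicates the same pair shown again; `difference` is
the chosen-minus-unchosen displayed payoff (rescaled by 9), included to
absorb the autocorrelation of the walks. The `reward` main effect is the
**model-based index** — outcome sensitivity that generalises across pairs
— and `same:reward` is the **model-free index**, the extra sensitivity
confined to the same pair.

`fit_multilevel_logistic()` offers two routes: the default two-stage
estimator (per-subject maximum-likelihood logistic fits, group inference
by one-sample t over subjects; separated subjects are refitted with a
small ridge penalty and flagged) and a joint `lme4::glmer` fit with all
coefficients as correlated random effects (`nAGQ = 0`). The two-stage
route is the default because it is orders of magnitude faster, never
fails to converge on simulated cohorts, and its group estimates agree in
sign and significance with the joint fit where both apply.

Simulated pure agents show the expected signatures: a `w = 1` cohort has
a strongly positive `reward` coefficient with a null `same:reward`
interaction; a `w = 0` cohort the reverse. One caveat the `difference`
regressor does not fully remove: because the walks are autocorrelated and
the shared `v2` leaks cross-pair information into the model-free system
with one-trial lag, a model-free cohort retains a small positive `reward`
main effect. It is several times smaller than the model-based cohort's and
often indistinguishable from zero at study-sized sessions, but it grows
visible in long sessions — a property of the paradigm, not an estimator
bug.

## The pipeline

`run_pipeline()` chains simulate → exclude → fit → analyse and writes a
self-describing bundle (trial logs, ground truth, MAP fits, stay tables,
ANOVA, regression fixed effects, MB/MF indices, paired self-vs-other
tests, correlations, a config echo and manifest). Runs are byte-identical
given the same configuration: every random draw flows from the config
seeds through `derive_seed()`. Exclusions mirror common practice: more
than 20% missed trials in a condition, or choosing one ship of a pair on
100% of that pair's presentations. A YAML config validated by
`validate_config()` (unknown keys are rejected by full name) and a thin
`Rscript` front end in `inst/cli/twostep.R` expose the same functionality
from the command line.

## Limitations

* Reaction times are not modelled; the response window is metadata.
* The generative model assumes a single α for both stages and shared
  `v2`; fitting data from a learner with split learning rates or separate
  model-free stage-2 values will be misspecified.
* MAP point estimates shrink toward prior means at the bounds of the
  support; population-level conclusions about `w` should lean on the
  paired within-subject design rather than absolute values.

## References

* Daw, N. D., Gershman, S. J., Seymour, B., Dayan, P., & Dolan, R. J.
  (2011). Model-based influences on humans' choices and striatal
  prediction errors. *Neuron*, 69(6), 1204–1215.
* Kool, W., Cushman, F. A., & Gershman, S. J. (2016). When does
  model-based control pay off? *PLOS Computational Biology*, 12(8),
  e1005090.
* Rummery, G. A., & Niranjan, M. (1994). *On-line Q-learning using
  connectionist systems.* Cambridge University Engineering Department.
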