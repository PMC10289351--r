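#' Transition structure of the two-step task
#'
#' Two ship pairs (`a` = S1/S2, `b` = S3/S4) and two planets. Each ship has a
#' fixed, deterministic destination, and each ship has an *equivalent* ship in
#' the other pair with the same destination (S1–S3 reach planet `P_A`, S2–S4
#' reach planet `P_B`). This equivalence is what separates model-based from
#' model-free behaviour: reward generalises across equivalent ships only for
#' an agent that uses the transition model.
#'
#' @return An object of class `transition_structure` with elements `pairs`
#'   (named list of ship-id pairs), `destination` (named character map
#'   ship -> planet) and `equivalent` (named character map ship -> ship).
#' @examples
#' ts <- transition_structure()
#' resolve_transition("S1", ts)
#' @export
transition_structure <- function() {
  structure(
    list(
      pairs = list(a = c("S1", "S2"), b = c("S3", "S4")),
      destination = c(S1 = "P_A", S2 = "P_B", S3 = "P_A", S4 = "P_B"),
      equivalent = c(S1 = "S3", S2 = "S4", S3 = "S1", S4 = "S2")
    ),
    class = "transition_structure"
  )
}

#' Resolve a ship's destination planet
#'
#' @param ship A ship id (`"S1"`..`"S4"`).
#' @param structure A [transition_structure()].
#' @return The planet id (`"P_A"` or `"P_B"`).
#' @export
resolve_transition <- function(ship, structure = transition_structure()) {
  if (!all(ship %in% names(structure$destination))) {
    stop_invalid("unknown ship id: ",
                 paste(setdiff(ship, names(structure$destination)), collapse = ", "))
  }
  unname(structure$destination[ship])
}

#' The equivalent ship in the other pair
#'
#' @inheritParams resolve_transition
#' @return The ship id with the same destination in the other pair.
#' @export
equivalent_ship <- function(ship, structure = transition_structure()) {
  if (!all(ship %in% names(structure$equivalent))) {
    stop_invalid("unknown ship id: ",
                 paste(setdiff(ship, names(structure$equivalent)), collapse = ", "))
  }
  unname(structure$equivalent[ship])
}

#' Task configuration
#'
#' Defaults reproduce the study design: 126 scored trials per condition in 3
#' blocks, a 1000 ms response window, payoffs displayed as integers between
#' -4 and +5, latent planet values drifting as bounded Gaussian random walks
#' with step SD 0.2, and 25 practice trials that are excluded from analysis.
#'
#' @param trials_per_condition Number of scored trials per condition; must be
#'   divisible by `blocks`.
#' @param blocks Number of blocks per condition.
#' @param practice_trials Number of practice (analysis-excluded) trials.
#' @param response_window_ms Response window in milliseconds (metadata only;
#'   reaction times are not modelled).
#' @param payoff_min,payoff_max Integer payoff display range.
#' @param miss_rate Probability of a missed (no-response) trial in
#'   simulation; the study's scored data correspond to `miss_rate = 0`.
#' @param walk_sigma Per-step SD of the latent Gaussian reward walks.
#' @param walk_init_range Range from which each walk's initial value is drawn
#'   uniformly.
#' @return An object of class `task_config`.
#' @export
task_config <- function(trials_per_condition = 126L, blocks = 3L,
                        practice_trials = 25L, response_window_ms = 1000,
                        payoff_min = -4L, payoff_max = 5L, miss_rate = 0,
                        walk_sigma = 0.2, walk_init_range = c(0.25, 0.75)) {
  trials_per_condition <- as.integer(trials_per_condition)
  blocks <- as.integer(blocks)
  if (trials_per_condition < 0L || blocks < 1L) {
    stop_invalid("`trials_per_condition` must be >= 0 and `blocks` >= 1")
  }
  if (trials_per_condition %% blocks != 0L) {
    stop_invalid("`trials_per_condition` must be divisible by `blocks`")
  }
  if (payoff_min >= payoff_max) stop_invalid("`payoff_min` must be < `payoff_max`")
  assert_number(miss_rate, "miss_rate", 0, 1)
  assert_number(walk_sigma, "walk_sigma", 0)
  structure(
    list(trials_per_condition = trials_per_condition, blocks = blocks,
         practice_trials = as.integer(practice_trials),
         response_window_ms = response_window_ms,
         payoff_min = as.integer(payoff_min),
         payoff_max = as.integer(payoff_max),
         miss_rate = miss_rate, walk_sigma = walk_sigma,
         walk_init_range = walk_init_range),
    class = "task_config"
  )
}

reflect01 <- function(x) {
  # fold back into [0,1]; at most a couple of iterations for sigma <= 1
  while (any(bad <- (x < 0 | x > 1))) {
    x[bad & x < 0] <- -x[bad & x < 0]
    bad <- x > 1
    x[bad] <- 2 - x[bad]
  }
  x
}

#' Generate latent reward walks for the two planets
#'
#' Each planet's latent value follows an independent Gaussian random walk
#' (zero-mean increments of SD `sigma`) confined to `[0, 1]` by reflection at
#' the bounds. The latent values are what the display mapping
#' ([payoff_from_value()]) turns into the integer payoffs shown on screen.
#'
#' @param n_trials Number of trials (walk length).
#' @param sigma Per-step standard deviation.
#' @param seed Optional seed; when supplied the walks are a deterministic
#'   function of it. When `NULL`, the current RNG stream is used.
#' @param init Optional length-2 vector of initial values in `[0, 1]`;
#'   defaults to independent draws from `Uniform(init_range)`.
#' @param init_range Range for the default uniform initial values.
#' @return An object of class `reward_walks`: a list with `values` (named
#'   list `P_A`, `P_B` of length-`n_trials` numeric vectors), `sigma`, `seed`.
#' @export
generate_reward_walks <- function(n_trials, sigma = 0.2, seed = NULL,
                                  init = NULL, init_range = c(0.25, 0.75)) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 0) {
    stop_invalid("`n_trials` must be a single non-negative count")
  }
  assert_number(sigma, "sigma", 0)
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) {
    init <- runif(2, init_range[1], init_range[2])
  } else {
    if (length(init) != 2L || any(init < 0 | init > 1)) {
      stop_invalid("`init` must be two values in [0, 1]")
    }
  }
  walk <- function(v0) {
    if (n_trials == 0L) return(numeric(0))
    out <- numeric(n_trials)
    v <- v0
    out[1] <- v
    if (n_trials > 1L) {
      steps <- rnorm(n_trials - 1L, mean = 0, sd = sigma)
      for (t in 2:n_trials) {
        v <- reflect01(v + steps[t - 1L])
        out[t] <- v
      }
    }
    out
  }
  structure(
    list(values = list(P_A = walk(init[1]), P_B = walk(init[2])),
         sigma = sigma, seed = seed),
    class = "reward_walks"
  )
}

#' Display mapping from latent value to integer payoff
#'
#' The unique monotone affine map from the latent `[0, 1]` scale onto the
#' displayed integer range -4..+5, with half-up rounding:
#' `payoff = round(9 v) - 4`.
#'
#' @param v Latent value(s) in `[0, 1]`.
#' @return Integer payoff(s) in `{-4, ..., +5}`.
#' @examples
#' payoff_from_value(c(0, 0.5, 1))  # -4, +1, +5
#' @export
payoff_from_value <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0 | v > 1)) {
    stop_invalid("latent values must lie in [0, 1]")
  }
  as.integer(floor(9 * v + 0.5)) - 4L
}

#' Balanced pair-presentation schedule
#'
#' Within each block, the two ship pairs are shown equally often in a
#' randomised order.
#'
#' @param n_trials Total number of trials; must be divisible by `blocks` and
#'   each block must split evenly between the two pairs.
#' @param blocks Number of blocks.
#' @param seed Optional seed for a deterministic schedule.
#' @return Character vector of pair labels (`"a"`/`"b"`), length `n_trials`.
#' @export
schedule_pairs <- function(n_trials, blocks = 1L, seed = NULL) {
  n_trials <- as.integer(n_trials)
  blocks <- as.integer(blocks)
  if (n_trials %% blocks != 0L) {
    stop_invalid("`n_trials` must be divisible by `blocks`")
  }
  per_block <- n_trials %/% blocks
  if (per_block %% 2L != 0L) {
    stop_invalid("trials per block must be even to balance the two pairs")
  }
  if (!is.null(seed)) set.seed(seed)
  unlist(lapply(seq_len(blocks), function(b) {
    sample(rep(c("a", "b"), each = per_block %/% 2L))
  }), use.names = FALSE)
}
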