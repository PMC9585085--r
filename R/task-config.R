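#' Task configuration for the probabilistic reversal avoidance task
#'
#' Describes the environment a simulated participant faces: 300 trials split
#' into 12 blocks (three each of 20, 24, 26 and 30 trials, shuffled per
#' participant), one response side carrying an 80% probability of avoidance
#' feedback and the other the complementary 20%, with the contingency
#' reversing at every block boundary (every 25 trials on average).
#'
#' @param block_lengths Integer vector of block lengths; the default is the
#'   study design, three blocks each of 20, 24, 26 and 30 trials.
#' @param p_avoid_optimal Probability of avoidance feedback when the
#'   currently optimal side is chosen (default 0.8).
#' @param p_avoid_nonoptimal Probability of avoidance feedback on the other
#'   side; defaults to the complementary probability.
#' @param miss_probability Per-trial probability that the simulated
#'   participant fails to respond in time (trial invalid, no feedback).
#' @param anticipation_probability Per-trial probability that a valid
#'   response is an anticipation (reaction time under 100 ms).
#' @param rt_median_ms,rt_sdlog Lognormal reaction-time parameters used only
#'   to exercise the exclusion filters; reaction times never enter the
#'   learning models.
#'
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$n_trials_total # 300
#' @export
task_config <- function(block_lengths = rep(c(20L, 24L, 26L, 30L), each = 3L),
                        p_avoid_optimal = 0.8,
                        p_avoid_nonoptimal = 1 - p_avoid_optimal,
                        miss_probability = 0,
                        anticipation_probability = 0,
                        rt_median_ms = 450,
                        rt_sdlog = 0.25) {
  if (length(block_lengths) == 0L || any(block_lengths < 1)) {
    stop("`block_lengths` must be a nonempty vector of positive counts",
         call. = FALSE)
  }
  assert_probability(p_avoid_optimal, "p_avoid_optimal")
  assert_probability(p_avoid_nonoptimal, "p_avoid_nonoptimal")
  assert_probability(miss_probability, "miss_probability")
  assert_probability(anticipation_probability, "anticipation_probability")
  structure(
    list(
      block_lengths = as.integer(block_lengths),
      p_avoid_optimal = p_avoid_optimal,
      p_avoid_nonoptimal = p_avoid_nonoptimal,
      n_trials_total = sum(as.integer(block_lengths)),
      miss_probability = miss_probability,
      anticipation_probability = anticipation_probability,
      rt_median_ms = rt_median_ms,
      rt_sdlog = rt_sdlog
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Reversal-task configuration\n")
  cat(sprintf("  %d trials in %d blocks (lengths: %s)\n", x$n_trials_total,
              length(x$block_lengths),
              paste(sort(unique(x$block_lengths)), collapse = "/")))
  cat(sprintf("  P(avoidance | optimal) = %.2f, P(avoidance | non-optimal) = %.2f\n",
              x$p_avoid_optimal, x$p_avoid_nonoptimal))
  invisible(x)
}

#' Agent specification for task simulation
#'
#' @param kind One of `"random"` (coin-flip chooser), `"rl_simple"` or
#'   `"rl_counterfactual"` (delta-rule learners, see [model_params()]),
#'   `"oracle"` (always picks the currently optimal side) or `"fixed_side"`.
#' @param params A [model_params()] object; required for the `rl_*` kinds.
#' @param side For `"fixed_side"`, which side to press (`"left"`/`"right"`).
#'
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(kind = c("random", "rl_simple", "rl_counterfactual",
                                "oracle", "fixed_side"),
                       params = NULL, side = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("rl_simple", "rl_counterfactual")) {
    if (is.null(params) || !inherits(params, "model_params")) {
      stop("RL agents require `params` created by model_params()",
           call. = FALSE)
    }
  } else if (!is.null(params)) {
    stop("`params` is only meaningful for rl_* agents", call. = FALSE)
  }
  if (kind == "fixed_side") {
    if (is.null(side) || !side %in% SIDES) {
      stop("fixed_side agents require `side` = 'left' or 'right'",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, params = params, side = side),
            class = "agent_spec")
}

#' Generative model for subjective scenario ratings
#'
#' After the learning task, participants rate each feedback scenario on a
#' 0-100 visual-analog scale. The generator draws
#' `rating = approach_mean + avoidance_effect * [scenario == avoidance]
#' + subject intercept + residual`, truncated to `[0, 100]`. Default
#' condition means follow the observed grand means (approach scenarios at
#' 25.34, avoidance rated 37.05 points higher).
#'
#' @param approach_mean Mean rating of approach scenarios (0-100 scale).
#' @param avoidance_effect Mean rating increase for avoidance scenarios.
#' @param subject_sd SD of the normal per-subject intercept.
#' @param residual_sd SD of the trial-level normal residual.
#' @param lower,upper Truncation bounds of the rating scale.
#'
#' @return An object of class `rating_model_spec`.
#' @export
rating_model_spec <- function(approach_mean = 25.34,
                              avoidance_effect = 37.05,
                              subject_sd = 8,
                              residual_sd = 10,
                              lower = 0, upper = 100) {
  if (!is.numeric(lower) || !is.numeric(upper) || upper <= lower) {
    stop("invalid truncation bounds: need lower < upper", call. = FALSE)
  }
  if (subject_sd < 0 || residual_sd < 0) {
    stop("standard deviations must be nonnegative", call. = FALSE)
  }
  structure(
    list(approach_mean = approach_mean, avoidance_effect = avoidance_effect,
         subject_sd = subject_sd, residual_sd = residual_sd,
         lower = lower, upper = upper),
    class = "rating_model_spec"
  )
}

#' Default simulated population: two strategy groups
#'
#' Mixture of counterfactual-learner profiles mirroring the fitted group
#' medians: a "non-explicit" majority (alpha = 0.50, alpha_hab = 0.084,
#' beta = 1.50, w = 0.78) and an "explicit" minority (alpha = 0.74,
#' alpha_hab = 0.06, beta = 1.84, w = 0.63), mixed 154:60.
#'
#' @return A list of group specifications, each with `name`, `weight` and
#'   `agent` fields, suitable for [generate_cohort()].
#' @export
default_population <- function() {
  list(
    non_explicit = list(
      name = "non_explicit", weight = 154 / 214,
      agent = agent_spec("rl_counterfactual",
                         params = model_params(alpha = 0.50, alpha_hab = 0.084,
                                               beta = 1.50, w = 0.78))
    ),
    explicit = list(
      name = "explicit", weight = 60 / 214,
      agent = agent_spec("rl_counterfactual",
                         params = model_params(alpha = 0.74, alpha_hab = 0.06,
                                               beta = 1.84, w = 0.63))
    )
  )
}
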