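#' Build a randomized block schedule
#'
#' Shuffles the configured block lengths into a uniformly random order,
#' draws the first block's optimal side uniformly, and alternates the
#' optimal side at every block boundary (the contingency reversal).
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @return An object of class `block_schedule`: a list with `blocks` (one
#'   row per block: `block_index`, `length`, `optimal_side`) and `trials`
#'   (per-trial expansion: `trial_index`, `block_index`,
#'   `within_block_index`, `optimal_side`; all indices 0-based).
#' @examples
#' sch <- build_block_schedule(task_config(), seed = 1)
#' nrow(sch$trials) # 300
#' @export
build_block_schedule <- function(config = task_config(), seed) {
  stopifnot(inherits(config, "task_config"))
  if (length(config$block_lengths) == 0L) {
    stop("configuration error: empty block list", call. = FALSE)
  }
  with_seed(seed, {
    lengths <- sample(config$block_lengths)
    first <- sample(SIDES, 1L)
  })
  n_blocks <- length(lengths)
  sides <- rep(c(first, setdiff(SIDES, first)), length.out = n_blocks)
  blocks <- data.frame(block_index = seq_len(n_blocks) - 1L,
                       length = lengths, optimal_side = sides,
                       stringsAsFactors = FALSE)
  trials <- data.frame(
    trial_index = seq_len(sum(lengths)) - 1L,
    block_index = rep(blocks$block_index, lengths),
    within_block_index = unlist(lapply(lengths, function(l) seq_len(l) - 1L),
                                use.names = FALSE),
    optimal_side = rep(sides, lengths),
    stringsAsFactors = FALSE
  )
  structure(list(blocks = blocks, trials = trials, config = config),
            class = "block_schedule")
}

# Rebuild a schedule skeleton from an observed trial table so agents can be
# replayed on a subject's own sequence of contingencies.
schedule_from_trials <- function(dataset, config = task_config()) {
  trials <- dataset[, c("trial_index", "block_index", "within_block_index",
                        "optimal_side")]
  rownames(trials) <- NULL
  blocks <- unique(trials[, c("block_index", "optimal_side")])
  blocks$length <- as.vector(table(trials$block_index)[as.character(blocks$block_index)])
  structure(list(blocks = blocks[, c("block_index", "length", "optimal_side")],
                 trials = trials, config = config),
            class = "block_schedule")
}

# Draw lognormal reaction times (ms) for valid responses; capped at the
# 1500 ms response deadline. Purely decorative for the models.
draw_rt <- function(n, config) {
  rt <- stats::rlnorm(n, meanlog = log(config$rt_median_ms),
                      sdlog = config$rt_sdlog)
  pmin(round(rt), 1499)
}

#' Simulate one participant on a block schedule
#'
#' Steps the agent through the schedule trial by trial. RL agents choose by
#' softmax on their current decision values and update on the realized
#' feedback; feedback is Bernoulli with probability
#' `p_avoid_optimal` when the currently optimal side was chosen and
#' `p_avoid_nonoptimal` otherwise. Missed trials (probability
#' `config$miss_probability`) are invalid: no choice, no feedback, and no
#' model update. Anticipations (probability
#' `config$anticipation_probability`) are valid responses with a reaction
#' time below 100 ms.
#'
#' @param agent An [agent_spec()].
#' @param schedule A [build_block_schedule()] result.
#' @param config The [task_config()] the schedule was built from.
#' @param seed Integer seed; fully reproducible.
#' @param subject_id Identifier stored in the output.
#' @param strategy_group Optional group label carried through to analyses.
#' @return A trial-level `data.frame` with columns `subject_id`,
#'   `strategy_group`, `trial_index`, `block_index`, `within_block_index`,
#'   `optimal_side`, `choice_side`, `valid`, `rt_ms`, `feedback`
#'   (`"avoidance"`/`"approach"`/`"none"`), `hit`.
#' @export
simulate_participant <- function(agent, schedule, config = schedule$config,
                                 seed, subject_id = "s1",
                                 strategy_group = NA_character_) {
  stopifnot(inherits(agent, "agent_spec"), inherits(schedule, "block_schedule"))
  trials <- schedule$trials
  n <- nrow(trials)
  rl <- agent$kind %in% c("rl_simple", "rl_counterfactual")
  if (rl && is.null(agent$params)) {
    stop("RL agent without parameters", call. = FALSE)
  }
  counterfactual <- identical(agent$kind, "rl_counterfactual")
  p <- agent$params
  with_seed(seed, {
    missed <- if (config$miss_probability > 0) {
      stats::runif(n) < config$miss_probability
    } else rep(FALSE, n)
    anticipated <- if (config$anticipation_probability > 0) {
      stats::runif(n) < config$anticipation_probability
    } else rep(FALSE, n)
    rt <- draw_rt(n, config)
    rt[anticipated] <- round(stats::runif(sum(anticipated), 20, 99))
    choice <- rep(NA_integer_, n)
    feedback <- rep("none", n)
    Q <- c(0.5, 0.5); H <- c(0, 0); D <- c(0.5, 0.5)
    opt <- side_to_int(trials$optimal_side)
    for (t in seq_len(n)) {
      if (missed[t]) next
      ch <- switch(agent$kind,
        random = sample(1:2, 1L),
        oracle = opt[t],
        fixed_side = side_to_int(agent$side),
        # rl_simple / rl_counterfactual
        {
          p_left <- 1 / (1 + exp((D[2L] - D[1L]) * p$beta))
          if (stats::runif(1) < p_left) 1L else 2L
        })
      p_avoid <- if (ch == opt[t]) config$p_avoid_optimal else config$p_avoid_nonoptimal
      r <- as.numeric(stats::runif(1) < p_avoid)
      choice[t] <- ch
      feedback[t] <- if (r == 1) "avoidance" else "approach"
      if (rl) {
        u_ <- 3L - ch
        Q[ch] <- Q[ch] + p$alpha * (r - Q[ch])
        if (counterfactual) Q[u_] <- Q[u_] + p$alpha * ((1 - r) - Q[u_])
        H[ch] <- H[ch] + p$alpha_hab * (1 - H[ch])
        H[u_] <- H[u_] + p$alpha_hab * (0 - H[u_])
        D <- p$w * H + (1 - p$w) * Q
      }
    }
  })
  valid <- !is.na(choice)
  rt[!valid] <- NA_real_
  out <- data.frame(
    subject_id = subject_id,
    strategy_group = strategy_group,
    trial_index = trials$trial_index,
    block_index = trials$block_index,
    within_block_index = trials$within_block_index,
    optimal_side = trials$optimal_side,
    choice_side = ifelse(valid, SIDES[choice], NA_character_),
    valid = valid,
    rt_ms = rt,
    feedback = feedback,
    stringsAsFactors = FALSE
  )
  out$hit <- ifelse(out$valid, out$choice_side == out$optimal_side, NA)
  out
}

#' Generate a synthetic cohort
#'
#' Each subject receives an independently shuffled block schedule, a group
#' label drawn from the population weights, and an independent simulation.
#' The default population mixes the two counterfactual-learner strategy
#' profiles ("non-explicit" and "explicit") in 154:60 proportion.
#'
#' @param n_subjects Number of subjects (0 gives an empty cohort).
#' @param population A list of groups (`name`, `weight`, `agent`), e.g.
#'   [default_population()].
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A stacked trial `data.frame` (one row per subject x trial).
#' @export
generate_cohort <- function(n_subjects, population = default_population(),
                            config = task_config(), seed) {
  if (length(n_subjects) != 1L || is.na(n_subjects) || n_subjects < 0) {
    stop("`n_subjects` must be a nonnegative count", call. = FALSE)
  }
  weights <- vapply(population, function(g) g$weight, numeric(1))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("population weights must sum to 1", call. = FALSE)
  }
  if (n_subjects == 0L) {
    return(data.frame())
  }
  groups <- with_seed(seed, {
    sample(names(population), n_subjects, replace = TRUE, prob = weights)
  })
  ids <- sprintf("s%03d", seq_len(n_subjects))
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    g <- population[[groups[i]]]
    sch <- build_block_schedule(config, seed = derive_seed(seed, 2L * i))
    out[[i]] <- simulate_participant(g$agent, sch, config,
                                     seed = derive_seed(seed, 2L * i + 1L),
                                     subject_id = ids[i],
                                     strategy_group = g$name)
  }
  do.call(rbind, out)
}

#' Draw model parameters from the fitting priors
#'
#' `beta ~ Gamma(shape k = 1.2, scale theta = 5)` (mean k*theta = 6);
#' `alpha`, `alpha_hab`, `w ~ Beta(1.1, 1.1)`.
#'
#' @param seed Integer seed.
#' @param n Number of draws.
#' @return A `data.frame` with `n` rows and columns `alpha`, `alpha_hab`,
#'   `beta`, `w`.
#' @export
sample_parameters <- function(seed, n = 1L) {
  with_seed(seed, {
    data.frame(
      alpha = stats::rbeta(n, 1.1, 1.1),
      alpha_hab = stats::rbeta(n, 1.1, 1.1),
      beta = stats::rgamma(n, shape = 1.2, scale = 5),
      w = stats::rbeta(n, 1.1, 1.1)
    )
  })
}

#' Generate subjective scenario ratings for a cohort
#'
#' Enumerates the 40 scenario instances shown in the evaluation task
#' (10 identity pairs x 2 anger positions x 2 seat positions; the
#' participant sits either far from the angry individual - an avoidance
#' scenario - or next to them - approach, 20 instances of each) and draws
#' one 0-100 rating per instance from the linear model in
#' [rating_model_spec()].
#'
#' @param cohort A trial table from [generate_cohort()] (only subject ids
#'   and group labels are used), or a character vector of subject ids.
#' @param spec A [rating_model_spec()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `subject_id`, `pair_id`,
#'   `anger_position`, `seat_position`, `scenario`
#'   (`"approach"`/`"avoidance"`), `rating` (2 decimals).
#' @export
generate_ratings <- function(cohort, spec = rating_model_spec(), seed) {
  stopifnot(inherits(spec, "rating_model_spec"))
  subjects <- if (is.character(cohort)) unique(cohort) else unique(cohort$subject_id)
  if (length(subjects) == 0L) {
    stop("cohort is empty: no subjects to rate", call. = FALSE)
  }
  grid <- expand.grid(pair_id = 1:10, anger_position = SIDES,
                      seat_position = SIDES, stringsAsFactors = FALSE)
  # Sitting on the same side as the angry individual = approach scenario.
  grid$scenario <- ifelse(grid$anger_position == grid$seat_position,
                          "approach", "avoidance")
  with_seed(seed, {
    out <- vector("list", length(subjects))
    for (i in seq_along(subjects)) {
      intercept <- stats::rnorm(1, 0, spec$subject_sd)
      mu <- spec$approach_mean + intercept +
        spec$avoidance_effect * (grid$scenario == "avoidance")
      r <- mu + stats::rnorm(nrow(grid), 0, spec$residual_sd)
      r <- pmin(pmax(r, spec$lower), spec$upper)
      out[[i]] <- data.frame(subject_id = subjects[i], grid,
                             rating = round(r, 2),
                             stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Degrade a dataset with misses and anticipations
#'
#' Marks a Bernoulli-selected subset of trials invalid (no choice, no
#' feedback) and turns another subset of the remaining valid trials into
#' anticipations (reaction time under 100 ms), preserving trial order.
#' Used to exercise the exclusion filters.
#'
#' @param dataset A single-subject (or stacked) trial table.
#' @param miss_probability,anticipation_probability Per-trial rates.
#' @param seed Integer seed.
#' @return The degraded trial table (same rows, same order).
#' @export
degrade_dataset <- function(dataset, miss_probability = 0,
                            anticipation_probability = 0, seed) {
  assert_probability(miss_probability, "miss_probability")
  assert_probability(anticipation_probability, "anticipation_probability")
  n <- nrow(dataset)
  with_seed(seed, {
    miss <- stats::runif(n) < miss_probability
    antic <- stats::runif(n) < anticipation_probability
    antic_rt <- round(stats::runif(n, 20, 99))
  })
  out <- dataset
  out$valid[miss] <- FALSE
  out$choice_side[miss] <- NA_character_
  out$feedback[miss] <- "none"
  out$rt_ms[miss] <- NA_real_
  out$hit[miss] <- NA
  antic <- antic & out$valid
  out$rt_ms[antic] <- antic_rt[antic]
  out
}
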