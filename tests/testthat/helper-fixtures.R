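# Fixtures and independent oracles used across the suite.

# Naive, deliberately different re-implementation of the two learning
# models' sequence likelihood: named-list state, per-row data.frame access,
# explicit delta-rule transcription. Used as the independent oracle against
# sequence_log_likelihood().
naive_sequence_ll <- function(dataset, params, kind) {
  Q <- list(left = 0.5, right = 0.5)
  H <- list(left = 0, right = 0)
  D <- list(left = 0.5, right = 0.5)
  ll <- 0
  for (i in seq_len(nrow(dataset))) {
    row <- dataset[i, ]
    if (!isTRUE(row$valid)) next
    a <- row$choice_side
    b <- if (a == "left") "right" else "left"
    p <- 1 / (1 + exp((D[[b]] - D[[a]]) * params$beta))
    ll <- ll + max(log(p), log(1e-12))
    R <- if (row$feedback == "avoidance") 1 else 0
    Q[[a]] <- Q[[a]] + params$alpha * (R - Q[[a]])
    if (kind == "counterfactual") {
      Q[[b]] <- Q[[b]] + params$alpha * ((1 - R) - Q[[b]])
    }
    H[[a]] <- H[[a]] + params$alpha_hab * (1 - H[[a]])
    H[[b]] <- H[[b]] + params$alpha_hab * (0 - H[[b]])
    for (s in c("left", "right")) {
      D[[s]] <- params$w * H[[s]] + (1 - params$w) * Q[[s]]
    }
  }
  ll
}

# Hand-built trial table with arbitrary choices/feedback, optionally with
# invalid trials mixed in. Not produced by the simulator, so tests of the
# likelihood do not depend on it.
make_trial_dataset <- function(choices, feedback, valid = NULL,
                               optimal = NULL, subject_id = "t1",
                               rt_ms = 400) {
  n <- length(choices)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(optimal)) optimal <- rep("left", n)
  feedback[!valid] <- "none"
  choices[!valid] <- NA_character_
  data.frame(
    subject_id = subject_id, strategy_group = NA_character_,
    trial_index = seq_len(n) - 1L, block_index = 0L,
    within_block_index = seq_len(n) - 1L,
    optimal_side = optimal, choice_side = choices, valid = valid,
    rt_ms = ifelse(valid, rt_ms, NA_real_), feedback = feedback,
    hit = ifelse(valid, choices == optimal, NA),
    stringsAsFactors = FALSE
  )
}

# Random short dataset for property tests (seeded by the caller).
random_trial_dataset <- function(n = 10L, p_invalid = 0, subject_id = "t1") {
  valid <- runif(n) >= p_invalid
  make_trial_dataset(
    choices = sample(c("left", "right"), n, replace = TRUE),
    feedback = sample(c("avoidance", "approach"), n, replace = TRUE),
    valid = valid,
    optimal = sample(c("left", "right"), n, replace = TRUE),
    subject_id = subject_id
  )
}

random_params <- function() {
  model_params(alpha = runif(1), alpha_hab = runif(1),
               beta = runif(1, 0, 10), w = runif(1))
}
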