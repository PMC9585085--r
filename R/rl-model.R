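#' Learning-model parameters
#'
#' The four free parameters of the delta-rule learners: `alpha`, the
#' learning rate applied to the instrumental value Q; `alpha_hab`, the rate
#' of the habit (choice-kernel) value H, which grows with repetition of a
#' response regardless of outcome; `beta`, the softmax inverse temperature;
#' and `w`, the perseverance weight mixing H and Q into the decision value
#' `D = w * H + (1 - w) * Q`.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param alpha_hab Habit/perseveration rate in `[0, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @param w Perseverance weight in `[0, 1]`.
#'
#' @return An object of class `model_params`.
#' @examples
#' model_params(alpha = 0.5, alpha_hab = 0.1, beta = 2, w = 0.3)
#' @export
model_params <- function(alpha, alpha_hab, beta, w) {
  for (nm in c("alpha", "alpha_hab", "w")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("`beta` must be a nonnegative number", call. = FALSE)
  }
  structure(list(alpha = alpha, alpha_hab = alpha_hab, beta = beta, w = w),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("model_params: alpha = %.3f, alpha_hab = %.3f, beta = %.3f, w = %.3f\n",
              x$alpha, x$alpha_hab, x$beta, x$w))
  invisible(x)
}

#' @export
as.data.frame.model_params <- function(x, ...) {
  data.frame(alpha = x$alpha, alpha_hab = x$alpha_hab, beta = x$beta, w = x$w)
}

# Log-probability floor protecting the optimizer at extreme beta.
.LOG_FLOOR <- log(1e-12)

#' Initial latent state
#'
#' Q values start at 0.5 for both sides (maximal uncertainty about the
#' avoidance probability), H at 0 (no response history), and the decision
#' value D is reported as 0.5 for the first choice; both sides are equal
#' either way, so the first-trial choice probability is 0.5 regardless of
#' `beta` or `w`. After the first feedback D is always recomputed as
#' `w * H + (1 - w) * Q`.
#'
#' @param params A [model_params()] object.
#' @return An object of class `latent_state` with named `Q`, `H`, `D`
#'   vectors (sides `left`, `right`).
#' @export
initial_state <- function(params) {
  stopifnot(inherits(params, "model_params"))
  structure(
    list(Q = c(left = 0.5, right = 0.5),
         H = c(left = 0, right = 0),
         D = c(left = 0.5, right = 0.5)),
    class = "latent_state"
  )
}

#' Softmax choice probability
#'
#' `P(a) = 1 / (1 + exp((D(b) - D(a)) * beta))`, the two-option softmax on
#' the combined decision values. `beta = 0` yields 0.5 for any state.
#'
#' @param state A `latent_state`.
#' @param params A [model_params()] object (only `beta` is used).
#' @param side `"left"` or `"right"`: the option whose probability is
#'   returned.
#' @return The choice probability; `P(left) + P(right) = 1` exactly.
#' @export
action_probability <- function(state, params, side) {
  a <- side_to_int(side)
  b <- 3L - a
  1 / (1 + exp((state$D[[b]] - state$D[[a]]) * params$beta))
}

#' One-trial latent-state update
#'
#' Applies the delta rule to the chosen side's Q value with prediction
#' error `delta_c = R_c - Q(c)` (reward coded 1 for avoidance feedback, 0
#' for approach). Under `kind = "counterfactual"` the unchosen side is
#' updated with the same learning rate against the foregone reward
#' `R_u = 1 - R_c`; under `kind = "simple"` it is left untouched. The habit
#' values of both sides then move, the chosen side toward 1 and the
#' unchosen toward 0 at rate `alpha_hab`, and D is recomputed as
#' `w * H + (1 - w) * Q`.
#'
#' Invalid trials (`feedback = "none"`: no response, so no feedback was
#' shown) leave the state untouched and are flagged in the returned update.
#'
#' @param state A `latent_state`.
#' @param chosen_side `"left"` or `"right"`.
#' @param feedback `"avoidance"`, `"approach"` or `"none"`.
#' @param params A [model_params()] object.
#' @param kind `"simple"` or `"counterfactual"`.
#' @return A list with elements `state` (the updated `latent_state`) and
#'   `update` (rewards, prediction errors and an `updated` flag).
#' @export
update_values <- function(state, chosen_side, feedback, params,
                          kind = c("simple", "counterfactual")) {
  kind <- match.arg(kind)
  if (identical(feedback, "none") || is.na(feedback)) {
    return(list(state = state,
                update = list(updated = FALSE, reward_chosen = NA_real_,
                              reward_unchosen = NA_real_,
                              delta_chosen = NA_real_,
                              delta_unchosen = NA_real_)))
  }
  if (!feedback %in% c("avoidance", "approach")) {
    stop("`feedback` must be 'avoidance', 'approach' or 'none'",
         call. = FALSE)
  }
  c_ <- side_to_int(chosen_side)
  u_ <- 3L - c_
  r_c <- if (feedback == "avoidance") 1 else 0
  r_u <- 1 - r_c
  delta_c <- r_c - state$Q[[c_]]
  delta_u <- if (kind == "counterfactual") r_u - state$Q[[u_]] else NA_real_
  state$Q[[c_]] <- state$Q[[c_]] + params$alpha * delta_c
  if (kind == "counterfactual") {
    state$Q[[u_]] <- state$Q[[u_]] + params$alpha * delta_u
  }
  state$H[[c_]] <- state$H[[c_]] + params$alpha_hab * (1 - state$H[[c_]])
  state$H[[u_]] <- state$H[[u_]] + params$alpha_hab * (0 - state$H[[u_]])
  state$D <- params$w * state$H + (1 - params$w) * state$Q
  list(state = state,
       update = list(updated = TRUE, reward_chosen = r_c,
                     reward_unchosen = r_u, delta_chosen = delta_c,
                     delta_unchosen = delta_u))
}

# Fast inner loop shared by the likelihood and the simulator-facing trace.
# choice: integer 1 (left) / 2 (right); reward: 0/1; valid: logical.
ll_core <- function(choice, reward, valid, alpha, alpha_hab, beta, w,
                    counterfactual, trace = FALSE) {
  n <- length(choice)
  Q <- c(0.5, 0.5)
  H <- c(0, 0)
  D <- c(0.5, 0.5)
  logp <- rep(NA_real_, n)
  ll <- 0
  if (trace) {
    Qtr <- matrix(NA_real_, n, 2L)
    Htr <- matrix(NA_real_, n, 2L)
    Dtr <- matrix(NA_real_, n, 2L)
  }
  for (t in seq_len(n)) {
    if (trace) {
      Qtr[t, ] <- Q
      Htr[t, ] <- H
      Dtr[t, ] <- D
    }
    if (!valid[t]) next
    c_ <- choice[t]
    u_ <- 3L - c_
    p <- 1 / (1 + exp((D[u_] - D[c_]) * beta))
    lp <- log(p)
    if (lp < .LOG_FLOOR) lp <- .LOG_FLOOR
    logp[t] <- lp
    ll <- ll + lp
    r <- reward[t]
    Q[c_] <- Q[c_] + alpha * (r - Q[c_])
    if (counterfactual) Q[u_] <- Q[u_] + alpha * ((1 - r) - Q[u_])
    H[c_] <- H[c_] + alpha_hab * (1 - H[c_])
    H[u_] <- H[u_] + alpha_hab * (0 - H[u_])
    D[1L] <- w * H[1L] + (1 - w) * Q[1L]
    D[2L] <- w * H[2L] + (1 - w) * Q[2L]
  }
  out <- list(log_lik = ll, trial_log_prob = logp, n_valid = sum(valid))
  if (trace) {
    colnames(Qtr) <- colnames(Htr) <- colnames(Dtr) <- SIDES
    out$trace <- list(Q = Qtr, H = Htr, D = Dtr)
  }
  out
}

# Pull integer choice / 0-1 reward / validity vectors out of a trial table.
dataset_arrays <- function(dataset) {
  stopifnot(is.data.frame(dataset))
  valid <- as.logical(dataset$valid) & !is.na(dataset$choice_side)
  choice <- rep(NA_integer_, nrow(dataset))
  choice[valid] <- side_to_int(dataset$choice_side[valid])
  reward <- rep(NA_real_, nrow(dataset))
  reward[valid] <- ifelse(dataset$feedback[valid] == "avoidance", 1, 0)
  list(choice = choice, reward = reward, valid = valid)
}

#' Sequence log-likelihood of a learning model
#'
#' Runs the chosen learner over a subject's ordered trials: the choice
#' probability of each valid trial is taken from the pre-feedback state
#' (softmax on D), the state is then updated with the realized feedback.
#' Invalid trials contribute no likelihood term and trigger no update. Log
#' probabilities are floored at `log(1e-12)` to keep the objective finite
#' at extreme inverse temperatures.
#'
#' @param dataset A single-subject trial table (see [simulate_participant()]
#'   for the schema).
#' @param params A [model_params()] object.
#' @param kind `"simple"` or `"counterfactual"`.
#' @param trace If `TRUE`, also return per-trial Q/H/D values (state before
#'   each trial's choice).
#' @return A list with `log_lik`, `trial_log_prob` (NA on invalid trials),
#'   `n_valid`, and optionally `trace`.
#' @export
sequence_log_likelihood <- function(dataset, params,
                                    kind = c("simple", "counterfactual"),
                                    trace = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "model_params"))
  arr <- dataset_arrays(dataset)
  if (!any(arr$valid)) {
    warning("dataset has no valid trials; log-likelihood is 0")
  }
  ll_core(arr$choice, arr$reward, arr$valid,
          params$alpha, params$alpha_hab, params$beta, params$w,
          counterfactual = (kind == "counterfactual"), trace = trace)
}

#' Log-likelihood of the random-choice baseline
#'
#' The parameter-free baseline chooses left or right with probability 0.5
#' on every valid trial, so its log-likelihood is `n_valid * log(0.5)`
#' (-207.94 for a fully responding 300-trial participant).
#'
#' @param dataset A single-subject trial table.
#' @return The log-likelihood (0 for a dataset with no valid trials).
#' @export
random_log_likelihood <- function(dataset) {
  arr <- dataset_arrays(dataset)
  sum(arr$valid) * log(0.5)
}
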