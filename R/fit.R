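#' Prior specification for MAP fitting
#'
#' The fitting objective weights the negative log-likelihood with prior
#' densities: a gamma prior (shape `k = 1.2`, scale `theta = 5`) on the
#' inverse temperature and Beta(1.1, 1.1) priors on the three unit-interval
#' parameters. `flat = TRUE` drops the prior term entirely (improper
#' uniform), turning the objective into the plain negative log-likelihood.
#'
#' @param beta_shape,beta_scale Gamma prior on `beta`.
#' @param unit_shape1,unit_shape2 Beta prior shapes shared by `alpha`,
#'   `alpha_hab` and `w`.
#' @param flat If `TRUE`, use improper uniform priors.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(beta_shape = 1.2, beta_scale = 5,
                       unit_shape1 = 1.1, unit_shape2 = 1.1,
                       flat = FALSE) {
  stopifnot(beta_shape > 0, beta_scale > 0, unit_shape1 > 0, unit_shape2 > 0)
  structure(list(beta_shape = beta_shape, beta_scale = beta_scale,
                 unit_shape1 = unit_shape1, unit_shape2 = unit_shape2,
                 flat = isTRUE(flat)),
            class = "prior_spec")
}

#' Joint log prior density
#'
#' @param params A [model_params()] object.
#' @param priors A [prior_spec()].
#' @return Sum of log prior densities; `-Inf` outside the support, 0 for
#'   flat priors.
#' @export
log_prior <- function(params, priors = prior_spec()) {
  stopifnot(inherits(priors, "prior_spec"))
  if (priors$flat) return(0)
  stats::dgamma(params$beta, shape = priors$beta_shape,
                scale = priors$beta_scale, log = TRUE) +
    stats::dbeta(params$alpha, priors$unit_shape1, priors$unit_shape2, log = TRUE) +
    stats::dbeta(params$alpha_hab, priors$unit_shape1, priors$unit_shape2, log = TRUE) +
    stats::dbeta(params$w, priors$unit_shape1, priors$unit_shape2, log = TRUE)
}

#' Prior-weighted negative log-likelihood (MAP objective)
#'
#' `penalized_nll = -log_lik(params) - log_prior(params)`. Parameters
#' outside their supports (including the Beta(1.1, 1.1) endpoints, where
#' the density vanishes) give `+Inf`, so the optimizer rejects them.
#'
#' @param params A [model_params()] object.
#' @param dataset A single-subject trial table.
#' @param kind `"simple"` or `"counterfactual"`.
#' @param priors A [prior_spec()].
#' @return The objective value.
#' @export
penalized_nll <- function(params, dataset, kind = c("simple", "counterfactual"),
                          priors = prior_spec()) {
  kind <- match.arg(kind)
  lp <- log_prior(params, priors)
  if (!is.finite(lp)) return(Inf)
  ll <- sequence_log_likelihood(dataset, params, kind)$log_lik
  -ll - lp
}

#' Fitting options
#'
#' @param eps Inset from the boundaries of the unit-interval parameters
#'   (and lower bound of `beta`) keeping the beta log-densities finite.
#' @param beta_max Upper bound on the inverse temperature; the gamma prior
#'   places negligible mass above 30 and larger values yield degenerate
#'   step-function likelihoods.
#' @param restarts Number of additional prior-drawn starting points (0
#'   reproduces the single fixed start `alpha = alpha_hab = w = 0.5`,
#'   `beta = 1`).
#' @param factr `optim` L-BFGS-B convergence tolerance factor.
#' @param seed Seed used to draw restart points.
#' @return An object of class `fit_options`.
#' @export
fit_options <- function(eps = 1e-6, beta_max = 30, restarts = 0L,
                        factr = 1e7, seed = 1L) {
  structure(list(eps = eps, beta_max = beta_max,
                 restarts = as.integer(restarts), factr = factr,
                 seed = as.integer(seed)),
            class = "fit_options")
}

# Parameter vector order used throughout the optimizer interface.
PAR_NAMES <- c("alpha", "alpha_hab", "beta", "w")

vec_to_params <- function(x) {
  model_params(alpha = x[1L], alpha_hab = x[2L], beta = x[3L], w = x[4L])
}

#' Fit one subject by MAP
#'
#' Bounded local minimization (L-BFGS-B, finite-difference gradients) of
#' [penalized_nll()] from the fixed starting point
#' `(alpha, alpha_hab, w) = 0.5`, `beta = 1`, within the box
#' `[eps, 1 - eps]^3 x [eps, beta_max]`. Optional multistart adds
#' prior-drawn starting points and keeps the best optimum.
#'
#' @param dataset A single-subject trial table with at least one valid
#'   trial.
#' @param kind `"simple"` or `"counterfactual"`.
#' @param priors A [prior_spec()].
#' @param options A [fit_options()].
#' @return An object of class `fit_result`: fitted [model_params()],
#'   `log_lik`, `penalized_objective`, `n_valid`, `converged`, `restarts`,
#'   `subject_id`, `kind`.
#' @export
fit_subject <- function(dataset, kind = c("simple", "counterfactual"),
                        priors = prior_spec(), options = fit_options()) {
  kind <- match.arg(kind)
  arr <- dataset_arrays(dataset)
  if (!any(arr$valid)) {
    stop("cannot fit a dataset with no valid trials", call. = FALSE)
  }
  cf <- (kind == "counterfactual")
  flat <- priors$flat
  objective <- function(x) {
    nll <- -ll_core(arr$choice, arr$reward, arr$valid,
                    x[1L], x[2L], x[3L], x[4L], cf)$log_lik
    if (flat) return(nll)
    lp <- stats::dgamma(x[3L], shape = priors$beta_shape,
                        scale = priors$beta_scale, log = TRUE) +
      stats::dbeta(x[1L], priors$unit_shape1, priors$unit_shape2, log = TRUE) +
      stats::dbeta(x[2L], priors$unit_shape1, priors$unit_shape2, log = TRUE) +
      stats::dbeta(x[4L], priors$unit_shape1, priors$unit_shape2, log = TRUE)
    if (!is.finite(lp)) return(.Machine$double.xmax)
    nll - lp
  }
  eps <- options$eps
  lower <- c(eps, eps, eps, eps)
  upper <- c(1 - eps, 1 - eps, options$beta_max, 1 - eps)
  starts <- list(c(0.5, 0.5, 1, 0.5))
  if (options$restarts > 0L) {
    extra <- sample_parameters(options$seed, n = options$restarts)
    extra$beta <- pmin(pmax(extra$beta, eps), options$beta_max)
    for (i in seq_len(options$restarts)) {
      starts[[i + 1L]] <- pmin(pmax(
        c(extra$alpha[i], extra$alpha_hab[i], extra$beta[i], extra$w[i]),
        lower), upper)
    }
  }
  best <- NULL
  converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = options$factr, maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- (fit$convergence == 0L)
    }
  }
  if (is.null(best)) {
    stop("optimization failed from every starting point", call. = FALSE)
  }
  params <- vec_to_params(best$par)
  ll <- sequence_log_likelihood(dataset, params, kind)$log_lik
  structure(
    list(subject_id = dataset$subject_id[1] %||% NA_character_,
         kind = kind, params = params, log_lik = ll,
         penalized_objective = best$value, n_valid = sum(arr$valid),
         converged = converged, restarts = options$restarts,
         seed = options$seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result [%s, %s]: LL = %.3f, objective = %.3f, %s\n",
              x$subject_id, x$kind, x$log_lik, x$penalized_objective,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' @export
as.data.frame.fit_result <- function(x, ...) {
  data.frame(subject_id = x$subject_id, model = x$kind,
             alpha = x$params$alpha, alpha_hab = x$params$alpha_hab,
             beta = x$params$beta, w = x$params$w,
             ll = x$log_lik, penalized_nll = x$penalized_objective,
             n_valid = x$n_valid, converged = x$converged,
             restarts = x$restarts, seed = x$seed,
             error = NA_character_, stringsAsFactors = FALSE)
}

fit_failure_row <- function(subject_id, model, msg) {
  data.frame(subject_id = subject_id, model = model,
             alpha = NA_real_, alpha_hab = NA_real_, beta = NA_real_,
             w = NA_real_, ll = NA_real_, penalized_nll = NA_real_,
             n_valid = NA_integer_, converged = FALSE,
             restarts = NA_integer_, seed = NA_integer_,
             error = msg, stringsAsFactors = FALSE)
}

#' Fit every subject of a cohort under one or more models
#'
#' Runs [fit_subject()] per subject x model and adds one row per subject
#' for the parameter-free random baseline ([random_log_likelihood()]).
#' Per-subject failures become flagged rows (message in `error`) rather
#' than aborting the cohort.
#'
#' @param cohort A stacked trial table.
#' @param kinds Models to fit, subset of `c("simple", "counterfactual")`.
#' @param priors A [prior_spec()].
#' @param options A [fit_options()].
#' @param include_random Add random-baseline rows (default `TRUE`).
#' @return A fit table `data.frame`: `subject_id`, `model`, parameters,
#'   `ll`, `penalized_nll`, `n_valid`, `converged`, `restarts`, `seed`,
#'   `error`.
#' @export
fit_cohort <- function(cohort, kinds = c("simple", "counterfactual"),
                       priors = prior_spec(), options = fit_options(),
                       include_random = TRUE) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  kinds <- match.arg(kinds, several.ok = TRUE)
  subjects <- unique(cohort$subject_id)
  rows <- list()
  for (sid in subjects) {
    ds <- cohort[cohort$subject_id == sid, , drop = FALSE]
    for (k in kinds) {
      rows[[length(rows) + 1L]] <- tryCatch(
        as.data.frame(fit_subject(ds, k, priors, options)),
        error = function(e) fit_failure_row(sid, k, conditionMessage(e)))
    }
    if (include_random) {
      ll0 <- random_log_likelihood(ds)
      row <- fit_failure_row(sid, "random", NA_character_)
      row$ll <- ll0
      row$penalized_nll <- -ll0
      row$n_valid <- sum(ds$valid)
      row$converged <- TRUE
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior-predictive simulation for one subject
#'
#' Replays the fitted agent on the subject's own block schedule `n_reps`
#' times (default 100, averaged) with fresh Bernoulli feedback, and
#' averages the per-trial choices. The `"conditional"` variant instead
#' conditions on the observed choices and feedback and returns the model's
#' per-trial probability of choosing the optimal side (deterministic, no
#' replication).
#'
#' @param dataset The subject's observed trial table (provides the
#'   schedule).
#' @param params Fitted [model_params()].
#' @param kind `"simple"` or `"counterfactual"`.
#' @param n_reps Number of generative replays (>= 1).
#' @param seed Integer seed.
#' @param config A [task_config()] for the feedback law.
#' @param type `"generative"` (default) or `"conditional"`.
#' @return A list with `per_trial` (a `data.frame`: `trial_index`,
#'   `mean_hit`, `mean_choice_right`) and `mean_hit` (scalar simulated hit
#'   proportion).
#' @export
posterior_predictive <- function(dataset, params,
                                 kind = c("simple", "counterfactual"),
                                 n_reps = 100L, seed = 1L,
                                 config = task_config(),
                                 type = c("generative", "conditional")) {
  kind <- match.arg(kind)
  type <- match.arg(type)
  stopifnot(inherits(params, "model_params"))
  if (type == "conditional") {
    res <- sequence_log_likelihood(dataset, params, kind, trace = TRUE)
    D <- res$trace$D
    opt <- side_to_int(dataset$optimal_side)
    p_opt <- 1 / (1 + exp((D[cbind(seq_len(nrow(D)), 3L - opt)] -
                             D[cbind(seq_len(nrow(D)), opt)]) * params$beta))
    per_trial <- data.frame(trial_index = dataset$trial_index,
                            mean_hit = p_opt,
                            mean_choice_right = ifelse(opt == 2L, p_opt, 1 - p_opt))
    return(list(per_trial = per_trial, mean_hit = mean(p_opt)))
  }
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  sch <- schedule_from_trials(dataset, config)
  spec <- agent_spec(if (kind == "simple") "rl_simple" else "rl_counterfactual",
                     params = params)
  hit_sum <- numeric(nrow(dataset))
  right_sum <- numeric(nrow(dataset))
  for (r in seq_len(n_reps)) {
    sim <- simulate_participant(spec, sch, config,
                                seed = derive_seed(seed, r),
                                subject_id = dataset$subject_id[1] %||% "s1")
    hit_sum <- hit_sum + as.numeric(sim$hit)
    right_sum <- right_sum + as.numeric(sim$choice_side == "right")
  }
  per_trial <- data.frame(trial_index = dataset$trial_index,
                          mean_hit = hit_sum / n_reps,
                          mean_choice_right = right_sum / n_reps)
  list(per_trial = per_trial, mean_hit = mean(per_trial$mean_hit))
}
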