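test_that("MAP objective combines likelihood and prior terms", {
  set.seed(91)
  ds <- random_trial_dataset(n = 20L)
  p <- model_params(alpha = 0.4, alpha_hab = 0.2, beta = 6, w = 0.3)

  # flat priors: objective is the plain negative log-likelihood
  nll <- -sequence_log_likelihood(ds, p, "simple")$log_lik
  expect_equal(penalized_nll(p, ds, "simple", prior_spec(flat = TRUE)), nll)

  # independent gamma/beta log-density evaluation
  k <- 1.2; theta <- 5
  lg <- (k - 1) * log(6) - 6 / theta - k * log(theta) - lgamma(k)
  lb <- function(x) {
    (1.1 - 1) * log(x) + (1.1 - 1) * log(1 - x) - lbeta(1.1, 1.1)
  }
  expect_equal(log_prior(p), lg + lb(0.4) + lb(0.2) + lb(0.3),
               tolerance = 1e-10)
  expect_equal(penalized_nll(p, ds, "simple"),
               nll - (lg + lb(0.4) + lb(0.2) + lb(0.3)), tolerance = 1e-10)

  # Beta(1.1, 1.1) density vanishes at the endpoints: rejected
  p0 <- model_params(alpha = 0, alpha_hab = 0.2, beta = 6, w = 0.3)
  expect_equal(penalized_nll(p0, ds, "simple"), Inf)
})

test_that("fit_subject respects the descent contract and the box", {
  cfg <- task_config()
  sch <- build_block_schedule(cfg, seed = 101)
  ds <- simulate_participant(
    agent_spec("rl_counterfactual", params = model_params(0.6, 0.1, 5, 0.3)),
    sch, cfg, seed = 102)
  for (kind in c("simple", "counterfactual")) {
    fit <- fit_subject(ds, kind)
    start <- model_params(0.5, 0.5, 1, 0.5)
    expect_lte(fit$penalized_objective, penalized_nll(start, ds, kind))
    expect_true(fit$params$alpha > 0 && fit$params$alpha < 1)
    expect_true(fit$params$beta > 0 && fit$params$beta <= 30)
    # stored objective reproduces penalized_nll at the fitted params
    expect_equal(penalized_nll(fit$params, ds, kind),
                 fit$penalized_objective, tolerance = 1e-8)
  }
  ds$valid <- FALSE
  ds$choice_side <- NA_character_
  expect_error(fit_subject(ds, "simple"), "no valid")
})

test_that("recovered learning rates are accurate at strong beta", {
  # 12 subjects at fixed generating parameters: mean absolute error of the
  # recovered learning rate stays well under 0.2
  cfg <- task_config()
  errs <- vapply(1:12, function(i) {
    sch <- build_block_schedule(cfg, seed = 1100 + i)
    ds <- simulate_participant(
      agent_spec("rl_counterfactual", params = model_params(0.6, 0.1, 5, 0.3)),
      sch, cfg, seed = 1200 + i)
    abs(fit_subject(ds, "counterfactual")$params$alpha - 0.6)
  }, numeric(1))
  expect_lt(mean(errs), 0.2)
})

test_that("fit_cohort produces one row per subject x model plus baselines", {
  co <- generate_cohort(3, seed = 111)
  fits <- fit_cohort(co)
  expect_equal(nrow(fits), 9L)
  expect_equal(sum(fits$model == "random"), 3L)
  expect_equal(fits$ll[fits$model == "random"],
               rep(300 * log(0.5), 3))
  expect_identical(fit_cohort(co), fits)

  # per-subject failure is a flagged row, not an abort
  bad <- co
  sel <- bad$subject_id == bad$subject_id[1]
  bad$valid[sel] <- FALSE
  bad$choice_side[sel] <- NA_character_
  bad$feedback[sel] <- "none"
  fits2 <- suppressWarnings(fit_cohort(bad))
  expect_equal(nrow(fits2), 9L)
  expect_true(any(!is.na(fits2$error)))
})

test_that("a near-empty dataset is dominated by the prior", {
  ds <- make_trial_dataset("left", "avoidance")
  fit <- fit_subject(ds, "simple")
  # Gamma(1.2, 5) has its mode at (k-1)*theta = 1; one trial cannot push
  # beta to either boundary
  expect_gt(fit$params$beta, 0.05)
  expect_lt(fit$params$beta, 10)
})

test_that("likelihood prefix: duplicating trials leaves the first copy's terms unchanged", {
  set.seed(121)
  ds <- random_trial_dataset(n = 30L)
  dup <- rbind(ds, transform(ds, trial_index = trial_index + 30L))
  p <- random_params()
  for (kind in c("simple", "counterfactual")) {
    single <- sequence_log_likelihood(ds, p, kind)$trial_log_prob
    double <- sequence_log_likelihood(dup, p, kind)$trial_log_prob
    expect_identical(double[1:30], single)
  }
})

test_that("posterior predictive averages indicators and tracks real hits", {
  cfg <- task_config()
  p <- model_params(0.7, 0.1, 5, 0.2)
  sch <- build_block_schedule(cfg, seed = 131)
  ds <- simulate_participant(agent_spec("rl_counterfactual", params = p),
                             sch, cfg, seed = 132)
  expect_equal(formals(posterior_predictive)$n_reps, 100L)
  pp <- posterior_predictive(ds, p, "counterfactual", n_reps = 10, seed = 133)
  expect_true(all(pp$per_trial$mean_hit >= 0 & pp$per_trial$mean_hit <= 1))
  expect_error(posterior_predictive(ds, p, "counterfactual", n_reps = 0),
               "n_reps")

  # heterogeneous well-learning cohort: per-subject simulated hit
  # proportions rank-correlate with the real ones (between-subject spread
  # comes from the parameters; a parameter-homogeneous cohort has no
  # subject-level signal to recover)
  set.seed(1999)
  real <- sim <- numeric(100)
  for (i in 1:100) {
    pi <- model_params(alpha = runif(1, 0.2, 1),
                       alpha_hab = runif(1, 0.02, 0.2),
                       beta = runif(1, 1, 10), w = runif(1, 0, 0.7))
    sch <- build_block_schedule(cfg, seed = 2000 + i)
    dsi <- simulate_participant(agent_spec("rl_counterfactual", params = pi),
                                sch, cfg, seed = 3000 + i)
    real[i] <- mean(dsi$hit)
    sim[i] <- posterior_predictive(dsi, pi, "counterfactual", n_reps = 50,
                                   seed = 4000 + i)$mean_hit
  }
  expect_gt(cor(real, sim, method = "spearman"), 0.7)

  # conditional variant is deterministic and bounded
  cond <- posterior_predictive(ds, p, "counterfactual", type = "conditional")
  expect_true(all(cond$per_trial$mean_hit > 0 & cond$per_trial$mean_hit < 1))
  expect_identical(cond,
                   posterior_predictive(ds, p, "counterfactual",
                                        type = "conditional"))
})

test_that("recovery report shape and the permutation null", {
  truth <- sample_parameters(seed = 141, n = 8)
  rep <- parameter_recovery_study(truth, "counterfactual", seed = 142)
  expect_equal(nrow(rep$table), 8L)
  expect_true(all(abs(rep$correlations) <= 1, na.rm = TRUE))
  # shuffled-label control: recovered alpha against permuted truth ~ 0
  set.seed(143)
  perm <- replicate(200, cor(rep$table$fit_alpha,
                             sample(rep$table$true_alpha),
                             method = "spearman"))
  expect_lt(abs(mean(perm)), 0.15)
})
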