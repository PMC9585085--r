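test_that("hit scoring and the binomial test against chance", {
  cfg <- task_config()
  sch <- build_block_schedule(cfg, seed = 151)
  oracle <- simulate_participant(agent_spec("oracle"), sch, cfg, seed = 152)
  expect_equal(score_hits(oracle)$proportion, 1.0)
  expect_lt(per_subject_binomial_test(oracle), 1e-80)

  # an always-wrong dataset scores zero
  wrong <- oracle
  wrong$choice_side <- ifelse(wrong$optimal_side == "left", "right", "left")
  wrong$hit <- FALSE
  expect_equal(score_hits(wrong)$proportion, 0.0)

  # exactly half hits: two-sided exact test is flat
  half <- make_trial_dataset(rep(c("left", "right"), 150),
                             rep("avoidance", 300),
                             optimal = rep("left", 300))
  expect_equal(per_subject_binomial_test(half), 1.0)

  empty <- make_trial_dataset("left", "avoidance", valid = FALSE)
  expect_warning(s <- score_hits(empty), "no valid")
  expect_true(is.na(s$proportion))
})

test_that("random choices hit at chance over pooled trials", {
  cfg <- task_config()
  hits <- unlist(lapply(1:34, function(i) {
    sch <- build_block_schedule(cfg, seed = 160 + i)
    simulate_participant(agent_spec("random"), sch, cfg, seed = 190 + i)$hit
  }))
  expect_gte(length(hits), 10000L)
  expect_lt(abs(mean(hits) - 0.5), 3 * sqrt(0.25 / length(hits)))
})

test_that("hyperbolic predictor has the stated anchor values", {
  expect_equal(hyp_trial(0), 0)
  expect_equal(hyp_trial(1), 0.5)
  expect_equal(hyp_trial(19), 0.95)
  expect_true(all(diff(hyp_trial(0:50)) > 0))
})

test_that("learning curve rises for learners and is flat at 1 for oracles", {
  cfg <- task_config()
  oracle_cohort <- do.call(rbind, lapply(1:5, function(i) {
    sch <- build_block_schedule(cfg, seed = 200 + i)
    simulate_participant(agent_spec("oracle"), sch, cfg, seed = 210 + i,
                         subject_id = sprintf("o%d", i))
  }))
  lc <- learning_curve(oracle_cohort)
  expect_equal(lc$curve$mean_hit, rep(1, 20))
  expect_true(lc$fit$degenerate)

  learner <- generate_cohort(
    30, population = list(g = list(name = "explicit", weight = 1,
                                   agent = default_population()$explicit$agent)),
    seed = 221)
  lc2 <- learning_curve(learner)
  expect_equal(nrow(lc2$curve), 20L)
  expect_gt(lc2$slope, 0)
})

test_that("repetition rates condition on previous feedback", {
  cfg <- task_config()
  sch <- build_block_schedule(cfg, seed = 231)
  fixed <- simulate_participant(agent_spec("fixed_side", side = "right"),
                                sch, cfg, seed = 232)
  rt <- repetition_table(fixed)
  expect_equal(rt$rep_after_avoidance, 1.0)
  expect_equal(rt$rep_after_approach, 1.0)
  # pair conservation
  expect_equal(sum(rt$pairs$prev_feedback == "avoidance") +
                 sum(rt$pairs$prev_feedback == "approach"), rt$n_pairs)
  expect_equal(rt$n_pairs, 299L)

  rnd <- do.call(rbind, lapply(1:20, function(i) {
    simulate_participant(agent_spec("random"),
                         build_block_schedule(cfg, seed = 240 + i), cfg,
                         seed = 260 + i, subject_id = sprintf("r%d", i))
  }))
  rr <- repetition_table(rnd)
  expect_lt(abs(rr$rep_after_avoidance - 0.5), 0.03)
  expect_lt(abs(rr$rep_after_approach - 0.5), 0.03)

  # deterministic feedback-driven limit: stay after avoidance, shift after
  # approach
  det <- simulate_participant(
    agent_spec("rl_counterfactual", params = model_params(1, 0, 30, 0)),
    sch, cfg, seed = 233)
  dt <- repetition_table(det)
  expect_gt(dt$win_stay, 0.95)
  expect_gt(dt$lose_shift, 0.95)

  two <- make_trial_dataset(c("left", NA), c("avoidance", "none"),
                            valid = c(TRUE, FALSE))
  expect_warning(repetition_table(two), "no eligible")
})

test_that("repetition by subjective value recovers a positive slope", {
  # agents that repeat with probability equal to the previous scenario's
  # subjective value; subjects differ in their value profiles
  set.seed(271)
  n_sub <- 25; n_tr <- 120
  cohort <- list(); ratings <- list()
  for (s in 1:n_sub) {
    v <- c(approach = runif(1, 0.05, 0.45), avoidance = runif(1, 0.55, 0.95))
    ch <- character(n_tr); fb <- character(n_tr)
    ch[1] <- "left"
    fb[1] <- sample(c("avoidance", "approach"), 1)
    for (t in 2:n_tr) {
      ch[t] <- if (runif(1) < v[[fb[t - 1]]]) ch[t - 1] else
        setdiff(c("left", "right"), ch[t - 1])
      fb[t] <- sample(c("avoidance", "approach"), 1)
    }
    cohort[[s]] <- make_trial_dataset(ch, fb, subject_id = sprintf("v%02d", s))
    ratings[[s]] <- data.frame(subject_id = sprintf("v%02d", s),
                               pair_id = rep(1:10, 2),
                               scenario = rep(c("approach", "avoidance"), each = 10),
                               rating = 100 * c(rep(v[["approach"]], 10),
                                                rep(v[["avoidance"]], 10)))
  }
  cohort <- do.call(rbind, cohort)
  ratings <- do.call(rbind, ratings)
  res <- repetition_by_value(cohort, ratings)
  expect_gt(res$slope, 0)
  # rescaling: ratings are divided by 100
  expect_true(all(res$pairs$value >= 0 & res$pairs$value <= 1))
  r37 <- data.frame(subject_id = "w1", pair_id = rep(1:10, 2),
                    scenario = rep(c("approach", "avoidance"), each = 10),
                    rating = rep(c(37.05, 80), each = 10))
  w1 <- make_trial_dataset(c("left", "right", "left"),
                           c("approach", "approach", "approach"),
                           subject_id = "w1")
  res37 <- suppressWarnings(repetition_by_value(w1, r37))
  expect_equal(unique(res37$pairs$value), 0.3705)

  # missing ratings are a named error
  expect_error(repetition_by_value(cohort, ratings[ratings$subject_id != "v01", ]),
               "v01")

  # constant values flag a degenerate fit
  flat <- ratings
  flat$rating <- 50
  expect_warning(res2 <- repetition_by_value(cohort, flat), "constant")
  expect_true(is.na(res2$slope))
})

test_that("exclusion criteria flag low responders and anticipators", {
  cfg <- task_config()
  sch <- build_block_schedule(cfg, seed = 281)
  clean <- simulate_participant(agent_spec("random"), sch, cfg, seed = 282,
                                subject_id = "clean")
  lazy <- degrade_dataset(clean, miss_probability = 0.15, seed = 283)
  lazy$subject_id <- "lazy"
  jumpy <- degrade_dataset(clean, anticipation_probability = 0.25, seed = 284)
  jumpy$subject_id <- "jumpy"
  rep <- apply_exclusions(rbind(clean, lazy, jumpy))
  expect_true(rep$retained[rep$subject_id == "clean"])
  expect_match(rep$reasons[rep$subject_id == "lazy"], "low_response_rate")
  expect_match(rep$reasons[rep$subject_id == "jumpy"], "excess_anticipations")
  # boundary: 85% response rate is excluded, 16% anticipation share is too
  expect_lt(rep$response_rate[rep$subject_id == "lazy"], 0.90)
  expect_gt(rep$anticipation_share[rep$subject_id == "jumpy"], 0.15)
  # idempotence on the retained subset
  kept <- rbind(clean, lazy, jumpy)
  kept <- kept[kept$subject_id %in% rep$subject_id[rep$retained], ]
  expect_identical(apply_exclusions(kept), apply_exclusions(kept))
})

test_that("rating summaries use grand means of per-subject means", {
  one <- data.frame(subject_id = "a", pair_id = rep(1:10, 2),
                    scenario = rep(c("approach", "avoidance"), each = 10),
                    rating = rep(c(20, 70), each = 10))
  s <- rating_summary(one)
  expect_equal(s$approach_mean, 20)
  expect_equal(s$difference, 50)
  expect_error(rating_summary(one[0, ]), "empty")
})

test_that("parameter-covariate correlations with BH adjustment", {
  # self-correlation is exactly 1
  ft <- data.frame(subject_id = sprintf("s%03d", 1:40), model = "counterfactual",
                   alpha = runif(40), alpha_hab = runif(40), beta = runif(40, 0, 10),
                   w = runif(40), ll = 0, penalized_nll = 0, n_valid = 300,
                   converged = TRUE, restarts = 0, seed = 1,
                   error = NA_character_)
  cov <- data.frame(subject_id = ft$subject_id, self = ft$alpha)
  res <- correlate_parameters(ft, cov)
  expect_equal(res$rho[res$parameter == "alpha" & res$covariate == "self"], 1)

  # independent covariates: ~5% raw positives, none surviving BH
  set.seed(291)
  ft$alpha <- runif(40); ft$w <- runif(40)
  cov <- data.frame(subject_id = ft$subject_id,
                    q1 = rnorm(40), q2 = rnorm(40), q3 = rnorm(40),
                    q4 = rnorm(40), q5 = rnorm(40))
  res <- correlate_parameters(ft, cov)
  expect_equal(nrow(res), 20L)
  expect_lt(mean(res$p < 0.05), 0.25)
  expect_equal(sum(res$p_adj < 0.05), 0L)

  # constant covariates are flagged, not propagated
  cov$flatline <- 1
  res <- correlate_parameters(ft, cov)
  expect_true(all(res$flag[res$covariate == "flatline"] == "constant"))

  # hand 5-point table matches the textbook rank formula 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(3, 1, 4, 2, 5); y <- c(2, 1, 5, 3, 4)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (5 * 24)
  ft5 <- ft[1:5, ]; ft5$alpha <- x
  res5 <- correlate_parameters(ft5, data.frame(subject_id = ft5$subject_id, y = y))
  expect_equal(res5$rho[res5$parameter == "alpha"], rho_hand)
})
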