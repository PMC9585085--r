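#' Hyperbolic trial predictor
#'
#' The saturating transform `y = 1 - 1/(1 + x)` of the within-block trial
#' number used as the predictor of learning curves; `hyp_trial(0) = 0`,
#' `hyp_trial(19) = 0.95`, bounded above by 1.
#'
#' @param x Within-block trial index (0-based).
#' @return Transformed values.
#' @export
hyp_trial <- function(x) 1 - 1 / (1 + x)

#' Score hits
#'
#' A hit is a valid choice of the side currently carrying the higher
#' avoidance probability.
#'
#' @param dataset A single-subject trial table.
#' @return A list with `hits` (per-trial logical, NA when invalid),
#'   `proportion` (over valid trials; NA and flagged when none), `n_valid`.
#' @export
score_hits <- function(dataset) {
  hits <- ifelse(dataset$valid, dataset$choice_side == dataset$optimal_side, NA)
  n_valid <- sum(dataset$valid)
  if (n_valid == 0L) {
    warning("no valid trials: hit proportion undefined")
    return(list(hits = hits, proportion = NA_real_, n_valid = 0L))
  }
  list(hits = hits, proportion = mean(hits, na.rm = TRUE), n_valid = n_valid)
}

#' Exact binomial test of hits against chance
#'
#' @param dataset A single-subject trial table with at least one valid
#'   trial.
#' @return Two-sided p-value of the exact binomial test of the hit count
#'   against 0.5.
#' @export
per_subject_binomial_test <- function(dataset) {
  s <- score_hits(dataset)
  if (s$n_valid == 0L) stop("no valid trials", call. = FALSE)
  stats::binom.test(sum(s$hits, na.rm = TRUE), s$n_valid, p = 0.5)$p.value
}

# Consecutive-valid-trial repetition pairs for one subject.
repetition_pairs <- function(dataset) {
  ds <- dataset[order(dataset$trial_index), , drop = FALSE]
  n <- nrow(ds)
  if (n < 2L) return(NULL)
  prev <- seq_len(n - 1L)
  cur <- prev + 1L
  ok <- ds$valid[prev] & ds$valid[cur]
  if (!any(ok)) return(NULL)
  data.frame(
    subject_id = ds$subject_id[cur][ok],
    trial_index = ds$trial_index[cur][ok],
    prev_feedback = ds$feedback[prev][ok],
    repetition = ds$choice_side[cur][ok] == ds$choice_side[prev][ok],
    stringsAsFactors = FALSE
  )
}

#' Repetition by previous feedback (win-stay / lose-shift)
#'
#' A repetition at trial t means the same side was chosen as at t-1; pairs
#' with an invalid trial on either end are dropped. Win-stay is the
#' repetition rate after avoidance feedback, lose-shift is one minus the
#' repetition rate after approach feedback.
#'
#' @param dataset A single-subject (or stacked) trial table.
#' @return A list with `pairs` (per-pair table), `rep_after_avoidance`,
#'   `rep_after_approach`, `win_stay`, `lose_shift`, `n_pairs`.
#' @export
repetition_table <- function(dataset) {
  parts <- split(dataset, dataset$subject_id)
  pairs <- do.call(rbind, lapply(parts, repetition_pairs))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    warning("no eligible consecutive valid trial pairs")
    return(list(pairs = NULL, rep_after_avoidance = NA_real_,
                rep_after_approach = NA_real_, win_stay = NA_real_,
                lose_shift = NA_real_, n_pairs = 0L))
  }
  rownames(pairs) <- NULL
  ra <- mean(pairs$repetition[pairs$prev_feedback == "avoidance"])
  rp <- mean(pairs$repetition[pairs$prev_feedback == "approach"])
  list(pairs = pairs, rep_after_avoidance = ra, rep_after_approach = rp,
       win_stay = ra, lose_shift = 1 - rp, n_pairs = nrow(pairs))
}

#' Per-subject behavioral summary
#'
#' @param cohort A stacked trial table.
#' @return A `data.frame` with one row per subject: `subject_id`,
#'   `strategy_group`, `n_valid`, `hit_proportion`, `binomial_p`,
#'   `rep_after_avoidance`, `rep_after_approach`, `win_stay`, `lose_shift`.
#' @export
behavior_summary <- function(cohort) {
  parts <- split(cohort, cohort$subject_id)
  rows <- lapply(parts, function(ds) {
    s <- score_hits(ds)
    rt <- suppressWarnings(repetition_table(ds))
    data.frame(
      subject_id = ds$subject_id[1],
      strategy_group = ds$strategy_group[1] %||% NA_character_,
      n_valid = s$n_valid,
      hit_proportion = s$proportion,
      binomial_p = if (s$n_valid > 0L) per_subject_binomial_test(ds) else NA_real_,
      rep_after_avoidance = rt$rep_after_avoidance,
      rep_after_approach = rt$rep_after_approach,
      win_stay = rt$win_stay,
      lose_shift = rt$lose_shift,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pooled logistic fit with subject-clustered standard errors. Returns
# coefficients, clustered SEs and z/p, or a degenerate flag when the
# response does not vary.
clustered_logistic <- function(df, formula, cluster) {
  y <- stats::model.response(stats::model.frame(formula, df))
  if (length(unique(y)) < 2L) {
    return(list(degenerate = TRUE, coefficients = NULL))
  }
  fit <- stats::glm(formula, family = stats::binomial(), data = df)
  vc <- sandwich::vcovCL(fit, cluster = df[[cluster]])
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  z <- est / se
  list(degenerate = FALSE,
       coefficients = data.frame(term = names(est), estimate = est,
                                 se_cluster = se, z = z,
                                 p = 2 * stats::pnorm(-abs(z)),
                                 row.names = NULL),
       glm = fit)
}

#' Pooled hyperbolic learning curve
#'
#' Restricts to the first 20 trials after each reversal (within-block
#' index 0-19), computes the mean hit rate per index, and fits a pooled
#' logistic regression of hit on `hyp_trial(index)` with subject-clustered
#' standard errors.
#'
#' @param cohort A stacked trial table.
#' @return A list with `curve` (`within_block_index`, `mean_hit`, `n`),
#'   `fit` (coefficient table, or `degenerate = TRUE` when hits do not
#'   vary), `slope` (the `hyp_trial` coefficient, NA when degenerate).
#' @export
learning_curve <- function(cohort) {
  df <- cohort[cohort$within_block_index <= 19L & cohort$valid, , drop = FALSE]
  df$hit_num <- as.numeric(df$choice_side == df$optimal_side)
  curve <- stats::aggregate(hit_num ~ within_block_index, df, mean)
  names(curve)[2] <- "mean_hit"
  curve$n <- as.vector(table(df$within_block_index)[as.character(curve$within_block_index)])
  df$hyp <- hyp_trial(df$within_block_index)
  fit <- clustered_logistic(df, hit_num ~ hyp, "subject_id")
  slope <- if (fit$degenerate) NA_real_ else {
    fit$coefficients$estimate[fit$coefficients$term == "hyp"]
  }
  list(curve = curve, fit = fit, slope = slope)
}

#' Repetition as a function of previous-feedback subjective value
#'
#' Each eligible trial pair carries the subject's mean rating (rescaled to
#' 0-1 by dividing by 100) of the scenario class received at t-1; a pooled
#' logistic regression of repetition on that value is fitted with
#' subject-clustered standard errors.
#'
#' @param cohort A stacked trial table.
#' @param ratings A rating table from [generate_ratings()] (or the same
#'   schema).
#' @return A list with `pairs` (per-pair table including `value`), `fit`
#'   (coefficient table or degenerate flag), `slope`.
#' @export
repetition_by_value <- function(cohort, ratings) {
  rt <- repetition_table(cohort)
  if (is.null(rt$pairs)) stop("no eligible pairs", call. = FALSE)
  pairs <- rt$pairs
  means <- stats::aggregate(rating ~ subject_id + scenario, ratings, mean)
  key <- paste(pairs$subject_id, pairs$prev_feedback)
  lookup <- stats::setNames(means$rating, paste(means$subject_id, means$scenario))
  value <- lookup[key]
  if (anyNA(value)) {
    missing <- unique(key[is.na(value)])
    stop("missing subjective ratings for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pairs$value <- as.numeric(value) / 100
  pairs$rep_num <- as.numeric(pairs$repetition)
  if (length(unique(pairs$value)) < 2L) {
    warning("subjective values are constant: slope undefined")
    return(list(pairs = pairs, fit = list(degenerate = TRUE), slope = NA_real_))
  }
  fit <- clustered_logistic(pairs, rep_num ~ value, "subject_id")
  slope <- if (fit$degenerate) NA_real_ else {
    fit$coefficients$estimate[fit$coefficients$term == "value"]
  }
  list(pairs = pairs, fit = fit, slope = slope)
}

#' Apply the response-quality exclusion criteria
#'
#' Subjects are excluded for a valid-response rate below 90% of trials, or
#' for anticipations (reaction time under 100 ms) making up more than 15%
#' of their valid responses.
#'
#' @param cohort A stacked trial table with `valid` and `rt_ms`.
#' @return A `data.frame` (class `exclusion_report`): `subject_id`,
#'   `response_rate`, `anticipation_share`, `retained`, `reasons`
#'   (comma-separated, empty when retained).
#' @export
apply_exclusions <- function(cohort) {
  parts <- split(cohort, cohort$subject_id)
  rows <- lapply(parts, function(ds) {
    rate <- mean(ds$valid)
    antic <- if (any(ds$valid)) {
      mean(ds$rt_ms[ds$valid] < 100, na.rm = TRUE)
    } else 0
    reasons <- character(0)
    if (rate < 0.90) reasons <- c(reasons, "low_response_rate")
    if (antic > 0.15) reasons <- c(reasons, "excess_anticipations")
    data.frame(subject_id = ds$subject_id[1], response_rate = rate,
               anticipation_share = antic,
               retained = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("exclusion_report", class(out))
  out
}

#' Summarize subjective scenario ratings
#'
#' Condition means are grand means of per-subject condition means, so
#' subjects with unequal instance counts carry equal weight.
#'
#' @param ratings A rating table (`subject_id`, `scenario`, `rating`).
#' @return A list with `approach_mean`, `avoidance_mean`, `difference`,
#'   and `per_subject` (subject x condition means).
#' @export
rating_summary <- function(ratings) {
  if (is.null(ratings) || nrow(ratings) == 0L) {
    stop("empty rating table", call. = FALSE)
  }
  per_subject <- stats::aggregate(rating ~ subject_id + scenario, ratings, mean)
  app <- per_subject$rating[per_subject$scenario == "approach"]
  avo <- per_subject$rating[per_subject$scenario == "avoidance"]
  list(approach_mean = mean(app), avoidance_mean = mean(avo),
       difference = mean(avo) - mean(app), per_subject = per_subject)
}

#' Spearman correlations between fitted parameters and covariates
#'
#' One Spearman rank correlation per (parameter, covariate) pair, with
#' Benjamini-Hochberg adjustment applied across the full matrix of tests.
#' Pairs involving a constant column are flagged and excluded from the
#' adjustment.
#'
#' @param fit_table A fit table (from [fit_cohort()]) restricted via
#'   `model` to one model's rows.
#' @param covariates A `data.frame` with `subject_id` plus numeric
#'   covariate columns (questionnaires, ratings, ...).
#' @param model Which model's parameters to correlate (default
#'   `"counterfactual"`).
#' @param parameters Parameter columns to use.
#' @return A long `data.frame`: `parameter`, `covariate`, `n`, `rho`, `p`,
#'   `p_adj`, `flag` (`"ok"` or `"constant"`).
#' @export
correlate_parameters <- function(fit_table, covariates,
                                 model = "counterfactual",
                                 parameters = c("alpha", "alpha_hab",
                                                "beta", "w")) {
  ft <- fit_table[fit_table$model == model & is.na(fit_table$error), , drop = FALSE]
  if (nrow(ft) == 0L) stop("no fit rows for model ", model, call. = FALSE)
  merged <- merge(ft[, c("subject_id", parameters)], covariates,
                  by = "subject_id")
  covs <- setdiff(names(covariates), "subject_id")
  rows <- list()
  for (p in parameters) {
    for (cv in covs) {
      x <- merged[[p]]
      y <- merged[[cv]]
      ok <- stats::complete.cases(x, y)
      if (length(unique(x[ok])) < 2L || length(unique(y[ok])) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, covariate = cv, n = sum(ok), rho = NA_real_,
          p = NA_real_, flag = "constant", stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, covariate = cv, n = sum(ok),
        rho = unname(ct$estimate), p = ct$p.value, flag = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- out$flag == "ok"
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out[, c("parameter", "covariate", "n", "rho", "p", "p_adj", "flag")]
}
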