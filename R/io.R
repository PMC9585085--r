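# Canonical CSV dialect: comma-separated, UTF-8, header row, "." decimal.
# Floats at 6 significant digits, log-likelihoods at 10.

TRIAL_COLUMNS <- c("subject_id", "strategy_group", "trial_index",
                   "block_index", "within_block_index", "optimal_side",
                   "choice_side", "valid", "rt_ms", "feedback", "hit")
RATING_COLUMNS <- c("subject_id", "pair_id", "scenario", "rating")
FIT_COLUMNS <- c("subject_id", "model", "alpha", "alpha_hab", "beta", "w",
                 "ll", "penalized_nll", "n_valid", "converged", "restarts",
                 "seed")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Write / read a trial-level CSV
#'
#' One row per trial; sides encoded `"left"`/`"right"`, feedback
#' `"avoidance"`/`"approach"` (empty string for invalid trials), 0-based
#' indices.
#'
#' @param cohort A stacked trial table.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the validated trial table.
#' @export
write_trials <- function(cohort, path) {
  check_columns(cohort, setdiff(TRIAL_COLUMNS, "strategy_group"), "trial table")
  out <- cohort
  if (is.null(out$strategy_group)) out$strategy_group <- NA_character_
  out <- out[, TRIAL_COLUMNS]
  out$feedback[out$feedback == "none"] <- ""
  out$rt_ms <- ifelse(is.na(out$rt_ms), "", format(out$rt_ms, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  check_columns(df, TRIAL_COLUMNS, basename(path))
  df$feedback[is.na(df$feedback) | df$feedback == ""] <- "none"
  df$choice_side[df$choice_side == ""] <- NA_character_
  df$valid <- as.logical(df$valid)
  df$hit <- as.logical(df$hit)
  bad <- which(df$valid & !df$choice_side %in% SIDES)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid choice_side at row(s) %s", basename(path),
                 paste(utils::head(bad, 5L), collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Write / read a rating CSV
#'
#' @param ratings A rating table.
#' @param path File path.
#' @export
write_ratings <- function(ratings, path) {
  check_columns(ratings, RATING_COLUMNS, "rating table")
  out <- ratings
  out$rating <- sprintf("%.2f", out$rating)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  check_columns(df, RATING_COLUMNS, basename(path))
  if (any(df$rating < 0 | df$rating > 100, na.rm = TRUE)) {
    stop(basename(path), ": ratings must lie in [0, 100]", call. = FALSE)
  }
  df
}

#' Write / read a fit-table CSV
#'
#' @param fit_table A fit table from [fit_cohort()].
#' @param path File path.
#' @export
write_fit_table <- function(fit_table, path) {
  check_columns(fit_table, FIT_COLUMNS, "fit table")
  out <- fit_table
  for (col in c("alpha", "alpha_hab", "beta", "w")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  for (col in c("ll", "penalized_nll")) {
    out[[col]] <- signif(out[[col]], 10)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fit_table
#' @export
read_fit_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  check_columns(df, FIT_COLUMNS, basename(path))
  if (is.null(df$error)) df$error <- NA_character_
  df$converged <- as.logical(df$converged)
  df
}

#' Read / write a pipeline configuration (YAML)
#'
#' The configuration round-trips losslessly: seeds, task design,
#' population profiles, rating-model parameters and fitting options.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  pop <- lapply(config$population, function(g) {
    list(name = g$name, weight = g$weight, kind = g$agent$kind,
         params = if (!is.null(g$agent$params)) unclass(g$agent$params))
  })
  doc <- list(
    seed = config$seed,
    n_subjects = config$n_subjects,
    models = config$models,
    task = unclass(config$task),
    population = pop,
    ratings = unclass(config$ratings),
    fit = unclass(config$fit)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  doc <- yaml::read_yaml(path)
  task <- do.call(task_config, doc$task[setdiff(names(doc$task), "n_trials_total")])
  population <- lapply(doc$population, function(g) {
    params <- if (!is.null(g$params)) do.call(model_params, g$params)
    list(name = g$name, weight = g$weight,
         agent = agent_spec(g$kind, params = params))
  })
  names(population) <- vapply(population, `[[`, character(1), "name")
  pipeline_config(
    seed = doc$seed, n_subjects = doc$n_subjects, models = doc$models,
    task = task, population = population,
    ratings = do.call(rating_model_spec, doc$ratings),
    fit = do.call(fit_options, doc$fit)
  )
}
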