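#' Pipeline configuration
#'
#' Bundles every knob of the simulate-fit-report pipeline under a single
#' global seed; every random stage receives a seed derived
#' deterministically from it.
#'
#' @param seed Global integer seed.
#' @param n_subjects Cohort size (the study's final sample was 214).
#' @param models RL models to fit.
#' @param task A [task_config()].
#' @param population A population spec (see [default_population()]).
#' @param ratings A [rating_model_spec()].
#' @param fit A [fit_options()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects = 214L,
                            models = c("simple", "counterfactual"),
                            task = task_config(),
                            population = default_population(),
                            ratings = rating_model_spec(),
                            fit = fit_options()) {
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 models = models, task = task, population = population,
                 ratings = ratings, fit = fit),
            class = "pipeline_config")
}

write_manifest <- function(out_dir, config, files, stage) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    n_subjects = config$n_subjects,
    package_version = as.character(utils::packageVersion("avoidrl")),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a cohort and write its CSV artifacts
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of written file paths.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config$n_subjects, config$population,
                            config$task, seed = config$seed)
  ratings <- generate_ratings(cohort, config$ratings,
                              seed = derive_seed(config$seed, 1L))
  files <- c(trials = file.path(out_dir, "trials.csv"),
             ratings = file.path(out_dir, "ratings.csv"))
  write_trials(cohort, files[["trials"]])
  write_ratings(ratings, files[["ratings"]])
  write_manifest(out_dir, config, as.list(files), "simulate")
  message(sprintf("simulate: %d subjects -> %s", config$n_subjects, out_dir))
  invisible(files)
}

#' Fit a cohort read from a trial CSV
#'
#' @param trials_path Path to a trial CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the fit-table path.
#' @export
run_fit <- function(trials_path, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_trials(trials_path)
  fits <- fit_cohort(cohort, kinds = config$models, options = config$fit)
  path <- file.path(out_dir, "fits.csv")
  write_fit_table(fits, path)
  message(sprintf("fit: %d rows -> %s", nrow(fits), path))
  invisible(path)
}

#' Behavioral and model-comparison reports
#'
#' Emits four artifacts: the per-subject behavior summary, the pooled
#' learning curve, the exclusion report, and the model-comparison report
#' (JSON). Value-based repetition analyses are skipped with a warning when
#' no rating file is supplied.
#'
#' @param fits_path Path to a fit-table CSV.
#' @param trials_path Path to the matching trial CSV.
#' @param ratings_path Optional path to a rating CSV.
#' @param out_dir Output directory.
#' @return Invisibly, the named vector of written file paths.
#' @export
run_report <- function(fits_path, trials_path, ratings_path = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- read_fit_table(fits_path)
  cohort <- read_trials(trials_path)
  mismatch <- union(setdiff(unique(fits$subject_id), unique(cohort$subject_id)),
                    setdiff(unique(cohort$subject_id), unique(fits$subject_id)))
  if (length(mismatch) > 0L) {
    stop("subject mismatch between fit table and trials: ",
         paste(utils::head(mismatch, 10L), collapse = ", "), call. = FALSE)
  }
  files <- c(behavior = file.path(out_dir, "behavior_summary.csv"),
             curve = file.path(out_dir, "learning_curve.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             comparison = file.path(out_dir, "comparison.json"))
  utils::write.csv(behavior_summary(cohort), files[["behavior"]],
                   row.names = FALSE)
  lc <- learning_curve(cohort)
  utils::write.csv(lc$curve, files[["curve"]], row.names = FALSE)
  utils::write.csv(apply_exclusions(cohort), files[["exclusions"]],
                   row.names = FALSE)
  cmp <- compare_models(likelihood_matrix(fits))
  jsonlite::write_json(
    list(friedman = cmp$friedman, pairwise = cmp$pairwise,
         summaries = cmp$summaries, n_subjects = cmp$n_subjects),
    files[["comparison"]], auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(ratings_path) && file.exists(ratings_path) &&
      length(readLines(ratings_path, n = 2L)) > 1L) {
    ratings <- read_ratings(ratings_path)
    rbv <- repetition_by_value(cohort, ratings)
    files[["repetition_value"]] <- file.path(out_dir, "repetition_by_value.csv")
    utils::write.csv(rbv$pairs, files[["repetition_value"]], row.names = FALSE)
  } else {
    warning("no rating data: value-based repetition analysis skipped")
  }
  message(sprintf("report: %d artifacts -> %s", length(files), out_dir))
  invisible(files)
}

#' End-to-end pipeline: simulate, fit, report
#'
#' Deterministic under the global seed in `config`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, the named vector of all artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  sim <- run_simulate(config, out_dir)
  fit <- run_fit(sim[["trials"]], config, out_dir)
  rep <- run_report(fit, sim[["trials"]], sim[["ratings"]], out_dir)
  invisible(c(sim, fits = fit, rep))
}
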