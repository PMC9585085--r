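#' Subjects x models log-likelihood matrix
#'
#' @param fit_table A fit table from [fit_cohort()].
#' @param penalized Use the penalized objective (negated) instead of the
#'   raw log-likelihood. Model comparison defaults to raw log-likelihoods;
#'   the parameter-free random baseline is identical either way.
#' @return A numeric matrix, rows = subjects, columns = models.
#' @export
likelihood_matrix <- function(fit_table, penalized = FALSE) {
  ft <- fit_table[is.na(fit_table$error) | fit_table$model == "random", ,
                  drop = FALSE]
  value <- if (penalized) -ft$penalized_nll else ft$ll
  subjects <- unique(ft$subject_id)
  models <- unique(ft$model)
  m <- matrix(NA_real_, length(subjects), length(models),
              dimnames = list(subjects, models))
  m[cbind(match(ft$subject_id, subjects), match(ft$model, models))] <- value
  if (anyNA(m)) {
    bad <- rownames(m)[apply(m, 1L, anyNA)]
    stop("missing model cells for subjects: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

#' Friedman rank test
#'
#' Within-subject midranks of the k models;
#' `chi2 = 12 / (n k (k + 1)) * sum(Rj^2) - 3 n (k + 1)` on `k - 1` degrees
#' of freedom. Ties within a row are handled by midranks and flagged.
#'
#' @param matrix A subjects x models numeric matrix (see
#'   [likelihood_matrix()]).
#' @return A list with `chi_sq`, `df`, `p`, `ties` flag.
#' @export
friedman_test <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2L, nrow(matrix) >= 2L)
  n <- nrow(matrix)
  k <- ncol(matrix)
  ranks <- t(apply(matrix, 1L, rank))
  ties <- any(apply(matrix, 1L, anyDuplicated) > 0L)
  if (ties) warning("ties within rows: midranks used")
  Rj <- colSums(ranks)
  chi_sq <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  df <- k - 1L
  list(chi_sq = chi_sq, df = df,
       p = stats::pchisq(chi_sq, df, lower.tail = FALSE), ties = ties)
}

# Rank-biserial effect size for the signed-rank test: (W+ - W-) / (W+ + W-).
signed_rank_biserial <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  wp <- sum(r[d > 0])
  wn <- sum(r[d < 0])
  (wp - wn) / (wp + wn)
}

#' Paired Wilcoxon signed-rank test with Bonferroni correction
#'
#' Zero differences are dropped (and flagged). The test statistic is the
#' positive-rank sum; p-values are exact for tie-free samples up to n = 25
#' and use the normal approximation with continuity correction otherwise.
#' The Bonferroni-corrected p is `min(1, p * n_comparisons)`.
#'
#' @param a,b Paired numeric vectors.
#' @param n_comparisons Number of tests in the family.
#' @return A list with `statistic` (positive-rank sum W+), `rank_sum_neg`,
#'   `z` (normal-approximation z score), `p`, `p_corrected`,
#'   `effect_size` (rank-biserial), `n_pairs` (nonzero differences),
#'   `n_dropped`.
#' @export
wilcoxon_signed_rank <- function(a, b, n_comparisons = 1L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  n_dropped <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero: test undefined")
    return(list(statistic = NA_real_, rank_sum_neg = NA_real_, z = NA_real_,
                p = NA_real_, p_corrected = NA_real_,
                effect_size = NA_real_, n_pairs = 0L,
                n_dropped = n_dropped))
  }
  r <- rank(abs(d))
  wp <- sum(r[d > 0])
  wn <- sum(r[d < 0])
  exact <- (n <= 25L) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE))
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  z <- (wp - mu) / sigma
  list(statistic = wp, rank_sum_neg = wn, z = z, p = wt$p.value,
       p_corrected = min(1, wt$p.value * n_comparisons),
       effect_size = (wp - wn) / (wp + wn),
       n_pairs = n, n_dropped = n_dropped)
}

#' Unpaired Wilcoxon (Mann-Whitney) test with rank-biserial effect size
#'
#' Two-sided rank-sum test: exact null for small tie-free samples, normal
#' approximation with continuity correction and midrank tie handling
#' otherwise. The effect size is the rank-biserial correlation
#' `2U / (n1 n2) - 1`: 0 for identically distributed groups, magnitude 1
#' for complete separation.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A list with `statistic` (Mann-Whitney U for `group_a`),
#'   `rank_sum` (rank sum of `group_a`), `p`, `effect_size`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            correct = TRUE))
  u <- unname(wt$statistic)
  n1 <- length(group_a)
  n2 <- length(group_b)
  list(statistic = u, rank_sum = u + n1 * (n1 + 1) / 2, p = wt$p.value,
       effect_size = 2 * u / (n1 * n2) - 1, n_a = n1, n_b = n2)
}

#' Spearman agreement between real and simulated hit proportions
#'
#' @param real,simulated Per-subject hit proportions (aligned).
#' @param group Optional group labels; group-wise correlations are added.
#' @return A list with `overall` (`rho`, `p`, `n`) and optionally
#'   `by_group`.
#' @export
real_vs_simulated_agreement <- function(real, simulated, group = NULL) {
  stopifnot(length(real) == length(simulated))
  spearman <- function(x, y) {
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      warning("constant vector: correlation undefined")
      return(list(rho = NA_real_, p = NA_real_, n = length(x)))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  out <- list(overall = spearman(real, simulated))
  if (!is.null(group)) {
    out$by_group <- lapply(split(seq_along(real), group), function(idx) {
      spearman(real[idx], simulated[idx])
    })
  }
  out
}

#' Full model-comparison report
#'
#' Friedman omnibus on the subjects x models log-likelihood matrix,
#' pairwise signed-rank tests (Bonferroni-corrected for the number of
#' pairs) with rank-biserial effect sizes, and per-model median/min/max.
#'
#' @param matrix A [likelihood_matrix()].
#' @return An object of class `comparison_report`.
#' @export
compare_models <- function(matrix) {
  models <- colnames(matrix)
  pairs <- utils::combn(models, 2L, simplify = FALSE)
  pairwise <- lapply(pairs, function(pr) {
    res <- wilcoxon_signed_rank(matrix[, pr[1]], matrix[, pr[2]],
                                n_comparisons = length(pairs))
    c(list(model_a = pr[1], model_b = pr[2]), res)
  })
  summaries <- data.frame(
    model = models,
    median = apply(matrix, 2L, stats::median),
    min = apply(matrix, 2L, min),
    max = apply(matrix, 2L, max),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(friedman = friedman_test(matrix), pairwise = pairwise,
                 summaries = summaries, n_subjects = nrow(matrix)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Model comparison over %d subjects\n", x$n_subjects))
  cat(sprintf("Friedman chi2(%d) = %.2f, p = %.3g%s\n", x$friedman$df,
              x$friedman$chi_sq, x$friedman$p,
              if (x$friedman$ties) " (ties: midranks)" else ""))
  print(transform(x$summaries, median = round(median, 2),
                  min = round(min, 2), max = round(max, 2)))
  for (pw in x$pairwise) {
    cat(sprintf("  %s vs %s: W+ = %.0f, z = %.2f, p_corr = %.3g, r = %.2f\n",
                pw$model_a, pw$model_b, pw$statistic, pw$z, pw$p_corrected,
                pw$effect_size))
  }
  invisible(x)
}
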