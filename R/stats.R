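#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank handling of ties. The
#' p-value is exact (by enumeration of rank assignments, via
#' `stats::wilcox.test`) when the smaller group has at most 8 observations
#' and there are no ties, and otherwise uses the normal approximation with
#' the tie correction. The reported `U` is the statistic of `x`, i.e. the
#' number of (x, y) pairs with x > y (ties counted 1/2), so
#' `U(x) + U(y) = n_x * n_y`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative One of "two.sided" (default), "less", "greater".
#' @param exact Force the exact/approximate switch; `NULL` applies the rule
#'   above.
#' @return A one-row tibble: `n_x`, `n_y`, `U`, `p_value`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (min(length(x), length(y)) <= 8) && !has_ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact, correct = TRUE)
  )
  tibble(
    n_x = length(x), n_y = length(y),
    U = unname(res$statistic),
    p_value = res$p.value,
    method = if (exact) "exact" else "normal_approx_tie_corrected"
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p-value uses the t approximation
#' with n - 2 degrees of freedom. Constant input (zero rank variance) is an
#' error because the correlation is undefined there.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("spearman_rho needs at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("constant input: rank variance is zero, correlation undefined")
  }
  res <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(res$estimate), p_value = res$p.value, n = length(x))
}

#' In-group versus out-group habitat score test
#'
#' Sums a category group's scores per sample and compares samples carrying
#' the target source label against all other samples with a Mann-Whitney U
#' test (e.g. soil-derived isolates' soil-related scores versus everyone
#' else's). The reported `U` is the in-group statistic.
#'
#' @param scores A [score_matrix()] result.
#' @param sample_labels Named character vector (or tibble `sample_id`,
#'   `label`) giving each sample's source label.
#' @param target_label The label defining the in-group.
#' @param category_group Character vector of categories to sum.
#' @param group_label Optional name for the reported row; defaults to the
#'   categories pasted together.
#' @return A one-row tibble: `group_label`, `n_in`, `n_out`, `U`,
#'   `p_value`, `median_in`, `median_out`.
#' @export
group_score_test <- function(scores, sample_labels, target_label,
                             category_group, group_label = NULL) {
  labels <- as_named_vector(sample_labels, "sample_id", "label", "sample_labels")
  use <- scores[scores$mapped, , drop = FALSE]
  if (nrow(use) < nrow(scores)) {
    warn(sprintf("dropping %d unmapped sample(s)", nrow(scores) - nrow(use)))
  }
  missing_lab <- setdiff(use$sample_id, names(labels))
  if (length(missing_lab)) {
    abort(sprintf("no label for sample(s): %s", paste(head(missing_lab, 5), collapse = ", ")))
  }
  g <- grouped_scores(use, category_group)
  lab <- labels[use$sample_id]
  if (all(lab == target_label) || !any(lab == target_label)) {
    abort("group_score_test needs samples both with and without the target label")
  }
  x <- unname(g[lab == target_label])
  y <- unname(g[lab != target_label])
  mw <- mann_whitney_u(x, y)
  tibble(
    group_label = group_label %||% paste(category_group, collapse = "+"),
    n_in = length(x), n_out = length(y),
    U = mw$U, p_value = mw$p_value,
    median_in = median(x), median_out = median(y)
  )
}

#' Run group score tests for several category groups
#'
#' @inheritParams group_score_test
#' @param groups Named list of category vectors.
#' @param adjust Apply Benjamini-Hochberg correction across groups and add a
#'   `p_adjusted` column (off by default; single-group analyses need none).
#' @return A tibble with one row per group.
#' @export
group_score_tests <- function(scores, sample_labels, target_label, groups,
                              adjust = FALSE) {
  out <- dplyr::bind_rows(lapply(names(groups), function(g) {
    group_score_test(scores, sample_labels, target_label, groups[[g]],
                     group_label = g)
  }))
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Correlate grouped habitat scores with an environmental gradient
#'
#' Spearman correlation between the per-sample sum of a category group's
#' scores and a numeric covariate (salinity, age, site order, ...). Samples
#' lacking the covariate or unmapped are dropped with a warning; fewer than
#' 3 usable samples is an error.
#'
#' @inheritParams group_score_test
#' @param metadata Named numeric vector (or tibble `sample_id`, `gradient`)
#'   of the covariate.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
gradient_correlation <- function(scores, metadata, category_group) {
  grad <- as_named_vector(metadata, "sample_id", "gradient", "metadata")
  use <- scores[scores$mapped, , drop = FALSE]
  g <- grouped_scores(use, category_group)
  usable <- intersect(names(g), names(grad)[!is.na(grad)])
  dropped <- nrow(scores) - length(usable)
  if (dropped > 0) {
    warn(sprintf("dropping %d sample(s) without scores or gradient metadata", dropped))
  }
  if (length(usable) < 3) {
    abort(sprintf("gradient_correlation needs >= 3 usable samples, got %d", length(usable)))
  }
  spearman_rho(unname(g[usable]), unname(grad[usable]))
}

#' Write test results as TSV
#'
#' Emits the standard columns test, group, n_in, n_out, statistic, p_value.
#'
#' @param x A tibble from [group_score_test()] or [gradient_correlation()].
#' @param path Output path.
#' @param test Label for the `test` column ("mann_whitney_u" or "spearman").
#' @return `path`, invisibly.
#' @export
write_test_results <- function(x, path, test = "mann_whitney_u") {
  col <- function(name, default) if (name %in% names(x)) x[[name]] else default
  out <- tibble(
    test = test,
    group = col("group_label", NA_character_),
    n_in = col("n_in", col("n", NA_integer_)),
    n_out = col("n_out", NA_integer_),
    statistic = col("U", col("rho", NA_real_)),
    p_value = x$p_value
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
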