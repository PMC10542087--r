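#' Cohort demographic and clinical summary
#'
#' Table-1-style description: continuous variables compared by
#' pooled-variance two-sample t-test, categorical variables by Pearson
#' chi-squared (without continuity correction by default).  Patient-only
#' clinical variables (symptom duration, JOA, NDI) are summarised without a
#' test.  A chi-squared cell with zero expected count marks the test as
#' unreliable, with a warning.
#'
#' @param meta Metadata tibble: `subject_id`, `group`, `age`, `sex`,
#'   `education_years`, and optionally `duration_months`, `joa`, `ndi`.
#' @param yates Apply Yates continuity correction to 2 x 2 chi-squared
#'   tables (default `FALSE`).
#' @return Tibble: `variable`, `patient_summary`, `control_summary`,
#'   `test`, `statistic`, `p`, `reliable`.
#' @export
describe_cohort <- function(meta, yates = FALSE) {
  if (any(table(meta$group) < 2)) abort("Need at least 2 subjects per group.")
  pat <- meta[meta$group == "patient", , drop = FALSE]
  ctl <- meta[meta$group == "control", , drop = FALSE]
  ms <- function(x) sprintf("%.2f +- %.2f", mean(x, na.rm = TRUE),
                            stats::sd(x, na.rm = TRUE))
  rows <- list()

  cont_row <- function(var) {
    tt <- stats::t.test(pat[[var]], ctl[[var]], var.equal = TRUE)
    tibble(variable = var, patient_summary = ms(pat[[var]]),
           control_summary = ms(ctl[[var]]), test = "two-sample t",
           statistic = unname(tt$statistic), p = tt$p.value, reliable = TRUE)
  }
  rows$age <- cont_row("age")
  if ("sex" %in% names(meta)) {
    tab <- table(meta$group, meta$sex)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    reliable <- all(expected > 0)
    if (!reliable) warn("Zero expected cell count; chi-squared test unreliable.")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    cnt <- function(df) paste(sprintf("%s=%d", colnames(tab),
                                      as.integer(table(factor(df$sex, colnames(tab))))),
                              collapse = " ")
    rows$sex <- tibble(variable = "sex", patient_summary = cnt(pat),
                       control_summary = cnt(ctl), test = "chi-squared",
                       statistic = unname(ct$statistic), p = ct$p.value,
                       reliable = reliable)
  }
  if ("education_years" %in% names(meta)) {
    rows$education <- cont_row("education_years")
  }
  for (var in intersect(c("duration_months", "joa", "ndi"), names(meta))) {
    rows[[var]] <- tibble(variable = var, patient_summary = ms(pat[[var]]),
                          control_summary = NA_character_, test = NA_character_,
                          statistic = NA_real_, p = NA_real_, reliable = TRUE)
  }
  bind_rows(rows)
}

#' Correlate dynamic network metrics with clinical severity
#'
#' Pearson (default) or Spearman correlation between a per-patient metric
#' and each clinical score, with pairwise deletion of missing scores and a
#' two-sided p from the t reference.  No multiple-testing correction is
#' applied; the number of tests is in the output so users can correct post
#' hoc.
#'
#' @param data Tibble with one row per patient: one or more metric columns
#'   and the score columns.
#' @param metric_cols Character vector of metric column names.
#' @param score_cols Character vector of score column names (default JOA
#'   and NDI).
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble: `metric`, `score`, `r`, `p`, `n`, `n_tests`.
#' @export
correlate_clinical <- function(data, metric_cols,
                               score_cols = c("joa", "ndi"),
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(metric = metric_cols, score = score_cols)
  out <- purrr::pmap_dfr(grid, function(metric, score) {
    x <- data[[metric]]
    y <- data[[score]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) abort(sprintf("Fewer than 3 paired observations for %s ~ %s.",
                                     metric, score))
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      abort(sprintf("Zero variance makes the correlation %s ~ %s undefined.",
                    metric, score))
    }
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    tibble(metric = metric, score = score, r = unname(ct$estimate),
           p = ct$p.value, n = length(x))
  })
  out$n_tests <- nrow(out)
  out
}
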