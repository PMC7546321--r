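#' Per-subject mean GFC over each cluster
#'
#' Arithmetic mean of the (Fisher-z) GFC values over a cluster's member
#' voxels, one row per subject, one column per cluster — the feature table
#' used for clinical correlation and classification.
#'
#' @param gfc_stack Subjects x voxels matrix in mask-column order.
#' @param clusters List from [extract_clusters].
#' @return Numeric matrix subjects x clusters (0 columns if no clusters),
#'   with column names `cluster_1`, `cluster_2`, ...
#' @export
cluster_means <- function(gfc_stack, clusters) {
  out <- vapply(clusters, function(cl)
    rowMeans(gfc_stack[, cl$columns, drop = FALSE]),
    numeric(nrow(gfc_stack)))
  out <- matrix(out, nrow = nrow(gfc_stack))
  colnames(out) <- if (length(clusters)) paste0("cluster_",
                                                seq_along(clusters)) else NULL
  out
}

#' Pearson correlation with the exact t-transform p-value
#'
#' Product-moment correlation; the two-sided p-value comes from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` referred to a Student t distribution
#' with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, non-constant).
#' @return List: `r`, `p`, `n`, `t`, `df`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in correlation input")
  r <- stats::cor(x, y)
  p <- pearson_p(r, n)
  list(r = r, p = p, n = n,
       t = r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2)
}

#' Two-sided p-value for a correlation coefficient
#'
#' The t-transform alone, usable when only a printed r and n are available.
#'
#' @param r Correlation coefficient, `|r| < 1`.
#' @param n Sample size (>= 3).
#' @return Two-sided p-value.
#' @export
pearson_p <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), n - 2)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m p)`; by default m is the number of p-values supplied.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, m * p)
}

#' Two-sample t-test (pooled-variance or Welch)
#'
#' Thin, explicit wrapper around [stats::t.test]: Student's pooled-variance
#' test is the default (the variant consistent with the questionnaire-style
#' demographic tables this pipeline reproduces); Welch is available by flag.
#'
#' @param x,y Numeric samples.
#' @param variant `"student_pooled"` (default) or `"welch"`.
#' @return List: `t`, `df`, `p`, `variant`.
#' @export
two_sample_ttest <- function(x, y, variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  ht <- stats::t.test(x, y, var.equal = variant == "student_pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, variant = variant)
}

#' Two-sample t-test from summary statistics
#'
#' Closed-form pooled or Welch t from group means, SDs and sizes — for
#' checking printed tables where raw values are unavailable.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @param variant `"student_pooled"` or `"welch"`.
#' @return List: `t`, `df`, `p`, `variant`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("student_pooled", "welch")) {
  variant <- match.arg(variant)
  if (variant == "student_pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    a <- sd1^2 / n1
    b <- sd2^2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), variant = variant)
}

#' Pearson chi-square test on a 2x2 table, no continuity correction
#'
#' The uncorrected Pearson chi-square (df = 1). Continuity correction is
#' deliberately off: the Yates-corrected statistic answers a different
#' question and does not reproduce the convention of the demographic tables
#' this pipeline mirrors.
#'
#' @param table_2x2 2x2 matrix of non-negative counts with positive margins.
#' @return List: `chi2`, `df`, `p`.
#' @export
chi_square_test <- function(table_2x2) {
  tab <- as.matrix(table_2x2)
  if (!identical(dim(tab), c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table margins must be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Demographic comparison table
#'
#' Group-wise mean (SD) and between-group tests for the standard cohort
#' table: t-tests for age, education and mean FD; chi-square for sex.
#'
#' @param subjects data.frame with columns `group`, `age`, `sex`,
#'   `education_years` and optionally `mean_fd`, `duration_months`.
#' @param variant t-test variant (see [two_sample_ttest]).
#' @return List of per-variable summaries and p-values, JSON-ready.
#' @export
demographics_table <- function(subjects, variant = "student_pooled") {
  pat <- subjects[subjects$group == "patient", ]
  con <- subjects[subjects$group == "control", ]
  summarise <- function(v) {
    tt <- two_sample_ttest(pat[[v]], con[[v]], variant)
    list(patients_mean = mean(pat[[v]]), patients_sd = stats::sd(pat[[v]]),
         controls_mean = mean(con[[v]]), controls_sd = stats::sd(con[[v]]),
         t = tt$t, p = tt$p)
  }
  sex_tab <- rbind(patient = c(sum(pat$sex == "male"), sum(pat$sex == "female")),
                   control = c(sum(con$sex == "male"), sum(con$sex == "female")))
  colnames(sex_tab) <- c("male", "female")
  out <- list(
    n_patients = nrow(pat), n_controls = nrow(con),
    sex = c(list(table = sex_tab), chi_square_test(sex_tab)),
    age = summarise("age"),
    education_years = summarise("education_years"))
  if ("mean_fd" %in% names(subjects)) out$mean_fd <- summarise("mean_fd")
  if ("duration_months" %in% names(subjects))
    out$duration_months <- list(
      patients_mean = mean(pat$duration_months, na.rm = TRUE),
      patients_sd = stats::sd(pat$duration_months, na.rm = TRUE))
  out
}

#' Correlate cluster features with illness duration in patients
#'
#' Pearson correlation between each cluster's mean GFC and illness duration,
#' within the patient group only, with Bonferroni adjustment over the number
#' of clusters tested.
#'
#' @param features Subjects x clusters matrix from [cluster_means].
#' @param subjects Cohort data.frame (`group`, `duration_months`).
#' @return data.frame: cluster_id, r, p, p_bonferroni, n (zero rows when
#'   there are no clusters).
#' @export
correlate_duration <- function(features, subjects) {
  pat <- subjects$group == "patient"
  m <- ncol(features)
  if (is.null(m) || m == 0L)
    return(data.frame(cluster_id = integer(0), r = numeric(0),
                      p = numeric(0), p_bonferroni = numeric(0),
                      n = integer(0)))
  res <- lapply(seq_len(m), function(j)
    pearson_corr(features[pat, j], subjects$duration_months[pat]))
  data.frame(cluster_id = seq_len(m),
             r = vapply(res, `[[`, numeric(1), "r"),
             p = vapply(res, `[[`, numeric(1), "p"),
             p_bonferroni = bonferroni(vapply(res, `[[`, numeric(1), "p"),
                                       m = m),
             n = vapply(res, `[[`, numeric(1), "n"))
}
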