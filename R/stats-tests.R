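#' Normality-based routing between Student t and Mann-Whitney
#'
#' Each group is screened with the Lilliefors-corrected one-sample
#' Kolmogorov-Smirnov test (mean and SD estimated from the data) at
#' `alpha`; only when both groups look normal is the pooled-variance
#' Student t test used, otherwise the Mann-Whitney U test. Constant
#' samples, and groups too small for the Lilliefors test (n < 5), are
#' routed nonparametric.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 3 values.
#' @param alpha Normality screening level, default 0.05.
#' @return `"student_t"` or `"mann_whitney"`.
#' @export
route_test <- function(sample_a, sample_b, alpha = 0.05) {
  for (s in list(sample_a, sample_b)) {
    if (length(s) < 3L) abort("Each group needs at least 3 observations.")
  }
  normal <- vapply(list(sample_a, sample_b), function(s) {
    if (sd(s) == 0) {
      warn("Constant sample: routing nonparametric.")
      return(FALSE)
    }
    if (length(s) < 5L) {
      inform("Group of size < 5: normality unassessable, routing nonparametric.")
      return(FALSE)
    }
    nortest::lillie.test(s)$p.value >= alpha
  }, logical(1))
  if (all(normal)) "student_t" else "mann_whitney"
}

#' Mann-Whitney U test with exact small-sample p
#'
#' Computes the midrank U statistic and, when the number of group
#' assignments is small enough to enumerate (`choose(n1 + n2, n1)` up to
#' `max_enum`), the exact permutation p value by full enumeration with the
#' two-sided `2 * min(tail)` convention; larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric samples.
#' @param max_enum Enumeration budget; default 200000 assignments.
#' @return A list with `U`, `p_value`, and `method` ("exact" or
#'   "normal_approx").
#' @export
mann_whitney <- function(x, y, max_enum = 2e5) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= max_enum) {
    ranksum <- combn(n1 + n2, n1, FUN = function(ix) sum(r[ix]))
    Uall <- ranksum - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Uall <= U + eps), mean(Uall >= U - eps)))
    list(U = U, p_value = p, method = "exact")
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    list(U = U, p_value = min(1, 2 * pnorm(-abs(z))),
         method = "normal_approx")
  }
}

#' Two-group comparison of one cohort variable
#'
#' Compares a variable between the pCR and non-pCR groups with the routed
#' test ([route_test()]): pooled-variance Student t when both groups pass
#' the normality screen, Mann-Whitney U otherwise. Summaries follow the
#' routing: mean (SD) per group under t, median \[IQR\] under
#' Mann-Whitney.
#'
#' @param cohort Wide cohort tibble with a logical `pcr` column; run
#'   [compute_deltas()] first for delta variables.
#' @param variable Column name to compare (string), e.g. `"f_pre"` or
#'   `"delta_D"`.
#' @param alpha Normality screening level.
#' @return A one-row tibble: `variable`, `test_used`, `statistic`,
#'   `p_value`, and per-group `summary` strings.
#' @examples
#' cohort <- compute_deltas(simulate_cohort(seed = 1))
#' compare_groups(cohort, "delta_D")
#' @export
compare_groups <- function(cohort, variable, alpha = 0.05) {
  if (!variable %in% names(cohort)) {
    abort(paste0("Variable `", variable, "` not found in the cohort."))
  }
  dat <- cohort[!is.na(cohort[[variable]]), ]
  a <- dat[[variable]][dat$pcr]
  b <- dat[[variable]][!dat$pcr]
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both groups must be non-empty for the comparison.")
  }
  test <- route_test(a, b, alpha = alpha)
  if (test == "student_t") {
    tt <- t.test(a, b, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    summ <- function(v) sprintf("%.3g (%.3g)", mean(v), sd(v))
  } else {
    mw <- mann_whitney(a, b)
    statistic <- mw$U
    p <- mw$p_value
    summ <- function(v) sprintf("%.3g [%.3g-%.3g]", median(v),
                                stats::quantile(v, 0.25),
                                stats::quantile(v, 0.75))
  }
  tibble::tibble(
    variable = variable,
    test_used = test,
    statistic = statistic,
    p_value = p,
    pcr_summary = summ(a),
    nonpcr_summary = summ(b),
    n_pcr = length(a),
    n_nonpcr = length(b)
  )
}

#' Spearman correlation between a parameter and mass shrinkage
#'
#' Midrank Spearman correlation (t-approximation p value, two-sided)
#' between an imaging parameter and a percent shrinkage measure, over
#' patients with both values present.
#'
#' @param cohort Cohort tibble after [compute_deltas()].
#' @param parameter Parameter column, e.g. `"D_mid"` or `"delta_f"`.
#' @param shrinkage Shrinkage column, `"shrink_MD_pct"` or
#'   `"shrink_V_pct"`.
#' @return A one-row tibble: `parameter`, `shrinkage`, `rho`, `p_value`,
#'   `n`.
#' @export
spearman_shrinkage <- function(cohort, parameter,
                               shrinkage = "shrink_V_pct") {
  for (col in c(parameter, shrinkage)) {
    if (!col %in% names(cohort)) {
      abort(paste0("Column `", col, "` not found in the cohort."))
    }
  }
  x <- cohort[[parameter]]
  y <- cohort[[shrinkage]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) abort("Need at least 4 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Constant variable: Spearman correlation undefined.")
    return(tibble::tibble(parameter = parameter, shrinkage = shrinkage,
                          rho = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(parameter = parameter, shrinkage = shrinkage,
                 rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
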