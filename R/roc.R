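#' AUC by pair counting with a Hanley-McNeil confidence interval
#'
#' The area under the ROC curve is estimated by the Mann-Whitney
#' pair-counting statistic: the proportion of (case, control) pairs in
#' which the case scores on the positive side, ties counting 1/2. The
#' orientation is chosen automatically so the reported AUC is >= 0.5 and
#' is returned (`"higher"` means larger scores predict the positive
#' class). The confidence interval is the normal interval with the
#' Hanley-McNeil standard error
#' \deqn{SE^2 = \frac{A(1-A) + (n_+ - 1)(Q_1 - A^2) + (n_- - 1)(Q_2 - A^2)}
#'              {n_+ n_-}}
#' with \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}, truncated to \[0, 1\].
#'
#' @param scores Numeric marker values.
#' @param labels Logical (or coercible) vector; `TRUE` is the positive
#'   class (pCR).
#' @param conf_level Confidence level, default 0.95.
#' @return A list with `auc`, `ci` (length 2), `se`, `orientation`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 2, 3, 2, 3, 4), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Both classes must be present to compute an AUC.")
  }
  auc_raw <- auc_pair_count(scores, labels)
  orientation <- if (auc_raw >= 0.5) "higher" else "lower"
  auc <- max(auc_raw, 1 - auc_raw)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * zq * se, 0), 1)
  list(auc = auc, ci = ci, se = se, orientation = orientation,
       n_pos = n_pos, n_neg = n_neg)
}

# Midrank formulation of the pair-counting (ties = 1/2) AUC estimator.
auc_pair_count <- function(scores, labels) {
  r <- rank(scores)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Youden-optimal operating cutoff
#'
#' Scans every candidate threshold at the midpoints between adjacent
#' distinct sorted scores (plus open ends) and returns the cutoff
#' maximising the Youden index J = sensitivity + specificity - 1 for the
#' given orientation. Ties in J are broken in favour of higher
#' sensitivity, then smaller |cutoff|.
#'
#' @inheritParams roc_auc
#' @param orientation `"higher"` if larger scores predict positive,
#'   `"lower"` otherwise (positive side includes the cutoff).
#' @return A list with `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
youden_cutoff <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || !any(!labels)) {
    abort("Both classes must be present to pick a cutoff.")
  }
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) {
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  } else {
    c(s - 1, s + 1)
  }
  best <- NULL
  for (ct in cand) {
    pred <- classify_by_cutoff(scores, ct,
                               if (orientation == "higher") ">=" else "<=")
    tp <- sum(pred & labels); fn <- sum(!pred & labels)
    fp <- sum(pred & !labels); tn <- sum(!pred & !labels)
    sens <- tp / (tp + fn); spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12 ||
        (abs(j - best$youden_j) <= 1e-12 &&
           (sens > best$sensitivity + 1e-12 ||
              (abs(sens - best$sensitivity) <= 1e-12 &&
                 abs(ct) < abs(best$cutoff))))) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   youden_j = j, tp = tp, fp = fp, tn = tn, fn = fn)
    }
  }
  best
}

#' Diagnostic accuracy metrics with exact Clopper-Pearson intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' confusion matrix, each as a percentage with the exact (Clopper-Pearson)
#' two-sided binomial confidence interval. A metric with a zero
#' denominator is returned as `NA` and flagged.
#'
#' @param tp,fp,tn,fn Non-negative confusion-matrix counts.
#' @param conf_level Confidence level, default 0.95.
#' @return A tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate_pct`, `ci_lo_pct`, `ci_hi_pct`, `defined`.
#' @examples
#' diagnostic_metrics(tp = 9, fp = 5, tn = 14, fn = 0)
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn, conf_level = 0.95) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) abort("Counts must be non-negative.")
  spec_tbl <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn)
  )
  purrr::map_dfr(names(spec_tbl), function(nm) {
    k <- spec_tbl[[nm]][1]; n <- spec_tbl[[nm]][2]
    if (n == 0) {
      return(tibble::tibble(metric = nm, numerator = k, denominator = n,
                            estimate_pct = NA_real_, ci_lo_pct = NA_real_,
                            ci_hi_pct = NA_real_, defined = FALSE))
    }
    ci <- binom.test(k, n, conf.level = conf_level)$conf.int
    tibble::tibble(metric = nm, numerator = k, denominator = n,
                   estimate_pct = 100 * k / n,
                   ci_lo_pct = 100 * ci[1], ci_hi_pct = 100 * ci[2],
                   defined = TRUE)
  })
}

#' Full ROC analysis of one marker
#'
#' Combines [roc_auc()], [youden_cutoff()] at the auto-selected
#' orientation, and [diagnostic_metrics()] at the chosen cutoff into one
#' `ivim_roc` object with [tidy()]/[glance()]/[ggplot2::autoplot()]
#' support.
#'
#' @inheritParams roc_auc
#' @param marker Optional marker name carried through to the output.
#' @return An `ivim_roc` object.
#' @export
roc_analysis <- function(scores, labels, marker = "marker",
                         conf_level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  auc <- roc_auc(scores, labels, conf_level = conf_level)
  cut <- youden_cutoff(scores, labels, orientation = auc$orientation)
  metrics <- diagnostic_metrics(cut$tp, cut$fp, cut$tn, cut$fn,
                                conf_level = conf_level)
  structure(
    list(marker = marker, auc = auc, cutoff = cut, metrics = metrics,
         scores = scores, labels = labels, conf_level = conf_level),
    class = "ivim_roc"
  )
}

#' @export
print.ivim_roc <- function(x, ...) {
  cat(sprintf(
    "<ivim_roc> %s: AUC %.3f (%.0f%% CI %.3f-%.3f), cutoff %.3f (%s), J %.3f\n",
    x$marker, x$auc$auc, 100 * x$conf_level, x$auc$ci[1], x$auc$ci[2],
    x$cutoff$cutoff, x$auc$orientation, x$cutoff$youden_j
  ))
  print(x$metrics)
  invisible(x)
}

#' Hanley-McNeil z-test for the difference of two AUCs
#'
#' Tests the difference between two correlated (same-patient) AUCs with
#' the Hanley-McNeil standard errors and the between-marker correlation
#' `r`:
#' \deqn{z = (A_1 - A_2) / \sqrt{SE_1^2 + SE_2^2 - 2 r SE_1 SE_2}.}
#' `r = 0` gives the unpaired (independent-sample) form. Supply `r` from
#' [auc_correlation()] for paired markers.
#'
#' @param auc1,auc2 AUCs in \[0.5, 1\].
#' @param n_pos,n_neg Class sizes shared by both markers.
#' @param r Between-marker score correlation in \[0, 1).
#' @return A one-row tibble: `auc1`, `auc2`, `z`, `p_value`, `r`.
#' @export
hanley_mcneil_test <- function(auc1, auc2, n_pos, n_neg, r = 0) {
  if (r < 0 || r >= 1) abort("`r` must be in [0, 1).")
  se1 <- hanley_mcneil_se(auc1, n_pos, n_neg)
  se2 <- hanley_mcneil_se(auc2, n_pos, n_neg)
  v <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (v <= 0) abort("Non-positive variance: `r` too extreme for these SEs.")
  z <- (auc1 - auc2) / sqrt(v)
  tibble::tibble(auc1 = auc1, auc2 = auc2, z = z,
                 p_value = 2 * pnorm(-abs(z)), r = r)
}

#' Between-marker correlation for paired AUC comparison
#'
#' The average of the Pearson correlations of the two markers computed
#' within the positive and within the negative class — the quantity the
#' Hanley-McNeil correction interpolates between. Returned clipped to
#' \[0, 0.99\] for use as `r` in [hanley_mcneil_test()].
#'
#' @param scores1,scores2 Paired marker values.
#' @param labels Logical class labels.
#' @return A correlation in \[0, 0.99\].
#' @export
auc_correlation <- function(scores1, scores2, labels) {
  labels <- as.logical(labels)
  keep <- complete.cases(scores1, scores2, labels)
  scores1 <- scores1[keep]; scores2 <- scores2[keep]
  labels <- labels[keep]
  cors <- vapply(c(TRUE, FALSE), function(g) {
    x <- scores1[labels == g]; y <- scores2[labels == g]
    if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y)
  }, numeric(1))
  r <- mean(cors, na.rm = TRUE)
  if (is.nan(r)) r <- 0
  min(max(r, 0), 0.99)
}
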