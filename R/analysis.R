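#' End-to-end response-prediction analysis of a cohort
#'
#' Runs the full biomarker evaluation over a wide cohort table:
#'
#' * pre, mid, and delta group comparisons (pCR vs non-pCR) for D, D*, f,
#'   MD and V, with Kolmogorov-Smirnov (Lilliefors) normality routing
#'   between the Student t and Mann-Whitney tests;
#' * ROC analysis of every parameter and delta-parameter (plus the size
#'   shrinkage percentages): pair-counting AUC with Hanley-McNeil CI,
#'   Youden-optimal cutoff, and sensitivity/specificity/PPV/NPV with
#'   exact Clopper-Pearson intervals;
#' * pairwise Hanley-McNeil z-tests between the AUCs of the change
#'   markers, using the within-class score correlations;
#' * Spearman correlations of pre/mid/delta D and f against the MD and V
#'   shrinkage percentages.
#'
#' Patients lacking the mid-treatment scan contribute to the pre-treatment
#' analyses only; when no patient has mid data the delta analyses are
#' skipped with a notice. All p values are two-sided and unadjusted
#' (`multiple_testing = "none"` is recorded in the output metadata);
#' pCR is the positive class throughout. The report is deterministic:
#' the same cohort gives byte-identical results.
#'
#' @param cohort Wide cohort tibble (see [simulate_cohort()] /
#'   [read_cohort_csv()]); deltas are computed internally if absent.
#' @param alpha Significance / normality-routing level, default 0.05.
#' @param conf_level Confidence level for all intervals.
#' @return An `ivim_analysis` object: list of tibbles `comparisons`,
#'   `roc_table`, `auc_comparisons`, `correlations`, plus `meta`. The
#'   underlying `ivim_roc` objects are kept in `roc_objects`.
#' @examples
#' report <- run_full_analysis(simulate_cohort(seed = 1))
#' report$roc_table
#' @export
run_full_analysis <- function(cohort, alpha = 0.05, conf_level = 0.95) {
  cohort <- tibble::as_tibble(cohort)
  if (!"pcr" %in% names(cohort)) abort("Cohort needs a logical `pcr` column.")
  if (length(unique(cohort$pcr)) < 2L) {
    abort("All response labels are identical; ROC analysis is undefined.")
  }
  if (!"delta_D" %in% names(cohort)) cohort <- compute_deltas(cohort)

  has_mid <- any(!is.na(cohort$D_mid))
  params <- c("D", "Dstar", "f", "MD", "V")
  vars <- paste0(params, "_pre")
  if (has_mid) {
    vars <- c(vars, paste0(params, "_mid"),
              paste0("delta_", c("D", "Dstar", "f")),
              "shrink_MD_pct", "shrink_V_pct")
  } else {
    inform("No mid-treatment data: running pre-treatment analyses only.")
  }

  comparisons <- purrr::map_dfr(vars, function(v) {
    compare_groups(cohort, v, alpha = alpha)
  })

  roc_objects <- purrr::map(vars, function(v) {
    keep <- !is.na(cohort[[v]])
    roc_analysis(cohort[[v]][keep], cohort$pcr[keep], marker = v,
                 conf_level = conf_level)
  })
  names(roc_objects) <- vars
  roc_table <- purrr::map_dfr(roc_objects, tidy_roc_row)

  auc_comparisons <- tibble::tibble()
  if (has_mid) {
    delta_vars <- c("delta_D", "delta_Dstar", "delta_f",
                    "shrink_MD_pct", "shrink_V_pct")
    pairs <- combn(delta_vars, 2L)
    complete <- stats::complete.cases(cohort[, delta_vars])
    sub <- cohort[complete, ]
    auc_comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      v1 <- pairs[1, j]; v2 <- pairs[2, j]
      r1 <- roc_objects[[v1]]; r2 <- roc_objects[[v2]]
      r <- auc_correlation(orient_scores(sub[[v1]], r1$auc$orientation),
                           orient_scores(sub[[v2]], r2$auc$orientation),
                           sub$pcr)
      res <- hanley_mcneil_test(r1$auc$auc, r2$auc$auc,
                                n_pos = sum(sub$pcr),
                                n_neg = sum(!sub$pcr), r = r)
      dplyr::mutate(res, marker1 = v1, marker2 = v2, .before = 1)
    })
  }

  correlations <- tibble::tibble()
  if (has_mid) {
    corr_params <- c("D_pre", "f_pre", "D_mid", "f_mid",
                     "delta_D", "delta_f")
    grid <- tidyr::expand_grid(parameter = corr_params,
                               shrinkage = c("shrink_MD_pct",
                                             "shrink_V_pct"))
    correlations <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
      spearman_shrinkage(cohort, grid$parameter[i], grid$shrinkage[i])
    })
  }

  structure(
    list(comparisons = comparisons, roc_table = roc_table,
         auc_comparisons = auc_comparisons, correlations = correlations,
         roc_objects = roc_objects,
         meta = list(alpha = alpha, conf_level = conf_level,
                     positive_class = "pcr",
                     multiple_testing = "none",
                     n_total = nrow(cohort),
                     n_with_mid = sum(!is.na(cohort$D_mid)))),
    class = "ivim_analysis"
  )
}

orient_scores <- function(x, orientation) {
  if (orientation == "lower") -x else x
}

tidy_roc_row <- function(r) {
  m <- r$metrics
  get <- function(nm, col) m[[col]][m$metric == nm]
  tibble::tibble(
    marker = r$marker,
    auc = r$auc$auc, auc_lo = r$auc$ci[1], auc_hi = r$auc$ci[2],
    orientation = r$auc$orientation,
    cutoff = r$cutoff$cutoff, youden_j = r$cutoff$youden_j,
    sens_pct = get("sensitivity", "estimate_pct"),
    sens_lo = get("sensitivity", "ci_lo_pct"),
    sens_hi = get("sensitivity", "ci_hi_pct"),
    spec_pct = get("specificity", "estimate_pct"),
    spec_lo = get("specificity", "ci_lo_pct"),
    spec_hi = get("specificity", "ci_hi_pct"),
    ppv_pct = get("ppv", "estimate_pct"),
    npv_pct = get("npv", "estimate_pct")
  )
}

#' @export
print.ivim_analysis <- function(x, ...) {
  cat("<ivim_analysis> ", x$meta$n_total, " patients (",
      x$meta$n_with_mid, " with mid-treatment data)\n\n", sep = "")
  cat("Group comparisons (pCR vs non-pCR):\n")
  print(x$comparisons, n = Inf)
  cat("\nROC table:\n")
  print(dplyr::select(x$roc_table, "marker", "auc", "auc_lo", "auc_hi",
                      "cutoff", "sens_pct", "spec_pct"), n = Inf)
  if (nrow(x$auc_comparisons) > 0) {
    cat("\nAUC comparisons (Hanley-McNeil):\n")
    print(x$auc_comparisons, n = Inf)
  }
  invisible(x)
}

#' @export
glance.ivim_analysis <- function(x, ...) {
  best <- x$roc_table[which.max(x$roc_table$auc), ]
  tibble::tibble(
    n_total = x$meta$n_total,
    n_with_mid = x$meta$n_with_mid,
    n_markers = nrow(x$roc_table),
    best_marker = best$marker,
    best_auc = best$auc,
    alpha = x$meta$alpha
  )
}
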