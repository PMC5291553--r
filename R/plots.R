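#' Plot a fitted IVIM signal decay
#'
#' Shows the measured decay (points) against the fitted biexponential
#' curve and the stage-1 monoexponential tissue component (dashed), on a
#' log signal axis.
#'
#' @param object An `ivim_fit` from [fit_ivim()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ivim_fit <- function(object, ...) {
  dat <- object$data
  bgrid <- seq(0, max(dat$b), length.out = 200)
  p <- object$params
  curves <- tibble::tibble(
    b = rep(bgrid, 2),
    signal = c(
      ivim_signal(p, bgrid),
      object$stage1$S0_tissue * exp(-bgrid * p$D)
    ),
    component = rep(c("biexponential fit", "tissue (high-b) component"),
                    each = length(bgrid))
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(linetype = .data$component),
      colour = "grey30"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b value (s/mm²)", y = "signal (a.u.)",
                  linetype = NULL,
                  title = sprintf(
                    "D = %.3f, D* = %s (×10⁻³ mm²/s), f = %.1f%%",
                    p$D * 1e3,
                    if (is.na(p$D_star)) "NA" else sprintf("%.1f", p$D_star * 1e3),
                    p$f * 100
                  )) +
    ggplot2::theme_minimal()
}

#' Plot an empirical ROC curve
#'
#' Draws the ROC curve of an [roc_analysis()] result with the
#' Youden-optimal operating point marked.
#'
#' @param object An `ivim_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ivim_roc <- function(object, ...) {
  sc <- orient_scores(object$scores, object$auc$orientation)
  lab <- object$labels
  thr <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- sc >= t
    tibble::tibble(
      fpr = sum(pred & !lab) / sum(!lab),
      tpr = sum(pred & lab) / sum(lab)
    )
  })
  op <- tibble::tibble(
    fpr = 1 - object$cutoff$specificity,
    tpr = object$cutoff$sensitivity
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = op, colour = "red", size = 3, shape = 4) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("%s: AUC %.3f (%.0f%% CI %.3f-%.3f)",
                      object$marker, object$auc$auc,
                      100 * object$conf_level,
                      object$auc$ci[1], object$auc$ci[2])
    ) +
    ggplot2::theme_minimal()
}

#' Compare parameter distributions between response groups
#'
#' Box plots of chosen cohort variables split by pCR status, the standard
#' first look at a candidate response biomarker.
#'
#' @param cohort Wide cohort tibble (deltas computed if absent).
#' @param variables Character vector of columns to plot.
#' @return A ggplot object.
#' @export
plot_group_comparison <- function(cohort,
                                  variables = c("delta_D", "delta_Dstar",
                                                "delta_f")) {
  if (!all(variables %in% names(cohort))) cohort <- compute_deltas(cohort)
  long <- tidyr::pivot_longer(
    dplyr::select(cohort, "pcr", dplyr::all_of(variables)),
    -"pcr", names_to = "variable", values_to = "value"
  )
  long <- dplyr::mutate(
    long, group = ifelse(.data$pcr, "pCR", "non-pCR")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.5) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
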