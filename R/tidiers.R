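#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmented IVIM fit
#'
#' @param x An `ivim_fit` from [fit_ivim()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`D`, `D_star`, `f`, `S0`),
#'   columns `term`, `estimate` (SI scales), and `estimate_reporting`
#'   (1e-3 mm^2/s for the diffusion coefficients, percent for f).
#' @export
tidy.ivim_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("D", "D_star", "f", "S0"),
    estimate = c(p$D, p$D_star, p$f, p$S0),
    estimate_reporting = c(p$D * 1e3, p$D_star * 1e3, p$f * 100, p$S0)
  )
}

#' @rdname tidy.ivim_fit
#' @export
glance.ivim_fit <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    sse = x$sse,
    n_high_b = x$n_high_b,
    dstar_identifiable = x$dstar_identifiable,
    n_b_values = nrow(x$data)
  )
}

#' Tidy a single-marker ROC analysis
#'
#' @param x An `ivim_roc` from [roc_analysis()].
#' @param ... Unused.
#' @return `tidy()` returns the per-metric table (with CIs); `glance()`
#'   returns one row with the AUC, its CI, the cutoff and the Youden
#'   index.
#' @export
tidy.ivim_roc <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.ivim_roc
#' @export
glance.ivim_roc <- function(x, ...) {
  tibble::tibble(
    marker = x$marker,
    auc = x$auc$auc, auc_lo = x$auc$ci[1], auc_hi = x$auc$ci[2],
    orientation = x$auc$orientation,
    cutoff = x$cutoff$cutoff,
    sensitivity = x$cutoff$sensitivity,
    specificity = x$cutoff$specificity,
    youden_j = x$cutoff$youden_j
  )
}
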