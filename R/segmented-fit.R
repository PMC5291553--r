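#' Stage 1: log-linear high-b fit for the true diffusion coefficient
#'
#' Over b values strictly above `b_threshold` the pseudo-diffusion term of
#' the IVIM model has decayed away, leaving
#' \eqn{S(b) \approx S_0 (1 - f) e^{-b D}}. `fit_high_b()` fits an ordinary
#' least-squares line to \eqn{\ln S} versus b on those points; the slope
#' gives `D` and the intercept, compared against the measured signal at
#' b = 0, gives the perfusion fraction via
#' \eqn{1 - f = e^{\mathrm{intercept}} / S(0)}.
#'
#' Points with non-positive signal (possible after magnitude averaging
#' under noise) are excluded; at least two usable high-b points are
#' required. `D` is floored at a small positive value and `f` clamped to
#' \[0, 1\].
#'
#' @param decay A data frame with columns `b` and `signal` (one row per b
#'   value), or a numeric signal vector accompanied by `b`.
#' @param b Numeric b values when `decay` is a bare signal vector.
#' @param b_threshold High-b cutoff in s/mm^2; the fit uses b strictly
#'   greater than this. Default 200 keeps b = 400, 800, 1000 of the
#'   default scheme.
#' @return A list with elements `D`, `f`, `S0_tissue` (the back-transformed
#'   intercept, \eqn{S_0(1-f)}), and `n_high_b`.
#' @examples
#' d <- ivim_decay(ivim_params(1e-3, NA, 0, 1000))
#' fit_high_b(d)$D
#' @export
fit_high_b <- function(decay, b = NULL, b_threshold = 200) {
  dat <- as_decay(decay, b)
  s0 <- dat$signal[dat$b == 0][1]
  if (is.na(s0) || s0 <= 0) {
    abort("Fitting requires a positive signal at b = 0.")
  }
  hi <- dat$b > b_threshold & dat$signal > 0
  if (sum(dat$b > b_threshold) < 2L) {
    abort("Need at least 2 b values above `b_threshold`.")
  }
  if (sum(hi) < 2L) {
    abort(paste0(
      "Fewer than 2 usable (positive-signal) points above b = ",
      b_threshold, "; cannot fit D."
    ))
  }
  fit <- lm(log(signal) ~ b, data = dat[hi, , drop = FALSE])
  D <- max(-coef(fit)[["b"]], 1e-12)
  s0_tissue <- exp(coef(fit)[["(Intercept)"]])
  f <- min(max(1 - s0_tissue / s0, 0), 1)
  list(D = D, f = f, S0_tissue = s0_tissue, n_high_b = sum(hi))
}

#' Stage 2: constrained nonlinear fit of the perfusion compartment
#'
#' With `D` fixed from [fit_high_b()], a damped (Levenberg-Marquardt)
#' least-squares fit of the full biexponential decay refines the perfusion
#' fraction `f` and the unweighted signal `S0` and estimates the
#' pseudo-diffusion coefficient `D_star`, subject to
#' `D_star` in \[`D`, `dstar_max`\] and `f` in \[0, `f_max`\].
#'
#' If the stage-1 perfusion fraction falls below `f_floor` the perfusion
#' term carries no information and `D_star` is declared unidentifiable:
#' stage 2 is skipped, `D_star` is `NA`, and `converged` is `FALSE`.
#'
#' @inheritParams fit_high_b
#' @param stage1 The list returned by [fit_high_b()].
#' @param dstar_max Upper bound on `D_star`, mm^2/s.
#' @param f_max Upper bound on `f` during the refinement.
#' @param f_floor Stage-1 `f` below which `D_star` is flagged
#'   unidentifiable.
#' @param dstar_init Initial `D_star`, mm^2/s.
#' @return An `ivim_fit` object; see [fit_ivim()].
#' @export
fit_perfusion <- function(decay, stage1, b = NULL, dstar_max = 0.5,
                          f_max = 0.6, f_floor = 0.01, dstar_init = 10e-3) {
  dat <- as_decay(decay, b)
  s0_meas <- dat$signal[dat$b == 0][1]
  D <- stage1$D

  if (stage1$f < f_floor) {
    params <- ivim_params(D = D, D_star = NA_real_, f = 0, S0 = s0_meas)
    resid <- dat$signal - ivim_signal(params, dat$b)
    return(new_ivim_fit(params, converged = FALSE, sse = sum(resid^2),
                        n_high_b = stage1$n_high_b, stage1 = stage1,
                        data = dat, dstar_identifiable = FALSE))
  }

  sig <- pmax(dat$signal, 1e-12)  # magnitude data; guard exact zeros
  model <- function(p) {
    p[["S0"]] * (p[["f"]] * exp(-dat$b * p[["Dstar"]]) +
                   (1 - p[["f"]]) * exp(-dat$b * D))
  }
  start <- c(f = min(stage1$f, f_max), Dstar = max(dstar_init, D),
             S0 = s0_meas)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) sig - model(p),
    lower = c(f = 0, Dstar = D, S0 = 0.1 * s0_meas),
    upper = c(f = f_max, Dstar = dstar_max, S0 = 10 * s0_meas),
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-12, ptol = 1e-12
    )
  )
  est <- coef(fit)
  converged <- fit$info %in% 1:4
  params <- ivim_params(D = D, D_star = max(est[["Dstar"]], D),
                        f = min(max(est[["f"]], 0), 1),
                        S0 = est[["S0"]])
  resid <- dat$signal - ivim_signal(params, dat$b)
  new_ivim_fit(params, converged = converged, sse = sum(resid^2),
               n_high_b = stage1$n_high_b, stage1 = stage1, data = dat,
               dstar_identifiable = TRUE)
}

#' Segmented two-stage IVIM fit of one signal decay
#'
#' Composes [fit_high_b()] (log-linear fit of `D` and the intercept-derived
#' `f` on b > `b_threshold`) with [fit_perfusion()] (bounded
#' Levenberg-Marquardt fit of `f`, `D_star`, `S0` on the full decay with
#' `D` held fixed). This is the segmented estimation procedure used
#' clinically for breast IVIM: the high-b segment is assumed free of
#' pseudo-diffusion, and the perfusion compartment is then recovered from
#' the low-b curvature.
#'
#' The fit is fully deterministic: identical decays give identical results.
#'
#' @inheritParams fit_perfusion
#' @param b_threshold High-b cutoff for stage 1, s/mm^2 (exclusive).
#' @return An object of class `ivim_fit` with fields `params`
#'   ([ivim_params]), `converged`, `sse`, `n_high_b`, `stage1`,
#'   `dstar_identifiable`, and the input `data`. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' truth <- ivim_params(D = 0.906e-3, D_star = 40.4e-3, f = 0.357, S0 = 1000)
#' fit <- fit_ivim(ivim_decay(truth))
#' tidy(fit)
#' @export
fit_ivim <- function(decay, b = NULL, b_threshold = 200, dstar_max = 0.5,
                     f_max = 0.6, f_floor = 0.01, dstar_init = 10e-3) {
  dat <- as_decay(decay, b)
  stage1 <- fit_high_b(dat, b_threshold = b_threshold)
  fit_perfusion(dat, stage1, dstar_max = dstar_max, f_max = f_max,
                f_floor = f_floor, dstar_init = dstar_init)
}

new_ivim_fit <- function(params, converged, sse, n_high_b, stage1, data,
                         dstar_identifiable) {
  structure(
    list(params = params, converged = converged, sse = sse,
         n_high_b = n_high_b, stage1 = stage1,
         dstar_identifiable = dstar_identifiable, data = data),
    class = "ivim_fit"
  )
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat("<ivim_fit> segmented biexponential fit\n")
  print(x$params)
  cat(sprintf("converged: %s | SSE: %.4g | high-b points: %d | D* %s\n",
              x$converged, x$sse, x$n_high_b,
              if (x$dstar_identifiable) "identifiable" else "unidentifiable"))
  invisible(x)
}

# Normalise decay input: data frame with (b, signal) or signal vector + b.
as_decay <- function(decay, b = NULL) {
  if (is.data.frame(decay)) {
    if (!all(c("b", "signal") %in% names(decay))) {
      abort("`decay` data frame needs columns `b` and `signal`.")
    }
    dat <- tibble::as_tibble(decay[, intersect(names(decay),
                                               c("b", "nex", "signal"))])
  } else {
    if (is.null(b)) abort("Supply `b` when `decay` is a bare signal vector.")
    if (length(b) != length(decay)) {
      abort("`decay` and `b` must have equal length.")
    }
    dat <- tibble::tibble(b = as.numeric(b), signal = as.numeric(decay))
  }
  if (any(dat$signal < 0, na.rm = TRUE)) {
    abort("Signal intensities must be non-negative (magnitude data).")
  }
  if (!any(dat$b == 0)) abort("The decay must include b = 0.")
  dat
}
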