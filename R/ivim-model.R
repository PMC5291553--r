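#' IVIM parameter set for one voxel or ROI
#'
#' Bundles the four parameters of the biexponential intravoxel incoherent
#' motion (IVIM) model: the true diffusion coefficient `D` (tissue-water
#' diffusion, mm^2/s), the pseudo-diffusion coefficient `D_star` (capillary
#' microcirculation, mm^2/s), the perfusion fraction `f` (fraction of the
#' b = 0 signal in the perfusion compartment), and the unweighted signal
#' `S0`. All values are on SI-like scales internally (mm^2/s, fractions);
#' the 1e-3 mm^2/s and percent scales common in reporting are applied only
#' at I/O boundaries.
#'
#' `D_star` may be `NA` to represent an unidentifiable pseudo-diffusion
#' coefficient (for example after a fit on a perfusion-free decay).
#'
#' @param D True diffusion coefficient, mm^2/s; must be > 0.
#' @param D_star Pseudo-diffusion coefficient, mm^2/s; must be >= `D`
#'   when not `NA`.
#' @param f Perfusion fraction in \[0, 1\].
#' @param S0 Signal at b = 0, arbitrary units; must be > 0.
#' @return An object of class `ivim_params`.
#' @examples
#' p <- ivim_params(D = 0.906e-3, D_star = 40.4e-3, f = 0.357, S0 = 1000)
#' ivim_signal(p, b = c(0, 200, 1000))
#' @export
ivim_params <- function(D, D_star, f, S0 = 1) {
  if (!is.numeric(D) || length(D) != 1L || is.na(D) || D <= 0) {
    abort("`D` must be a single positive number (mm^2/s).")
  }
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    abort("`f` must be a single number in [0, 1].")
  }
  if (!is.numeric(S0) || length(S0) != 1L || is.na(S0) || S0 <= 0) {
    abort("`S0` must be a single positive number.")
  }
  if (length(D_star) != 1L) abort("`D_star` must have length 1.")
  if (!is.na(D_star) && D_star < D) {
    abort("`D_star` must be >= `D` (identifiability convention).")
  }
  structure(
    list(D = D, D_star = as.numeric(D_star), f = f, S0 = S0),
    class = "ivim_params"
  )
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf(
    "<ivim_params> D = %.3f e-3 mm^2/s, D* = %s e-3 mm^2/s, f = %.1f%%, S0 = %.4g\n",
    x$D * 1e3,
    if (is.na(x$D_star)) "NA" else sprintf("%.1f", x$D_star * 1e3),
    x$f * 100, x$S0
  ))
  invisible(x)
}

#' Biexponential IVIM forward signal
#'
#' Evaluates the IVIM signal equation
#' \deqn{S(b) = S_0 \left[ f e^{-b D^*} + (1 - f) e^{-b D} \right]}
#' at the requested b values. At b = 0 the signal equals `S0` exactly; for
#' positive `D` and `D_star` the decay is non-increasing in b. When
#' `f = 0` the model reduces to the monoexponential `S0 exp(-b D)`; an
#' `NA` `D_star` is permitted in that case only.
#'
#' @param params An [ivim_params] object.
#' @param b Numeric vector of b values (s/mm^2), or a [bvalue_scheme].
#' @return Numeric vector of signal intensities, one per b value.
#' @export
ivim_signal <- function(params, b) {
  stopifnot(inherits(params, "ivim_params"))
  if (inherits(b, "bvalue_scheme")) b <- b$b_values
  if (any(b < 0)) abort("b values must be non-negative.")
  if (is.na(params$D_star)) {
    if (params$f > 0) {
      abort("`D_star` is NA but `f` > 0: the perfusion term is undefined.")
    }
    return(params$S0 * exp(-b * params$D))
  }
  params$S0 * (params$f * exp(-b * params$D_star) +
                 (1 - params$f) * exp(-b * params$D))
}

#' Simulate a noiseless signal decay as a tibble
#'
#' Convenience wrapper pairing [ivim_signal()] with a scheme; the returned
#' tibble is the tabular decay format accepted by [fit_ivim()].
#'
#' @inheritParams ivim_signal
#' @param scheme A [bvalue_scheme]; defaults to [default_scheme()].
#' @return A tibble with columns `b`, `nex`, `signal`.
#' @examples
#' ivim_decay(ivim_params(1.1e-3, 14.8e-3, 0.292, 1000))
#' @export
ivim_decay <- function(params, scheme = default_scheme()) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  tibble::tibble(
    b = scheme$b_values,
    nex = scheme$nex,
    signal = ivim_signal(params, scheme$b_values)
  )
}
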