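#' Voxel-wise segmented IVIM fitting over a 4D volume
#'
#' Applies [fit_ivim()] to every voxel inside `mask` of a 4D multi-b
#' volume (x, y, z, b). Out-of-mask voxels are `NA` in every map; voxels
#' whose stage-1 fit fails (for example all-zero signal) stay `NA` and are
#' excluded from `fit_mask`'s converged subset.
#'
#' @param volume 4D numeric array; the 4th axis must match `scheme`.
#' @param scheme A [bvalue_scheme].
#' @param mask 3D logical array matching the spatial grid; voxels to fit.
#' @param ... Passed to [fit_ivim()] (`b_threshold`, `dstar_max`, `f_max`,
#'   `f_floor`).
#' @return An `ivim_maps` object: list with 3D arrays `D`, `D_star`, `f`,
#'   `S0`, logical arrays `fit_mask` and `converged_mask`, the scheme, and
#'   counters `n_attempted` / `n_converged`.
#' @export
fit_parameter_maps <- function(volume, scheme, mask, ...) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  dims <- dim(volume)
  if (length(dims) != 4L) abort("`volume` must be a 4D array (x, y, z, b).")
  if (dims[4L] != length(scheme)) {
    abort("4th axis of `volume` must match the number of b values.")
  }
  if (!identical(dim(mask), dims[1:3])) {
    abort("`mask` must match the spatial grid of `volume`.")
  }
  mask <- array(as.logical(mask), dim = dims[1:3])
  spatial <- dims[1:3]
  empty <- array(NA_real_, dim = spatial)
  maps <- list(D = empty, D_star = empty, f = empty, S0 = empty)
  converged_mask <- array(FALSE, dim = spatial)
  fitted_mask <- array(FALSE, dim = spatial)

  idx <- which(mask)
  nvox <- prod(spatial)
  for (i in idx) {
    sig <- volume[i + nvox * (seq_len(dims[4L]) - 1L)]
    res <- tryCatch(
      fit_ivim(sig, b = scheme$b_values, ...),
      error = function(e) NULL
    )
    if (is.null(res)) next
    fitted_mask[i] <- TRUE
    converged_mask[i] <- res$converged
    maps$D[i] <- res$params$D
    maps$D_star[i] <- res$params$D_star
    maps$f[i] <- res$params$f
    maps$S0[i] <- res$params$S0
  }

  structure(
    list(D = maps$D, D_star = maps$D_star, f = maps$f, S0 = maps$S0,
         fit_mask = mask, fitted_mask = fitted_mask,
         converged_mask = converged_mask, scheme = scheme,
         n_attempted = length(idx), n_converged = sum(converged_mask)),
    class = "ivim_maps"
  )
}

#' @export
print.ivim_maps <- function(x, ...) {
  cat("<ivim_maps> grid ", paste(dim(x$D), collapse = " x "),
      " | attempted ", x$n_attempted,
      " | converged ", x$n_converged, "\n", sep = "")
  invisible(x)
}

#' Tabulate voxel-wise IVIM maps
#'
#' Converts an [fit_parameter_maps()] result into one row per fitted voxel,
#' the tabular form used by ROI summaries and plotting.
#'
#' @param x An `ivim_maps` object.
#' @param ... Unused.
#' @return A tibble with voxel indices `i`, `j`, `k`, the four parameter
#'   estimates, and a `converged` flag.
#' @export
tidy.ivim_maps <- function(x, ...) {
  idx <- which(x$fitted_mask, arr.ind = TRUE)
  tibble::tibble(
    i = idx[, 1L], j = idx[, 2L], k = idx[, 3L],
    D = x$D[x$fitted_mask],
    D_star = x$D_star[x$fitted_mask],
    f = x$f[x$fitted_mask],
    S0 = x$S0[x$fitted_mask],
    converged = x$converged_mask[x$fitted_mask]
  )
}

#' @export
glance.ivim_maps <- function(x, ...) {
  tibble::tibble(
    n_voxels = prod(dim(x$D)),
    n_attempted = x$n_attempted,
    n_converged = x$n_converged,
    convergence_rate = if (x$n_attempted > 0) {
      x$n_converged / x$n_attempted
    } else NA_real_
  )
}
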