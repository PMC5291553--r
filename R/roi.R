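#' ROI mean parameters with triplicate re-measurement
#'
#' Averages the fitted `D`, `D_star` and `f` maps over a region of
#' interest. Mirroring the manual workflow in which a reader re-draws the
#' ROI and the three measurements are averaged, `n_repeats` re-draws are
#' simulated by randomly dropping a small fraction of the ROI's boundary
#' voxels (seeded jitter) before averaging the repeat means. `D_star` is
#' averaged over identifiable voxels only (non-`NA`); when none exist the
#' `D_star` mean is `NA` with a message.
#'
#' @param maps An `ivim_maps` object from [fit_parameter_maps()].
#' @param roi 3D logical array selecting the region.
#' @param n_repeats Number of simulated re-measurements, default 3.
#' @param jitter_frac Fraction of boundary voxels dropped per re-draw.
#' @param seed Integer seed for the jitter.
#' @return A one-row tibble with columns `D`, `D_star`, `f` (SI scales),
#'   `n_voxels`, and `n_repeats`.
#' @export
roi_summary <- function(maps, roi, n_repeats = 3L, jitter_frac = 0.1,
                        seed = 1L) {
  stopifnot(inherits(maps, "ivim_maps"))
  roi <- array(as.logical(roi), dim = dim(maps$D))
  usable <- roi & maps$fitted_mask
  if (!any(usable)) abort("ROI contains no fitted voxels.")
  set.seed(seed)
  draws <- purrr::map(seq_len(n_repeats), function(r) {
    m <- if (r == 1L) usable else jitter_roi(usable, jitter_frac)
    if (!any(m)) m <- usable
    dstar <- maps$D_star[m]
    tibble::tibble(
      D = mean(maps$D[m], na.rm = TRUE),
      D_star = if (all(is.na(dstar))) NA_real_ else mean(dstar, na.rm = TRUE),
      f = mean(maps$f[m], na.rm = TRUE)
    )
  })
  out <- dplyr::summarise(
    dplyr::bind_rows(draws),
    D = mean(.data$D), D_star = mean(.data$D_star), f = mean(.data$f)
  )
  if (is.na(out$D_star)) {
    inform("D* unidentifiable everywhere in the ROI; D* mean is NA.")
  }
  dplyr::mutate(out, n_voxels = sum(usable), n_repeats = n_repeats)
}

# Drop a random subset of 6-connected boundary voxels from a mask.
jitter_roi <- function(mask, frac) {
  d <- dim(mask)
  interior <- mask
  shift <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    keep <- max(1L, 1L + by):min(n, n + by)
    dst[[ax]] <- keep
    src[[ax]] <- keep - by
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) {
    interior <- interior & shift(mask, ax, 1L) & shift(mask, ax, -1L)
  }
  boundary <- which(mask & !interior)
  if (length(boundary) == 0L) return(mask)
  ndrop <- round(frac * length(boundary))
  if (ndrop == 0L) return(mask)
  out <- mask
  out[sample(boundary, ndrop)] <- FALSE
  out
}

#' Maximum transverse diameter of a lesion mask
#'
#' The largest in-plane (transverse-slice) distance between any two mask
#' voxel centres, maximised over slices, in mm. A single-voxel mask has
#' diameter 0 by the centre-to-centre convention.
#'
#' @param mask 3D logical array; third axis indexes transverse slices.
#' @param voxel_size Numeric length-3 voxel spacing in mm (in-plane x,
#'   in-plane y, slice spacing).
#' @return Diameter in mm.
#' @export
max_diameter <- function(mask, voxel_size = c(2.5, 2.5, 6)) {
  mask <- as.array(mask)
  if (!any(mask)) abort("Mask is empty; no diameter defined.")
  best <- 0
  for (k in seq_len(dim(mask)[3L])) {
    idx <- which(mask[, , k], arr.ind = TRUE)
    if (nrow(idx) < 2L) next
    pts <- cbind(idx[, 1L] * voxel_size[1L], idx[, 2L] * voxel_size[2L])
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
    dmat <- as.matrix(stats::dist(pts))
    best <- max(best, max(dmat))
  }
  best
}

#' Lesion volume from a voxel mask
#'
#' Voxel count times in-plane area times slice spacing, the slice-by-slice
#' contour integration used on clinical workstations.
#'
#' @inheritParams max_diameter
#' @return Volume in mm^3; an empty mask returns 0 with a warning.
#' @export
lesion_volume <- function(mask, voxel_size = c(2.5, 2.5, 6)) {
  mask <- as.array(mask)
  n <- sum(mask)
  if (n == 0L) {
    warn("Mask is empty; volume is 0.")
    return(0)
  }
  n * voxel_size[1L] * voxel_size[2L] * voxel_size[3L]
}
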