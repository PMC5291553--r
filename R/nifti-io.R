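#' Read a multi-b DWI dataset from NIfTI + bval files
#'
#' @param volume_path 4D NIfTI volume (x, y, z, b).
#' @param bval_path FSL-style bval text file.
#' @param mask_path Optional 3D NIfTI lesion/fit mask (non-zero = inside).
#' @param nex_path Optional YAML sidecar with the per-b NEX list.
#' @return A list with `volume` (4D array), `scheme` ([bvalue_scheme]) and
#'   `mask` (3D logical array or `NULL`).
#' @export
read_dwi <- function(volume_path, bval_path, mask_path = NULL,
                     nex_path = NULL) {
  vol <- array(as.numeric(RNifti::readNifti(volume_path)),
               dim = dim(RNifti::readNifti(volume_path)))
  scheme <- read_bval(bval_path, nex_path)
  if (length(dim(vol)) != 4L || dim(vol)[4L] != length(scheme)) {
    abort("Volume's 4th axis must match the bval file.")
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    mask <- array(as.numeric(m) != 0, dim = dim(m))
    if (!identical(dim(mask), dim(vol)[1:3])) {
      abort("Mask grid must match the volume's spatial grid.")
    }
  }
  list(volume = vol, scheme = scheme, mask = mask)
}

#' Write fitted IVIM parameter maps as NIfTI files
#'
#' One file per parameter (`D.nii.gz`, `Dstar.nii.gz`, `f.nii.gz`,
#' `S0.nii.gz`, `converged.nii.gz`) plus a JSON-free plain-text fit report.
#' D and D* are written in mm^2/s and f as a fraction.
#'
#' @param maps An `ivim_maps` object from [fit_parameter_maps()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_parameter_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "ivim_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(maps$D), file.path(dir, "D.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$D_star),
                     file.path(dir, "Dstar.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$f), file.path(dir, "f.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$S0), file.path(dir, "S0.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(maps$converged_mask * 1),
                     file.path(dir, "converged.nii.gz"))
  rep <- glance(maps)
  writeLines(
    paste(names(rep), unlist(rep), sep = ": "),
    file.path(dir, "fit_report.txt")
  )
  invisible(dir)
}

#' Write a digital phantom to disk
#'
#' Emits the noisy 4D volume, the ground-truth parameter maps, the lesion
#' mask (NIfTI), the bval line and the NEX YAML sidecar, so the phantom can
#' round-trip through [read_dwi()] and external tools.
#'
#' @param phantom An `ivim_phantom` from [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ivim_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(phantom$volume),
                     file.path(dir, "dwi.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$lesion_mask * 1),
                     file.path(dir, "lesion_mask.nii.gz"))
  for (nm in c("D", "D_star", "f", "S0")) {
    RNifti::writeNifti(RNifti::asNifti(phantom$truth[[nm]]),
                       file.path(dir, paste0("truth_", nm, ".nii.gz")))
  }
  write_bval(phantom$scheme, file.path(dir, "dwi.bval"),
             nex_path = file.path(dir, "dwi_nex.yaml"))
  invisible(dir)
}
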