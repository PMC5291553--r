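#' Longitudinal delta-parameters and shrinkage percentages
#'
#' Adds the treatment-change columns to a wide cohort table: for each IVIM
#' parameter the difference pre minus mid
#' (\eqn{\Delta x = x_{pre} - x_{mid}}), and for size measures the percent
#' shrinkage \eqn{100 (x_{pre} - x_{mid}) / x_{pre}}. Under this sign
#' convention a parameter that rises under therapy (as D does in
#' responders) has a negative delta, while delta-f is in percentage points
#' because f itself is carried in percent on the reporting scale.
#'
#' Patients missing the mid-treatment scan get `NA` deltas and are dropped
#' from delta-based analyses downstream (the pre-only subset remains
#' usable).
#'
#' @param cohort A cohort tibble in the wide reporting-scale layout of
#'   [simulate_cohort()]: columns `id`, `pcr`, and `<param>_pre` /
#'   `<param>_mid` for `D`, `Dstar` (1e-3 mm^2/s), `f` (%), `MD` (mm),
#'   `V` (mm^3).
#' @return The cohort with columns `delta_D`, `delta_Dstar`, `delta_f`,
#'   `shrink_MD_pct`, `shrink_V_pct` appended.
#' @examples
#' tbl <- tibble::tibble(id = "fig1", pcr = TRUE,
#'                       D_pre = 0.906, D_mid = 1.310,
#'                       Dstar_pre = 40.4, Dstar_mid = 13.8,
#'                       f_pre = 35.7, f_mid = 14.2,
#'                       MD_pre = 40, MD_mid = 18, V_pre = 3e4, V_mid = 4e3)
#' compute_deltas(tbl)$delta_D  # -0.404
#' @export
compute_deltas <- function(cohort) {
  need <- c("D_pre", "D_mid", "Dstar_pre", "Dstar_mid", "f_pre", "f_mid",
            "MD_pre", "MD_mid", "V_pre", "V_mid")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    abort(paste("Cohort is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(cohort),
    delta_D = .data$D_pre - .data$D_mid,
    delta_Dstar = .data$Dstar_pre - .data$Dstar_mid,
    delta_f = .data$f_pre - .data$f_mid,
    shrink_MD_pct = 100 * (.data$MD_pre - .data$MD_mid) / .data$MD_pre,
    shrink_V_pct = 100 * (.data$V_pre - .data$V_mid) / .data$V_pre
  )
}

#' Classify patients against an operating cutoff
#'
#' Applies a decision threshold to a marker value. `direction = "<="`
#' predicts the positive class (pCR) for values at or below the cutoff —
#' the orientation used for delta-D, where a strongly negative delta
#' (large rise in D) marks responders; `direction = ">="` predicts
#' positive at or above. Ties at the cutoff fall on the positive side.
#'
#' @param value Numeric marker value(s).
#' @param cutoff Decision threshold on the same scale.
#' @param direction `"<="` or `">="`; which side predicts positive.
#' @return Logical vector of predicted-positive flags.
#' @examples
#' classify_by_cutoff(c(-0.404, -0.300, -0.05), -0.163, "<=")
#' @export
classify_by_cutoff <- function(value, cutoff, direction = c("<=", ">=")) {
  direction <- match.arg(direction)
  if (direction == "<=") value <= cutoff else value >= cutoff
}
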