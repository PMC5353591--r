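#' Cumulative dose-volume histogram over a mask
#'
#' Computes the cumulative DVH: for each dose edge d the percentage of the
#' mask's voxels receiving at least d Gy. Edges run from 0 to the smallest
#' multiple of `bin_width` at or above the maximum dose within the mask,
#' so the curve always starts at 100% (every voxel receives >= 0 Gy) and
#' ends at or below the last voxel's dose. Relative volume is by voxel
#' count -- voxel volume is uniform within one grid.
#'
#' @param dose `image_grid` of dose (Gy), aligned to `mask`.
#' @param mask non-empty `binary_mask` (anatomical lung or a functional
#'   mask's `$mask`); a `functional_mask` is accepted directly.
#' @param bin_width dose bin width in Gy; default 0.1.
#' @param mask_label label stored alongside the curve (e.g. `"lung"`,
#'   `"Q-functional"`).
#' @return A tibble of class `fl_dvh` with columns `dose_gy`, `volume_pct`,
#'   `mask_label`.
#' @examples
#' lung <- binary_mask(array(TRUE, dim = c(5, 5, 4)), spacing = c(3, 3, 3))
#' dose <- image_grid(array(10, dim = c(5, 5, 4)), spacing = c(3, 3, 3))
#' cumulative_dvh(dose, lung, bin_width = 1)
#' @export
cumulative_dvh <- function(dose, mask, bin_width = 0.1, mask_label = "lung") {
  mask <- as_mask(mask)
  stop_if_misaligned(dose, mask, "dose and mask")
  if (mask_count(mask) == 0) abort("empty mask: DVH undefined.")
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be > 0.")
  d <- dose$values[mask$values]
  if (any(d < 0)) abort("negative dose values in grid.")
  edges <- seq(0, ceiling(max(d) / bin_width) * bin_width, by = bin_width)
  ds <- sort(d)
  n <- length(ds)
  # voxels with dose >= edge: n minus the count strictly below the edge
  n_ge <- n - findInterval(edges, ds, left.open = TRUE)
  out <- tibble(
    dose_gy = edges,
    volume_pct = 100 * n_ge / n,
    mask_label = mask_label
  )
  class(out) <- c("fl_dvh", class(out))
  out
}

#' Mean dose over a mask
#'
#' Arithmetic mean of the dose over the mask's voxels: the mean lung dose
#' (MLD) when the mask is the anatomical lung, Q-MLD / V-MLD when it is a
#' functional mask.
#'
#' @inheritParams cumulative_dvh
#' @return mean dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  mask <- as_mask(mask)
  stop_if_misaligned(dose, mask, "dose and mask")
  if (mask_count(mask) == 0) abort("empty mask: mean dose undefined.")
  mean(dose$values[mask$values])
}

#' Relative volume receiving at least x Gy (Vx)
#'
#' Percentage of the mask's voxels whose dose reaches `x` Gy: V20 at the
#' default `x = 20`. The comparison at the boundary is `>=` by default,
#' matching common treatment-planning-system convention; `inequality =
#' "gt"` switches to a strict `>`.
#'
#' @inheritParams cumulative_dvh
#' @param x dose threshold in Gy (>= 0); default 20.
#' @param inequality `"ge"` (default) or `"gt"`.
#' @return percentage in \[0, 100\].
#' @export
vx <- function(dose, mask, x = 20, inequality = c("ge", "gt")) {
  inequality <- match.arg(inequality)
  mask <- as_mask(mask)
  stop_if_misaligned(dose, mask, "dose and mask")
  if (mask_count(mask) == 0) abort("empty mask: Vx undefined.")
  if (!is.numeric(x) || x < 0) abort("`x` must be a dose >= 0 Gy.")
  d <- dose$values[mask$values]
  if (any(d < 0)) abort("negative dose values in grid.")
  # same evaluation order as cumulative_dvh so edge values tie out exactly
  100 * sum(if (inequality == "ge") d >= x else d > x) / length(d)
}

#' Anatomical and functional dose-volume metrics for one patient
#'
#' The six per-patient metrics: V20 and MLD over the anatomical lung, and
#' their perfusion- (Q-) and ventilation- (V-) functional counterparts
#' over the respective functional masks. Functional relative volumes use
#' the functional mask itself as denominator (percent of *functional*
#' lung), so every functional DVH starts at 100%.
#'
#' @param dose `image_grid` of dose (Gy).
#' @param lung anatomical lung `binary_mask`.
#' @param q_func,v_func perfusion and ventilation `functional_mask`
#'   objects derived from `lung`.
#' @param x Vx threshold in Gy; default 20.
#' @param inequality boundary rule passed to [vx()].
#' @param patient_id optional identifier column.
#' @return One-row tibble with columns `patient_id` (if given), `V20`,
#'   `MLD`, `Q_V20`, `Q_MLD`, `V_V20`, `V_MLD` (percent / Gy); the Vx
#'   columns are named `V20` style for any `x` via the attribute
#'   `vx_dose_gy`.
#' @export
compute_metrics <- function(dose, lung, q_func, v_func, x = 20,
                            inequality = c("ge", "gt"), patient_id = NULL) {
  inequality <- match.arg(inequality)
  for (fm in list(q = q_func, v = v_func)) {
    if (mask_count(as_mask(fm)) == 0) {
      abort(paste0("empty ", fm$modality, " functional mask: metrics undefined."))
    }
  }
  out <- tibble(
    V20 = vx(dose, lung, x, inequality),
    MLD = mean_dose(dose, lung),
    Q_V20 = vx(dose, q_func, x, inequality),
    Q_MLD = mean_dose(dose, q_func),
    V_V20 = vx(dose, v_func, x, inequality),
    V_MLD = mean_dose(dose, v_func)
  )
  if (!is.null(patient_id)) out <- dplyr::bind_cols(tibble(patient_id = patient_id), out)
  attr(out, "vx_dose_gy") <- x
  attr(out, "threshold_fraction") <- q_func$threshold_fraction
  out
}

#' Activity-weighted functional dose metrics
#'
#' An explicit non-default alternative to binary-mask functional metrics:
#' each lung voxel contributes in proportion to its SPECT activity. The
#' weighted mean dose is sum(activity * dose) / sum(activity) over the
#' lung, and the weighted Vx is the percentage of total lung activity
#' located in voxels at or above `x` Gy.
#'
#' @param dose `image_grid` of dose (Gy).
#' @param activity `image_grid` of SPECT counts.
#' @param lung `binary_mask` of anatomical lung.
#' @param x Vx threshold in Gy; default 20.
#' @return One-row tibble with `fMLD` (Gy) and `fVx` (%).
#' @export
activity_weighted_metrics <- function(dose, activity, lung, x = 20) {
  stop_if_misaligned(dose, lung, "dose and lung")
  stop_if_misaligned(activity, lung, "activity and lung")
  w <- activity$values[lung$values]
  d <- dose$values[lung$values]
  if (sum(w) <= 0) abort("zero total activity within lung.")
  tibble(
    fMLD = sum(w * d) / sum(w),
    fVx = 100 * sum(w[d >= x]) / sum(w)
  )
}

#' Write a DVH curve to CSV
#'
#' Columns `dose_gy`, `volume_pct`, `mask_label`, full precision.
#'
#' @param dvh tibble from [cumulative_dvh()].
#' @param path output file.
#' @export
write_dvh_csv <- function(dvh, path) {
  write.csv(as.data.frame(dvh), path, row.names = FALSE)
  invisible(path)
}
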