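#' Segment functional lung from SPECT activity
#'
#' Defines perfusion- or ventilation-functional lung as the lung voxels
#' whose SPECT activity reaches a stated fraction (default 30%) of the
#' reference maximum activity. The reference maximum is taken *within the
#' lung mask*, not the whole field of view, so injection-site or tracheal
#' hot spots cannot dominate the reference. The complement within the lung
#' is non-functional lung. Because the threshold is relative, the
#' segmentation is invariant to rescaling of the activity map.
#'
#' The boundary rule is closed by default (activity >= threshold is
#' included), which makes the uniform-activity case degenerate to the full
#' lung; `boundary = "strict"` switches to a strict inequality. An optional
#' robust reference (`reference = "quantile"`, default 99th percentile
#' within lung) guards against single-voxel hot spots; the default is the
#' strict maximum.
#'
#' @param activity `image_grid` of SPECT counts, aligned to `lung`.
#' @param lung non-empty `binary_mask` of anatomical lung.
#' @param threshold_fraction fraction of the reference maximum in (0, 1];
#'   default 0.30.
#' @param modality `"perfusion"` or `"ventilation"` (recorded metadata).
#' @param boundary `"closed"` (include voxels at exactly the threshold,
#'   default) or `"strict"`.
#' @param reference `"max"` (default) or `"quantile"`.
#' @param reference_prob quantile used when `reference = "quantile"`.
#' @return A `functional_mask`: list with `mask` (`binary_mask`),
#'   `modality`, `threshold_fraction`, `boundary`, `reference_max`
#'   (counts), `lung_voxels` and `lung_volume_cm3` of the parent lung mask.
#' @examples
#' lung <- binary_mask(array(TRUE, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' act <- image_grid(array(runif(64), dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' fm <- segment_functional(act, lung, 0.3, "perfusion")
#' fm$reference_max
#' @export
segment_functional <- function(activity, lung,
                               threshold_fraction = 0.30,
                               modality = c("perfusion", "ventilation"),
                               boundary = c("closed", "strict"),
                               reference = c("max", "quantile"),
                               reference_prob = 0.99) {
  modality <- match.arg(modality)
  boundary <- match.arg(boundary)
  reference <- match.arg(reference)
  stop_if_misaligned(activity, lung, "activity and lung mask")
  if (!is.numeric(threshold_fraction) || length(threshold_fraction) != 1 ||
      threshold_fraction <= 0 || threshold_fraction > 1) {
    abort("`threshold_fraction` must be a single value in (0, 1].")
  }
  if (mask_count(lung) == 0) abort("lung mask is empty.")
  a <- activity$values[lung$values]
  ref <- if (reference == "max") max(a) else as.numeric(stats::quantile(a, reference_prob))
  if (ref <= 0) {
    abort(paste0("all-zero ", modality, " activity within lung: no functional reference."))
  }
  thr <- threshold_fraction * ref
  inc <- if (boundary == "closed") activity$values >= thr else activity$values > thr
  m <- binary_mask(inc & lung$values, lung$spacing, lung$origin)
  structure(
    list(mask = m, modality = modality,
         threshold_fraction = threshold_fraction,
         boundary = boundary,
         reference_max = ref,
         lung_voxels = mask_count(lung),
         lung_volume_cm3 = mask_volume(lung)),
    class = "functional_mask"
  )
}

#' @export
print.functional_mask <- function(x, ...) {
  cat("<functional_mask> ", x$modality, ", threshold ",
      x$threshold_fraction * 100, "% of reference max ",
      signif(x$reference_max, 5), " counts (", x$boundary, ")\n  ",
      mask_count(x$mask), " / ", x$lung_voxels, " lung voxels functional (",
      signif(100 * mask_count(x$mask) / x$lung_voxels, 4), "%)\n", sep = "")
  invisible(x)
}

as_mask <- function(x) {
  if (inherits(x, "functional_mask")) x$mask else x
}

#' V/Q mismatch decomposition of two functional masks
#'
#' Splits the union of perfusion- and ventilation-functional lung into
#' matched (Q and V), perfusion-only (Q without V: the classic COPD-type
#' mismatch of visible perfusion with absent ventilation) and
#' ventilation-only regions, reporting absolute volumes and fractions of
#' the parent lung volume.
#'
#' @param q_func,v_func `functional_mask` objects derived from the same
#'   lung mask (perfusion and ventilation respectively).
#' @return A tibble with columns `region` (`matched`, `q_only`, `v_only`),
#'   `volume_cm3` and `fraction_of_lung`.
#' @export
mismatch_report <- function(q_func, v_func) {
  q <- as_mask(q_func); v <- as_mask(v_func)
  stop_if_misaligned(q, v, "Q and V functional masks")
  if (!isTRUE(all.equal(q_func$lung_volume_cm3, v_func$lung_volume_cm3))) {
    abort("Q and V functional masks derive from different lung masks.")
  }
  vol <- function(arr) sum(arr) * prod(q$spacing) / 1000
  vols <- c(matched = vol(q$values & v$values),
            q_only = vol(q$values & !v$values),
            v_only = vol(!q$values & v$values))
  tibble(
    region = names(vols),
    volume_cm3 = unname(vols),
    fraction_of_lung = unname(vols) / q_func$lung_volume_cm3
  )
}
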