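#' Tidy a Spearman correlation result
#'
#' @param x an `fl_spearman` from [spearman_cor()].
#' @param ... unused.
#' @return one-row tibble with `r`, `p`, `n`, `p_method`.
#' @method tidy fl_spearman
#' @export
tidy.fl_spearman <- function(x, ...) {
  tibble(r = x$r, p = x$p, n = x$n, p_method = x$p_method)
}

#' @rdname tidy.fl_spearman
#' @method glance fl_spearman
#' @export
glance.fl_spearman <- function(x, ...) tidy(x)

#' Tidy a functional mask
#'
#' @param x a `functional_mask` from [segment_functional()].
#' @param ... unused.
#' @return one-row tibble summarizing the segmentation: modality,
#'   threshold, reference maximum, functional voxel count/volume and the
#'   functional fraction of lung.
#' @method tidy functional_mask
#' @export
tidy.functional_mask <- function(x, ...) {
  tibble(
    modality = x$modality,
    threshold_fraction = x$threshold_fraction,
    boundary = x$boundary,
    reference_max = x$reference_max,
    functional_voxels = mask_count(x$mask),
    functional_volume_cm3 = mask_volume(x$mask),
    fraction_of_lung = mask_count(x$mask) / x$lung_voxels
  )
}

#' One-line summaries of result tables
#'
#' `glance()` on a subgroup correlation table returns one row per stratum
#' (sample size, dominance label, strongest metric).
#'
#' @param x an `fl_subgroup_table` from [subgroup_correlations()].
#' @param ... unused.
#' @method glance fl_subgroup_table
#' @export
glance.fl_subgroup_table <- function(x, ...) {
  x |>
    group_by(.data$subgroup) |>
    summarise(
      n = max(.data$n),
      dominance = .data$dominance[1],
      best_metric = if (all(is.na(.data$r))) NA_character_
                    else .data$metric[which.max(abs(.data$r))],
      .groups = "drop"
    )
}
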