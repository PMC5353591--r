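#' Volumetric scalar grids and binary masks
#'
#' `image_grid()` wraps a 3D numeric array (dose in Gy or SPECT activity in
#' counts) together with its voxel geometry; `binary_mask()` does the same
#' for a 3D logical array. Geometry follows one fixed convention: voxel
#' indices are 0-based in world-coordinate formulas, axes are ordered
#' (x, y, z), and `origin` is the position (mm) of the *center* of voxel
#' (0, 0, 0) in the shared patient frame. All downstream dose-volume
#' computation assumes grids sharing a frame have been co-registered
#' upstream.
#'
#' @param values 3D numeric array (`image_grid`) or array coercible to
#'   logical (`binary_mask`). Must be finite; grids must be non-negative
#'   (dose and activity are physically non-negative).
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, mm position of the center of voxel
#'   (0,0,0). Default `c(0, 0, 0)`.
#' @return An object of class `image_grid` or `binary_mask`: a list with
#'   elements `values`, `spacing`, `origin`.
#' @examples
#' g <- image_grid(array(1, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' m <- binary_mask(array(TRUE, dim = c(4, 4, 4)), spacing = c(2, 2, 2))
#' mask_volume(m)
#' @export
image_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  check_geometry_args(values, spacing, origin)
  if (!is.numeric(values)) {
    abort("`values` must be a numeric 3D array.")
  }
  if (any(!is.finite(values))) {
    abort("`values` contains non-finite entries; repair or reject upstream.")
  }
  if (any(values < 0)) {
    abort("`values` must be non-negative (dose in Gy or activity counts).")
  }
  structure(
    list(values = values, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "image_grid"
  )
}

#' @rdname image_grid
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  check_geometry_args(values, spacing, origin)
  if (is.numeric(values)) {
    if (any(!is.finite(values)) || any(!(values %in% c(0, 1)))) {
      abort("numeric mask `values` must contain only 0 and 1.")
    }
    values <- array(values != 0, dim = dim(values))
  }
  if (!is.logical(values)) {
    abort("`values` must be a logical (or 0/1 numeric) 3D array.")
  }
  if (anyNA(values)) abort("mask `values` contains NA.")
  structure(
    list(values = values, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "binary_mask"
  )
}

check_geometry_args <- function(values, spacing, origin) {
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array.")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive finite values (mm).")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    abort("`origin` must be three finite values (mm).")
  }
  invisible(TRUE)
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      "  range [", signif(min(x$values), 5), ", ", signif(max(x$values), 5), "]\n",
      sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, ", sum(x$values), " voxels set (",
      signif(mask_volume(x), 5), " cm^3)\n", sep = "")
  invisible(x)
}

grid_shape <- function(x) dim(x$values)

#' Check that two volumes share one voxel geometry
#'
#' A pure predicate: `TRUE` iff the shapes are equal, spacings agree within
#' 1e-6 mm per axis and origins within 1e-3 mm per axis. The tolerances
#' absorb file-format round-tripping noise without hiding real
#' misregistration; callers that require alignment raise an error when the
#' predicate is false (see [stop_if_misaligned()]).
#'
#' @param a,b `image_grid` or `binary_mask` objects.
#' @return `TRUE` or `FALSE`.
#' @export
validate_alignment <- function(a, b) {
  tol <- fl_tolerances()
  identical(grid_shape(a), grid_shape(b)) &&
    all(abs(a$spacing - b$spacing) <= tol$spacing_tol) &&
    all(abs(a$origin - b$origin) <= tol$origin_tol)
}

#' @rdname validate_alignment
#' @param what label naming the pair in the error message.
#' @export
stop_if_misaligned <- function(a, b, what = "inputs") {
  if (!validate_alignment(a, b)) {
    abort(paste0("geometry mismatch between ", what,
                 ": shapes/spacings/origins do not agree within tolerance."))
  }
  invisible(TRUE)
}

#' Voxelwise intersection of two aligned binary masks
#'
#' @param a,b aligned `binary_mask` objects.
#' @return A `binary_mask` with the logical AND of the inputs.
#' @export
mask_intersect <- function(a, b) {
  stop_if_misaligned(a, b, "masks")
  binary_mask(a$values & b$values, a$spacing, a$origin)
}

#' Volume of a binary mask in cubic centimetres
#'
#' Number of set voxels times the voxel volume (product of the spacings,
#' converted from mm^3 to cm^3).
#'
#' @param m a `binary_mask`.
#' @return volume in cm^3.
#' @export
mask_volume <- function(m) {
  sum(m$values) * prod(m$spacing) / 1000
}

mask_count <- function(m) sum(m$values)

#' Resample a grid onto the geometry of a reference grid
#'
#' Maps every reference voxel center into the source frame and interpolates.
#' `linear` interpolates trilinearly and is the default for smooth fields
#' (dose, activity); `nearest` copies the nearest source voxel and is the
#' only mode appropriate for binary masks (it preserves binarity). Reference
#' voxels whose centers fall outside the source extent are filled with 0 --
#' no activity and no dose outside the imaged volume.
#'
#' The source extent is the span of voxel centers (continuous index in
#' `[0, n-1]` per axis) for linear interpolation, widened by half a voxel
#' (`[-0.5, n-0.5]`) for nearest-neighbour lookup.
#'
#' @param source `image_grid` or `binary_mask` to resample.
#' @param reference `image_grid` or `binary_mask` supplying the target
#'   geometry.
#' @param mode `"linear"` or `"nearest"`. Masks must use `"nearest"`.
#' @return Object of the same class as `source` on the reference geometry.
#' @export
resample_to <- function(source, reference, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  is_mask <- inherits(source, "binary_mask")
  if (is_mask && mode != "nearest") {
    abort("binary masks must be resampled with mode = \"nearest\" to stay binary.")
  }
  src <- if (is_mask) array(as.numeric(source$values), dim = dim(source$values)) else source$values
  sdim <- dim(src)
  rdim <- grid_shape(reference)
  if (mode == "linear" && any(sdim < 2L)) {
    axis <- c("x", "y", "z")[which(sdim < 2L)[1]]
    abort(paste0("linear resampling needs >= 2 source voxels along every axis; ",
                 "axis ", axis, " is degenerate."))
  }

  # continuous source index of each reference voxel center, per axis
  # (axis-aligned frames make the mapping separable)
  cidx <- lapply(1:3, function(ax) {
    world <- reference$origin[ax] + (seq_len(rdim[ax]) - 1) * reference$spacing[ax]
    (world - source$origin[ax]) / source$spacing[ax]
  })

  if (mode == "nearest") {
    idx <- lapply(1:3, function(ax) {
      i <- floor(cidx[[ax]] + 0.5)
      inb <- cidx[[ax]] >= -0.5 & cidx[[ax]] <= sdim[ax] - 0.5
      list(i = pmin(pmax(i, 0), sdim[ax] - 1) + 1L, inb = inb)
    })
    out <- src[idx[[1]]$i, idx[[2]]$i, idx[[3]]$i, drop = FALSE]
    dim(out) <- rdim
    out <- zero_outside(out, lapply(idx, `[[`, "inb"))
  } else {
    lo <- lapply(1:3, function(ax) {
      i0 <- floor(cidx[[ax]])
      inb <- cidx[[ax]] >= 0 & cidx[[ax]] <= sdim[ax] - 1
      i0 <- pmin(pmax(i0, 0), sdim[ax] - 2)
      list(i0 = i0 + 1L, f = cidx[[ax]] - i0, inb = inb)
    })
    out <- array(0, dim = rdim)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- outer(outer(corner_weight(lo[[1]]$f, dx), corner_weight(lo[[2]]$f, dy)),
                 corner_weight(lo[[3]]$f, dz))
      dim(w) <- rdim
      block <- src[lo[[1]]$i0 + dx, lo[[2]]$i0 + dy, lo[[3]]$i0 + dz, drop = FALSE]
      dim(block) <- rdim
      out <- out + w * block
    }
    out <- zero_outside(out, lapply(lo, `[[`, "inb"))
  }

  if (is_mask) {
    binary_mask(array(out != 0, dim = rdim), reference$spacing, reference$origin)
  } else {
    image_grid(pmax(out, 0), reference$spacing, reference$origin)
  }
}

corner_weight <- function(f, d) if (d == 0) 1 - f else f

zero_outside <- function(arr, inb) {
  d <- dim(arr)
  keep <- outer(outer(inb[[1]], inb[[2]]), inb[[3]])
  dim(keep) <- d
  arr[!keep] <- 0
  arr
}
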