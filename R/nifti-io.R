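#' Read and write volumes as NIfTI
#'
#' Grids and masks are stored as NIfTI-1 volumes with an axis-aligned
#' affine: the rotation part must be diagonal with positive entries
#' (spacing on the diagonal, origin in the translation column). Oblique or
#' axis-flipped affines are rejected with an explicit error rather than
#' silently reinterpreted, because a half-voxel or handedness mistake in a
#' dose grid is invisible downstream. Masks are written as 0/1 integer
#' volumes.
#'
#' @param path file path, `.nii` or `.nii.gz`.
#' @return `read_image_grid()` returns an `image_grid`; `read_binary_mask()`
#'   a `binary_mask`. The writers return `path` invisibly.
#' @name nifti_io
NULL

read_nifti_geometry <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- unclass(RNifti::xform(img))
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6)) {
    abort(paste0("oblique affine in ", path,
                 ": only axis-aligned volumes are supported; resample upstream."))
  }
  if (any(diag(rot) <= 0)) {
    abort(paste0("axis-flipped affine in ", path,
                 ": negative diagonal entries are not supported."))
  }
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) {
    abort(paste0(path, " is not a 3D volume."))
  }
  attributes(vals) <- list(dim = dim(vals))  # drop RNifti image attributes
  list(values = vals, spacing = diag(rot), origin = xf[1:3, 4])
}

#' @rdname nifti_io
#' @export
read_image_grid <- function(path) {
  g <- read_nifti_geometry(path)
  if (any(!is.finite(g$values))) {
    abort(paste0(path, " contains non-finite voxel values; rejected."))
  }
  image_grid(g$values, g$spacing, g$origin)
}

#' @rdname nifti_io
#' @export
read_binary_mask <- function(path) {
  g <- read_nifti_geometry(path)
  u <- unique(as.vector(g$values))
  if (!all(u %in% c(0, 1))) {
    abort(paste0(path, " is not a 0/1 mask volume (values: ",
                 paste(utils::head(sort(u), 5), collapse = ", "), " ...)."))
  }
  binary_mask(g$values, g$spacing, g$origin)
}

#' @rdname nifti_io
#' @param x an `image_grid` or `binary_mask`.
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "binary_mask")) {
    array(as.integer(x$values), dim = dim(x$values))
  } else {
    x$values
  }
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$spacing
  aff <- diag(c(x$spacing, 1))
  aff[1:3, 4] <- x$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a DICOM RT-DOSE grid (not implemented)
#'
#' Placeholder for a DICOM RT-DOSE import path. The supported input format
#' is NIfTI; convert RT-DOSE exports (applying the DoseGridScaling factor)
#' with an external tool such as plastimatch or dcm2niix, then load with
#' [read_image_grid()].
#'
#' @param path DICOM file path (unused).
#' @export
read_dicom_rt_dose <- function(path) {
  abort(paste0(
    "DICOM RT-DOSE reading is not implemented. Convert ", path,
    " to NIfTI (applying DoseGridScaling) with e.g. plastimatch or dcm2niix, ",
    "then use read_image_grid()."
  ))
}
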