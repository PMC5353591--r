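#' Specification for a digital thorax phantom
#'
#' Describes everything needed to build a co-registered dose + V/Q
#' activity + lung-mask bundle: grid geometry, two-ellipsoid lung
#' anatomy, a dose model made of Gaussian or box "beam" fields with a
#' stated peak (the clinical prescription range is 60-66 Gy at 2
#' Gy/fraction), and a per-modality activity model -- a baseline count
#' level with multiplicative lognormal noise, reduced to a residual
#' fraction inside listed defect regions. A ventilation-only defect with
#' a small residual emulates the COPD-type V/Q mismatch of absent
#' ventilation with preserved perfusion.
#'
#' The default geometry (40 x 40 x 30 voxels at 4 x 4 x 5 mm) is an
#' invented SPECT-like resolution; the source study reports none.
#'
#' @param shape,spacing,origin grid geometry (voxels; mm; mm).
#' @param lungs list of ellipsoids, each `list(center =, radii =)` in mm
#'   (world frame); their union is the lung mask.
#' @param beams list of dose fields: `list(type = "gaussian"|"box",
#'   center =, sigma_or_halfwidth =, peak_gy =)`.
#' @param q_activity,v_activity `list(baseline =, noise_cv =, defects =
#'   list(list(center =, radii =, residual =), ...))`; `residual` in
#'   \[0, 1).
#' @param seed integer seed making the phantom reproducible.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(40, 40, 30),
                         spacing = c(4, 4, 5),
                         origin = c(0, 0, 0),
                         lungs = list(
                           list(center = c(50, 80, 75), radii = c(34, 48, 60)),
                           list(center = c(110, 80, 75), radii = c(34, 48, 60))
                         ),
                         beams = list(
                           list(type = "gaussian", center = c(80, 80, 75),
                                sigma_or_halfwidth = c(30, 30, 40), peak_gy = 62)
                         ),
                         q_activity = list(baseline = 100, noise_cv = 0.15, defects = list()),
                         v_activity = list(baseline = 100, noise_cv = 0.15, defects = list()),
                         seed = 1L) {
  if (any(shape < 1) || any(spacing <= 0)) abort("non-positive grid specification.")
  for (b in beams) if (b$peak_gy <= 0) abort("beam peak dose must be > 0 Gy.")
  for (act in list(q_activity, v_activity)) {
    for (d in act$defects) {
      if (d$residual < 0 || d$residual >= 1) {
        abort("defect residual-activity fraction must be in [0, 1).")
      }
    }
  }
  structure(list(shape = as.integer(shape), spacing = spacing, origin = origin,
                 lungs = lungs, beams = beams,
                 q_activity = q_activity, v_activity = v_activity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# world coordinates of voxel centers, one matrix row per voxel (x fastest)
voxel_centers <- function(shape, spacing, origin) {
  ax <- lapply(1:3, function(i) origin[i] + (seq_len(shape[i]) - 1) * spacing[i])
  list(
    x = rep(ax[[1]], times = shape[2] * shape[3]),
    y = rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
    z = rep(ax[[3]], each = shape[1] * shape[2])
  )
}

inside_ellipsoid <- function(ctr, center, radii) {
  ((ctr$x - center[1]) / radii[1])^2 +
    ((ctr$y - center[2]) / radii[2])^2 +
    ((ctr$z - center[3]) / radii[3])^2 <= 1
}

#' Generate a digital thorax phantom
#'
#' Builds the four mutually aligned volumes described by a
#' [phantom_spec()]: non-negative dose with the stated beam peaks, V and
#' Q activity maps (baseline x lognormal noise, times the residual
#' fraction inside each defect, zero outside the lung), and the
#' two-ellipsoid lung mask. Deterministic given the spec's seed.
#'
#' @param spec a `phantom_spec`.
#' @return `list(dose, q_activity, v_activity, lung)`.
#' @export
generate_phantom <- function(spec) {
  shape <- spec$shape
  ctr <- voxel_centers(shape, spec$spacing, spec$origin)
  lung_v <- Reduce(`|`, lapply(spec$lungs, function(e) inside_ellipsoid(ctr, e$center, e$radii)))
  lung <- binary_mask(array(lung_v, dim = shape), spec$spacing, spec$origin)
  if (mask_count(lung) == 0) abort("lung ellipsoids produce an empty mask on this grid.")

  dose_v <- rep(0, prod(shape))
  for (b in spec$beams) {
    fld <- if (b$type == "gaussian") {
      b$peak_gy * exp(-0.5 * (((ctr$x - b$center[1]) / b$sigma_or_halfwidth[1])^2 +
                              ((ctr$y - b$center[2]) / b$sigma_or_halfwidth[2])^2 +
                              ((ctr$z - b$center[3]) / b$sigma_or_halfwidth[3])^2))
    } else {
      b$peak_gy * (abs(ctr$x - b$center[1]) <= b$sigma_or_halfwidth[1] &
                   abs(ctr$y - b$center[2]) <= b$sigma_or_halfwidth[2] &
                   abs(ctr$z - b$center[3]) <= b$sigma_or_halfwidth[3])
    }
    dose_v <- pmax(dose_v, fld)
  }
  dose <- image_grid(array(dose_v, dim = shape), spec$spacing, spec$origin)

  build_activity <- function(act, stream_offset) {
    vals <- local_seed(spec$seed + stream_offset, {
      n <- prod(shape)
      sdlog <- sqrt(log(1 + act$noise_cv^2))
      act$baseline * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
    })
    for (d in act$defects) {
      inside <- inside_ellipsoid(ctr, d$center, d$radii)
      if (any(inside & !lung_v)) abort("activity defect region extends outside the lung.")
      vals[inside] <- vals[inside] * d$residual
    }
    vals[!lung_v] <- 0
    image_grid(array(vals, dim = shape), spec$spacing, spec$origin)
  }

  list(dose = dose,
       q_activity = build_activity(spec$q_activity, 1L),
       v_activity = build_activity(spec$v_activity, 2L),
       lung = lung)
}
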