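#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline with its default:
#' the relative segmentation threshold (30% of maximum activity), the Vx
#' dose level (20 Gy), the DVH bin width (0.1 Gy), the Vx boundary rule,
#' the functional-metric mode, the dominance-label equivalence width
#' (0.05 on mean |r|), the p-value method and, for permutation p-values,
#' the permutation count and seed. Unknown or out-of-range values are
#' rejected.
#'
#' @param threshold_fraction segmentation threshold in (0, 1]; default 0.30.
#' @param vx_dose_gy Vx dose level in Gy >= 0; default 20.
#' @param dvh_bin_width_gy DVH bin width in Gy > 0; default 0.1.
#' @param vx_inequality `"ge"` or `"gt"`; default `"ge"`.
#' @param segment_boundary `"closed"` or `"strict"`; default `"closed"`.
#' @param functional_mode `"binary_mask"` or `"activity_weighted"`;
#'   default `"binary_mask"`.
#' @param dominance_epsilon equivalence width; default 0.05.
#' @param p_method `"t_approx"` or `"permutation"`.
#' @param n_perm permutation count; default 10000.
#' @param seed integer seed governing all randomness in a run.
#' @return a `run_config` list.
#' @export
run_config <- function(threshold_fraction = 0.30,
                       vx_dose_gy = 20,
                       dvh_bin_width_gy = 0.1,
                       vx_inequality = c("ge", "gt"),
                       segment_boundary = c("closed", "strict"),
                       functional_mode = c("binary_mask", "activity_weighted"),
                       dominance_epsilon = 0.05,
                       p_method = c("t_approx", "permutation"),
                       n_perm = 10000,
                       seed = 1L) {
  vx_inequality <- match.arg(vx_inequality)
  segment_boundary <- match.arg(segment_boundary)
  functional_mode <- match.arg(functional_mode)
  p_method <- match.arg(p_method)
  stopifnot_range <- function(v, lo, hi, name, lo_open = FALSE) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (if (lo_open) v <= lo else v < lo) || v > hi) {
      abort(paste0("`", name, "` out of range."))
    }
  }
  stopifnot_range(threshold_fraction, 0, 1, "threshold_fraction", lo_open = TRUE)
  stopifnot_range(vx_dose_gy, 0, Inf, "vx_dose_gy")
  stopifnot_range(dvh_bin_width_gy, 0, Inf, "dvh_bin_width_gy", lo_open = TRUE)
  stopifnot_range(dominance_epsilon, 0, 1, "dominance_epsilon", lo_open = TRUE)
  stopifnot_range(n_perm, 1, Inf, "n_perm")
  structure(list(
    threshold_fraction = threshold_fraction,
    vx_dose_gy = vx_dose_gy,
    dvh_bin_width_gy = dvh_bin_width_gy,
    vx_inequality = vx_inequality,
    segment_boundary = segment_boundary,
    functional_mode = functional_mode,
    dominance_epsilon = dominance_epsilon,
    p_method = p_method,
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a configuration file over the defaults
#'
#' Reads a JSON (or YAML, by extension) mapping, validates it strictly --
#' unknown keys and out-of-range values are errors naming the key -- and
#' merges it over the [run_config()] defaults.
#'
#' @param path config file (`.json`, `.yaml`/`.yml`).
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs require the yaml package; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Write the effective configuration as JSON
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat("  ", k, ": ", as.character(x[[k]]), "\n", sep = "")
  invisible(x)
}
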