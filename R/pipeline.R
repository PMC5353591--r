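cohort_csv_columns <- function() {
  c("patient_id", "V20", "MLD", "Q_V20", "Q_MLD", "V_V20", "V_MLD",
    "sex", "age_years", "histology", "stage", "location", "copd", "pft",
    "chemo", "rilt_grade")
}

#' Read and write the per-patient cohort CSV
#'
#' The cohort schema is fixed: columns `patient_id, V20, MLD, Q_V20,
#' Q_MLD, V_V20, V_MLD, sex, age_years, histology, stage, location,
#' copd, pft, chemo, rilt_grade` (metrics in % and Gy). `read_cohort_csv()`
#' aborts naming any missing column and derives `age_group` from
#' `age_years` (70 is the cut).
#'
#' @param cohort tibble with at least the schema columns.
#' @param path CSV file path.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- cohort_csv_columns()
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  write.csv(as.data.frame(cohort[, cols]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_csv_columns(), names(df))
  if (length(missing)) {
    abort(paste0("cohort CSV is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- as_tibble(df)
  out$age_group <- ifelse(out$age_years < 70, "<70", ">70")
  out
}

segment_pair <- function(bundle, config) {
  q <- segment_functional(bundle$q_activity, bundle$lung,
                          config$threshold_fraction, "perfusion",
                          boundary = config$segment_boundary)
  v <- segment_functional(bundle$v_activity, bundle$lung,
                          config$threshold_fraction, "ventilation",
                          boundary = config$segment_boundary)
  list(q = q, v = v)
}

#' Per-patient dose-volume analysis of one phantom or image bundle
#'
#' Segments both functional regions and returns the metric row plus the
#' three DVH curves (anatomical, Q-functional, V-functional).
#'
#' @param bundle `list(dose, q_activity, v_activity, lung)`.
#' @param config a [run_config()].
#' @param patient_id identifier placed in the metric row.
#' @return `list(metrics = one-row tibble, dvh = tibble of three stacked
#'   curves, q_func = , v_func = )`.
#' @export
analyze_bundle <- function(bundle, config = run_config(), patient_id = "case") {
  fm <- segment_pair(bundle, config)
  metrics <- compute_metrics(bundle$dose, bundle$lung, fm$q, fm$v,
                             x = config$vx_dose_gy,
                             inequality = config$vx_inequality,
                             patient_id = patient_id)
  dvh <- bind_rows(
    cumulative_dvh(bundle$dose, bundle$lung, config$dvh_bin_width_gy, "lung"),
    cumulative_dvh(bundle$dose, fm$q, config$dvh_bin_width_gy, "Q-functional"),
    cumulative_dvh(bundle$dose, fm$v, config$dvh_bin_width_gy, "V-functional")
  )
  list(metrics = metrics, dvh = dvh, q_func = fm$q, v_func = fm$v)
}

#' Run the full dosimetry-plus-cohort pipeline and write its artifacts
#'
#' End-to-end composition: for every image bundle, functional
#' segmentation, DVH curves and the six-metric record; for the cohort
#' table, the characteristic comparison (table1.csv) and the stratified
#' correlation table with dominance labels (table2.csv). A manifest JSON
#' records the configuration, seed, package version and the MD5 of every
#' written artifact, so a rerun can be checked for bit-identity. Outputs
#' are written to a temporary quarantine directory first and promoted to
#' `out_dir` only if every stage succeeds; a failed stage leaves the
#' partial outputs quarantined and aborts with the patient and stage
#' named.
#'
#' @param bundles named list of image bundles (may be empty).
#' @param cohort cohort tibble (see [write_cohort_csv()]) or `NULL`.
#' @param out_dir output directory, created if needed.
#' @param config a [run_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(bundles = list(), cohort = NULL, out_dir,
                         config = run_config()) {
  stage_dir <- file.path(tempfile("funlung-quarantine-"))
  dir.create(stage_dir, recursive = TRUE)
  artifacts <- character()

  emit_csv <- function(df, name) {
    p <- file.path(stage_dir, name)
    write.csv(as.data.frame(df), p, row.names = FALSE)
    artifacts <<- c(artifacts, name)
    p
  }

  metrics_rows <- list()
  for (id in names(bundles)) {
    res <- tryCatch(
      analyze_bundle(bundles[[id]], config, patient_id = id),
      error = function(e) {
        abort(paste0("pipeline failed for patient '", id,
                     "' during per-patient analysis (partial outputs in ",
                     stage_dir, "): ", conditionMessage(e)))
      }
    )
    emit_csv(res$dvh, paste0("dvh_", id, ".csv"))
    metrics_rows[[id]] <- res$metrics
  }
  if (length(metrics_rows)) {
    emit_csv(bind_rows(metrics_rows), "metrics.csv")
  }

  if (!is.null(cohort)) {
    t1 <- tryCatch(compare_characteristics(cohort), error = function(e) {
      abort(paste0("pipeline failed during characteristic comparison: ",
                   conditionMessage(e)))
    })
    t2 <- tryCatch(
      subgroup_correlations(cohort, epsilon = config$dominance_epsilon,
                            p_method = config$p_method,
                            n_perm = config$n_perm, seed = config$seed),
      error = function(e) {
        abort(paste0("pipeline failed during subgroup correlation: ",
                     conditionMessage(e)))
      }
    )
    emit_csv(t1, "table1.csv")
    emit_csv(t2, "table2.csv")
    emit_csv(cohort[, intersect(cohort_csv_columns(), names(cohort))], "cohort.csv")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("funlung")),
    config = unclass(config),
    n_bundles = length(bundles),
    n_patients = if (is.null(cohort)) 0L else nrow(cohort),
    artifact_md5 = as.list(tools::md5sum(file.path(stage_dir, artifacts)))
  )
  names(manifest$artifact_md5) <- artifacts
  jsonlite::write_json(manifest, file.path(stage_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, "manifest.json")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(file.path(stage_dir, artifacts), file.path(out_dir, artifacts),
                  overwrite = TRUE)
  if (!all(ok)) abort("failed to promote artifacts from quarantine.")
  unlink(stage_dir, recursive = TRUE)
  invisible(manifest)
}
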