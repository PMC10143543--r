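# Delimited-text IO for the two canonical recording layouts and the cohort
# manifest. Dialect: comma-separated, "." decimal, mandatory header row.

#' Write / read an insole recording as CSV
#'
#' The canonical 51-column layout: `time_s`, then per foot (left block, right
#' block) `p01..p16`, `acc_x/y/z`, `gyr_x/y/z`, `cop_x`, `cop_y`,
#' `total_force`.
#'
#' @param recording an [insole_recording()].
#' @param path file path.
#' @return `write_insole_csv` the path invisibly; `read_insole_csv` an
#'   [insole_recording()].
#' @export
write_insole_csv <- function(recording, path) {
  stopifnot(inherits(recording, "insole_recording"))
  data.table::fwrite(recording$data, path)
  invisible(path)
}

#' @rdname write_insole_csv
#' @export
read_insole_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path)
  if (ncol(d) != length(INSOLE_COLS))
    stop(sprintf("%s: expected the 51-column insole layout, found %d columns",
                 path, ncol(d)), call. = FALSE)
  if (nrow(d) == 0L) stop(path, ": no samples", call. = FALSE)
  if (!identical(names(d), INSOLE_COLS))
    stop(path, ": column names do not match the canonical insole layout",
         call. = FALSE)
  check_numeric_finite(d, path)
  if (any(diff(d$time_s) <= 0))
    stop(sprintf("%s: non-monotone timestamp at line %d", path,
                 which(diff(d$time_s) <= 0)[1L] + 2L), call. = FALSE)
  insole_recording(d, fs = 1 / stats::median(diff(d$time_s)))
}

#' Write / read an ankle-IMU recording as CSV
#'
#' Ten columns: `unix_time_s`, `acc_x/y/z` (g), `gyr_x/y/z` (dps),
#' `mag_x/y/z` (T). Placement is not stored in the file; supply it on read.
#'
#' @param recording an [imu_recording()].
#' @param path file path.
#' @param placement `"left_ankle"` or `"right_ankle"` (read only).
#' @return `write_imu_csv` the path invisibly; `read_imu_csv` an
#'   [imu_recording()].
#' @export
write_imu_csv <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  data.table::fwrite(recording$data, path)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, placement = c("left_ankle", "right_ankle")) {
  placement <- match.arg(placement)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path)
  if (ncol(d) != length(IMU_COLS))
    stop(sprintf("%s: expected the 10-column IMU layout, found %d columns",
                 path, ncol(d)), call. = FALSE)
  if (nrow(d) == 0L) stop(path, ": no samples", call. = FALSE)
  if (!identical(names(d), IMU_COLS))
    stop(path, ": column names do not match the canonical IMU layout",
         call. = FALSE)
  check_numeric_finite(d, path)
  if (any(diff(d$unix_time_s) <= 0))
    stop(sprintf("%s: non-monotone timestamp at line %d", path,
                 which(diff(d$unix_time_s) <= 0)[1L] + 2L), call. = FALSE)
  imu_recording(d, placement = placement,
                fs = 1 / stats::median(diff(d$unix_time_s)))
}

check_numeric_finite <- function(d, path) {
  for (cn in names(d)) {
    x <- d[[cn]]
    if (!is.numeric(x))
      stop(sprintf("%s: column '%s' is not numeric", path, cn), call. = FALSE)
    bad <- which(!is.finite(x))
    if (length(bad))
      stop(sprintf("%s: non-finite value in column '%s' at row %d", path, cn,
                   bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write / read a cohort manifest
#'
#' @param manifest the manifest data.frame from [generate_cohort()].
#' @param path file path.
#' @return the path invisibly / the manifest data.frame.
#' @export
write_manifest_csv <- function(manifest, path) {
  data.table::fwrite(manifest, path)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.data.frame(data.table::fread(path))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> extract (both systems) -> compare -> classify and
#' writes every table under `out_dir`: the manifest, the two per-session
#' feature tables, the cross-system agreement report and the classification
#' report. All randomness flows from `seed` (overriding the spec's).
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if absent).
#' @param seed master seed; defaults to `spec$seed`.
#' @param stages which stages to run (later stages need the earlier ones).
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(spec = simulation_spec(), out_dir, seed = spec$seed,
                         stages = c("extract", "compare", "classify")) {
  spec$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- extract_cohort_features(spec)
  write_manifest_csv(feats$manifest, file.path(out_dir, "manifest.csv"))
  data.table::fwrite(feats$insole, file.path(out_dir, "insole_features.csv"))
  data.table::fwrite(feats$imu, file.path(out_dir, "imu_features.csv"))
  res <- list(features = feats)
  if ("compare" %in% stages) {
    agr <- compare_systems(feats$insole, feats$imu, feats$manifest)
    data.table::fwrite(agr$table, file.path(out_dir, "agreement_report.csv"))
    res$agreement <- agr
  }
  if ("classify" %in% stages) {
    reports <- lapply(c(insole = "insole", imu = "imu", combined = "combined"),
      function(set) {
        fm <- build_feature_table(feats$insole, feats$imu, feats$manifest,
                                  set = set)
        evaluate_classifiers(fm, seed = spec$seed)
      })
    tab <- do.call(rbind, lapply(names(reports), function(nm) {
      m <- reports[[nm]]$metrics
      cbind(feature_set = nm, m)
    }))
    data.table::fwrite(tab, file.path(out_dir, "classification_report.csv"))
    res$classification <- reports
  }
  cfg <- list(seed = spec$seed, n_subjects = spec$n_subjects,
              cycles_per_session = spec$cycles_per_session,
              effect_scale = spec$effect_scale)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run_config.json"))
  invisible(res)
}
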