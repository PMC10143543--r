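# Canonical channel layouts of the two recording formats.
# Insole: 51 columns = time + 25 channels per foot (left block then right).
insole_foot_cols <- function(prefix) {
  paste0(prefix, c(sprintf("p%02d", 1:16),
                   "acc_x", "acc_y", "acc_z",
                   "gyr_x", "gyr_y", "gyr_z",
                   "cop_x", "cop_y", "total_force"))
}
INSOLE_COLS <- c("time_s", insole_foot_cols("l_"), insole_foot_cols("r_"))
IMU_COLS <- c("unix_time_s",
              "acc_x", "acc_y", "acc_z",
              "gyr_x", "gyr_y", "gyr_z",
              "mag_x", "mag_y", "mag_z")

#' Construct an instrumented-insole recording
#'
#' A thin validated container around the canonical 51-column table:
#' `time_s` (100 Hz), then per foot (left block first) 16 pressure channels
#' `p01..p16` (N/cm^2), 3-axis acceleration (g), 3-axis angular velocity
#' (dps), centre of pressure `cop_x`/`cop_y` (dimensionless, in [-0.5, 0.5])
#' and `total_force` (N).
#'
#' @param data a data.frame/data.table with exactly the canonical columns.
#' @param fs nominal sampling rate in Hz.
#' @return object of class `insole_recording`.
#' @export
insole_recording <- function(data, fs = 100) {
  data <- data.table::as.data.table(data)
  if (!identical(names(data), INSOLE_COLS))
    stop(sprintf("insole recording must have the %d canonical columns (got %d)",
                 length(INSOLE_COLS), ncol(data)), call. = FALSE)
  if (nrow(data) == 0L) stop("insole recording has no samples", call. = FALSE)
  if (any(diff(data$time_s) <= 0))
    stop("insole timestamps must strictly increase", call. = FALSE)
  structure(list(data = data, fs = fs), class = "insole_recording")
}

#' Construct an ankle-IMU recording
#'
#' Ten canonical columns: `unix_time_s` (59.5 Hz nominal), 3-axis
#' acceleration (g), 3-axis angular velocity (dps), 3-axis magnetic field (T).
#'
#' @param data a data.frame/data.table with the canonical columns.
#' @param placement `"left_ankle"` or `"right_ankle"`.
#' @param fs nominal sampling rate in Hz.
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(data, placement = c("left_ankle", "right_ankle"),
                          fs = 59.5) {
  placement <- match.arg(placement)
  data <- data.table::as.data.table(data)
  if (!identical(names(data), IMU_COLS))
    stop(sprintf("IMU recording must have the %d canonical columns (got %d)",
                 length(IMU_COLS), ncol(data)), call. = FALSE)
  if (nrow(data) == 0L) stop("IMU recording has no samples", call. = FALSE)
  if (any(diff(data$unix_time_s) <= 0))
    stop("IMU timestamps must strictly increase", call. = FALSE)
  structure(list(data = data, placement = placement, fs = fs),
            class = "imu_recording")
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("Insole recording: %d samples @ %g Hz (%.1f s), 51 channels\n",
              nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording (%s): %d samples @ %g Hz (%.1f s)\n",
              x$placement, nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

# Pressure matrix (N x 16) of one foot ("l" or "r").
foot_pressure <- function(rec, foot) {
  as.matrix(rec$data[, paste0(foot, "_", sprintf("p%02d", 1:16)), with = FALSE])
}
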