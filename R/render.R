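# Trapezoidal contact profile in [0, 1]. The rising edge is placed so the
# profile crosses `f_on` of its plateau exactly at the contact-on time, and the
# falling edge so it crosses `f_off` exactly at the contact-off time. The
# default fractions mirror the detector's auto thresholds (5% on, 4% = 5% with
# a 20% hysteresis band off), which is what makes noise-free threshold
# crossings land on the ground-truth event times to sub-sample accuracy.
contact_profile <- function(t, on, off, ramp, f_on = 0.05, f_off = 0.04) {
  s0 <- on - f_on * ramp
  s1 <- off - (1 - f_off) * ramp
  rise <- (t - s0) / ramp
  fall <- (s1 + ramp - t) / ramp
  pmax(0, pmin(1, rise, fall))
}

add_intervals <- function(t, on, off, ramp) {
  v <- numeric(length(t))
  keep <- off > 0
  for (i in which(keep)) v <- v + contact_profile(t, on[i], off[i], ramp)
  v
}

gauss_spikes <- function(t, centers, amp, sigma) {
  v <- numeric(length(t))
  for (ct in centers) {
    idx <- which(abs(t - ct) < 5 * sigma)
    if (length(idx)) v[idx] <- v[idx] + amp * exp(-(t[idx] - ct)^2 / (2 * sigma^2))
  }
  v
}

# Per-region contact intervals implied by a timeline, including the partial
# leading stance (events of the virtual preceding cycle, shifted back by the
# first cycle's duration) and the trailing right heel strike, so that the
# detector sees complete edges for every exposed cycle.
contact_intervals <- function(timeline) {
  cy <- timeline$cycles
  n <- nrow(cy)
  if (n == 0L) return(NULL)
  d1 <- cy$t01_next[1L] - cy$t01[1L]
  dn <- cy$t01_next[n] - cy$t01[n]
  list(
    r_heel = cbind(on = c(cy$t01[1L] - d1, cy$t01, cy$t01_next[n]),
                   off = c(cy$t04[1L] - d1, cy$t04, cy$t01_next[n] + (cy$t04[n] - cy$t01[n]))),
    r_toe  = cbind(on = c(cy$t03[1L] - d1, cy$t03, cy$t03[n] + dn),
                   off = c(cy$t06[1L] - d1, cy$t06, cy$t06[n] + dn)),
    l_heel = cbind(on = c(cy$t05[1L] - d1, cy$t05, cy$t05[n] + dn),
                   off = c(cy$t08[1L] - d1, cy$t08, cy$t08[n] + dn)),
    l_toe  = cbind(on = c(cy$t07[1L] - d1, cy$t07, cy$t07[n] + dn),
                   off = c(cy$t02[1L], cy$t02_next, cy$t02_next[n] + dn))
  )
}

#' Render a timeline into a synthetic insole recording
#'
#' Produces the canonical 51-channel, 100 Hz insole table from a ground-truth
#' timeline. Heel-group cells carry pressure exactly during each foot's
#' heel-contact interval (heel strike to heel off) and toe-group cells during
#' toe contact (toe strike to toe off), with short linear ramps aligned so
#' that relative-threshold crossings reproduce the truth event times. Total
#' force is the area-weighted sum of all cell pressures; the centre of
#' pressure advances heel-to-toe during stance. Additive Gaussian sensor
#' noise (truncated at zero pressure) is controlled by the spec.
#'
#' @param timeline a [sample_gait_timeline()] result.
#' @param spec the [simulation_spec()] used to draw it.
#' @param seed noise seed (defaults to a child of `spec$seed`).
#' @return an [insole_recording()].
#' @export
render_insole <- function(timeline, spec, seed = child_seed(spec$seed, 1L)) {
  validate_gait_timeline(timeline)
  fs <- spec$insole_fs
  cy <- timeline$cycles
  n <- nrow(cy)
  dur <- if (n > 0L) cy$t02_next[n] + spec$tail_s else spec$lead_in_s + spec$tail_s
  t <- seq.int(0L, floor(dur * fs)) / fs
  N <- length(t)
  iv <- contact_intervals(timeline)

  amp_h <- spec$peak_pressure_heel * spec$amplitude_scale
  amp_t <- spec$peak_pressure_toe * spec$amplitude_scale
  mid_sensors <- setdiff(1:16, c(spec$heel_sensors, spec$toe_sensors))

  with_seed(seed, {
    cols <- vector("list", length(INSOLE_COLS))
    names(cols) <- INSOLE_COLS
    cols$time_s <- t
    for (foot in c("l", "r")) {
      heel_prof <- if (is.null(iv)) numeric(N) else
        add_intervals(t, iv[[paste0(foot, "_heel")]][, "on"],
                      iv[[paste0(foot, "_heel")]][, "off"], spec$ramp_s)
      toe_prof <- if (is.null(iv)) numeric(N) else
        add_intervals(t, iv[[paste0(foot, "_toe")]][, "on"],
                      iv[[paste0(foot, "_toe")]][, "off"], spec$ramp_s)
      press <- matrix(0, nrow = N, ncol = 16)
      press[, spec$heel_sensors] <- heel_prof * amp_h
      press[, spec$toe_sensors] <- toe_prof * amp_t
      if (length(mid_sensors))
        press[, mid_sensors] <- 0  # mid-foot cells quiescent by default
      if (spec$pressure_noise_sd > 0)
        press <- press + matrix(stats::rnorm(N * 16, 0, spec$pressure_noise_sd), N, 16)
      press <- pmax(press, 0)
      for (j in 1:16) cols[[paste0(foot, "_", sprintf("p%02d", j))]] <- press[, j]

      heel_force <- rowSums(press[, spec$heel_sensors, drop = FALSE]) * spec$sensor_area_cm2
      toe_force <- rowSums(press[, spec$toe_sensors, drop = FALSE]) * spec$sensor_area_cm2
      cols[[paste0(foot, "_total_force")]] <- rowSums(press) * spec$sensor_area_cm2

      strikes <- if (n == 0L) numeric(0) else if (foot == "r") cy$t01 else cy$t05
      acc_noise <- spec$imu_accel_noise_sd
      cols[[paste0(foot, "_acc_x")]] <- stats::rnorm(N, 0, acc_noise)
      cols[[paste0(foot, "_acc_y")]] <- stats::rnorm(N, 0, acc_noise)
      cols[[paste0(foot, "_acc_z")]] <- 1 + gauss_spikes(t, strikes, 1.5, 0.02) +
        stats::rnorm(N, 0, acc_noise)
      for (ax in c("x", "y", "z"))
        cols[[paste0(foot, "_gyr_", ax)]] <- stats::rnorm(N, 0, spec$imu_gyro_noise_sd)

      denom <- heel_force + toe_force
      cop_y <- ifelse(denom > 1e-9, 0.3 * (toe_force - heel_force) / pmax(denom, 1e-9), 0)
      cols[[paste0(foot, "_cop_y")]] <- pmin(pmax(cop_y, -0.5), 0.5)
      cols[[paste0(foot, "_cop_x")]] <-
        pmin(pmax(stats::rnorm(N, 0, 0.01), -0.5), 0.5)
    }
    insole_recording(data.table::as.data.table(cols), fs = fs)
  })
}

#' Render a timeline into a pair of synthetic ankle-IMU recordings
#'
#' Produces left- and right-ankle 59.5 Hz recordings whose gyroscope Z axis
#' shows the canonical sagittal shank-rotation morphology: one positive
#' mid-swing lobe per stride (Hann-shaped, centred mid-swing), a deep negative
#' dip at that foot's toe-off and a shallower negative dip at its initial
#' contact (heel strike). Accelerometer magnitude spikes at initial contact.
#' Timestamps are seconds from session start on the nominal 1/59.5 s grid.
#'
#' @inheritParams render_insole
#' @return list with elements `left` and `right`, both [imu_recording()]s.
#' @export
render_imu <- function(timeline, spec, seed = child_seed(spec$seed, 2L)) {
  validate_gait_timeline(timeline)
  fs <- spec$imu_fs
  cy <- timeline$cycles
  n <- nrow(cy)
  dur <- if (n > 0L) cy$t02_next[n] + spec$tail_s else spec$lead_in_s + spec$tail_s
  t <- seq.int(0L, floor(dur * fs)) / fs
  N <- length(t)
  sigma <- 0.02

  render_foot <- function(to, ic, placement, foot_seed) {
    with_seed(foot_seed, {
      gz <- numeric(N)
      for (i in seq_along(to)) {
        ctr <- (to[i] + ic[i]) / 2
        half <- 0.3 * (ic[i] - to[i])
        idx <- which(abs(t - ctr) < half)
        if (length(idx))
          gz[idx] <- gz[idx] + spec$ms_amplitude_dps *
            cos(pi * (t[idx] - ctr) / (2 * half))^2
      }
      gz <- gz - gauss_spikes(t, to, spec$to_dip_dps, sigma) -
        gauss_spikes(t, ic, spec$ic_dip_dps, sigma)
      gz <- gz + stats::rnorm(N, 0, spec$imu_gyro_noise_sd)
      acc_z <- 1 + gauss_spikes(t, ic, 1.0, sigma) +
        stats::rnorm(N, 0, spec$imu_accel_noise_sd)
      dt <- data.table::data.table(
        unix_time_s = t,
        acc_x = stats::rnorm(N, 0, spec$imu_accel_noise_sd),
        acc_y = stats::rnorm(N, 0, spec$imu_accel_noise_sd),
        acc_z = acc_z,
        gyr_x = stats::rnorm(N, 0, spec$imu_gyro_noise_sd),
        gyr_y = stats::rnorm(N, 0, spec$imu_gyro_noise_sd),
        gyr_z = gz,
        mag_x = 2e-05 + stats::rnorm(N, 0, 1e-07),
        mag_y = stats::rnorm(N, 0, 1e-07),
        mag_z = 4e-05 + stats::rnorm(N, 0, 1e-07))
      imu_recording(dt, placement = placement, fs = fs)
    })
  }

  if (n == 0L) {
    left <- render_foot(numeric(0), numeric(0), "left_ankle", child_seed(seed, 1L))
    right <- render_foot(numeric(0), numeric(0), "right_ankle", child_seed(seed, 2L))
  } else {
    # left swing: left toe off (t02) -> left heel strike (t05), same cycle;
    # right swing: right toe off (t06) -> next right heel strike (t01')
    left <- render_foot(cy$t02, cy$t05, "left_ankle", child_seed(seed, 1L))
    right <- render_foot(cy$t06, cy$t01_next, "right_ankle", child_seed(seed, 2L))
  }
  list(left = left, right = right)
}

#' Ground-truth IMU events implied by a timeline
#'
#' Returns, per foot, the (toe-off, mid-swing, initial-contact) triples the
#' IMU renderer encodes: TO and IC are the timeline's toe-off/heel-strike
#' events, MS the midpoint of each swing (where the rendered lobe peaks).
#' Used by tests and the acceptance script to score event recovery.
#' @param timeline a `gait_timeline`.
#' @return list of data.frames `left`, `right` with columns t_to, t_ms, t_ic.
#' @export
imu_truth_events <- function(timeline) {
  cy <- timeline$cycles
  mk <- function(to, ic) data.frame(t_to = to, t_ms = (to + ic) / 2, t_ic = ic)
  list(left = mk(cy$t02, cy$t05), right = mk(cy$t06, cy$t01_next))
}
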