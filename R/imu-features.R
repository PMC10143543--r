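# Per-foot temporal quantities from a stride table. Cycle k runs IC_k ->
# IC_{k+1}; its stance is IC_k -> TO_{k+1} and its swing TO_{k+1} -> IC_{k+1},
# so stance + swing = cycle exactly by construction.
foot_temporal <- function(strides) {
  n <- nrow(strides)
  if (n < 2L)
    return(list(cycle = numeric(0), stance = numeric(0), swing = numeric(0),
                n_ic = n))
  ic <- strides$t_ic; to <- strides$t_to
  cycle <- diff(ic)
  stance <- to[-1L] - ic[-n]
  swing <- ic[-1L] - to[-1L]
  list(cycle = cycle, stance = stance, swing = swing, n_ic = n)
}

asym_index <- function(l, r) {
  if (!is.finite(l) || !is.finite(r) || (l + r) == 0) return(NA_real_)
  abs(l - r) / ((l + r) / 2)
}

# Signal energy sum(x^2) * dt over an optional time window.
signal_energy <- function(t, x2, window = NULL) {
  if (!is.null(window)) {
    keep <- t >= window[1L] & t <= window[2L]
    x2 <- x2[keep]
  }
  sum(x2) * stats::median(diff(t))
}

#' Compute single-sensor IMU gait features
#'
#' Temporal features per foot (gait cycle duration IC to next IC, stance IC
#' to next TO, swing TO to IC, cadence as cycle rate in 1/s) plus the
#' contralateral single support (one foot's single support is the other
#' foot's swing), step count (IC events, both feet), and the energy /
#' excursion / asymmetry set: total gyroscope energy (dps^2 s), cumulative
#' and per-stride-maximum accelerometer energy (g^2 s), range of shank
#' motion (deg, swing excursion of the integrated gyro Z), a normalized
#' stride-length surrogate (swing excursion times a configurable leg-length
#' factor; no exact definition is published, so it is labelled a surrogate),
#' a walking-speed proxy (stride-length surrogate x cadence), maximum
#' rotation rate, and |L-R|/mean asymmetry indices. Leg-averaged variants
#' are emitted for all per-foot features. Double support is deliberately not
#' computed: it needs both sensors simultaneously, which the single-sensor
#' feature policy excludes.
#'
#' @param left_events,right_events [detect_imu_gait_events()] results.
#' @param left_rec,right_rec the corresponding [imu_recording()]s (needed for
#'   energy/excursion features; temporal features work without them).
#' @param bout optional c(start_s, end_s) window for the energy features.
#' @param leg_length_factor dimensionless scale of the stride-length
#'   surrogate (default 0.01 per degree of swing excursion).
#' @return object of class `imu_features`: named numeric `session` vector
#'   plus per-foot stride tables.
#' @export
compute_imu_features <- function(left_events, right_events,
                                 left_rec = NULL, right_rec = NULL,
                                 bout = NULL, leg_length_factor = 0.01) {
  lt <- foot_temporal(left_events$strides)
  rt <- foot_temporal(right_events$strides)

  mfin <- function(x) if (length(x)) mean(x) else NA_real_
  sfin <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  cyc_l <- mfin(lt$cycle); cyc_r <- mfin(rt$cycle)
  cad_l <- if (is.finite(cyc_l)) 1 / cyc_l else NA_real_
  cad_r <- if (is.finite(cyc_r)) 1 / cyc_r else NA_real_

  feats <- c(
    walking_cadence = mean(c(cad_l, cad_r), na.rm = TRUE),
    cycle_duration_l = cyc_l, cycle_duration_r = cyc_r,
    cycle_duration_avg = mean(c(cyc_l, cyc_r), na.rm = TRUE),
    cycle_duration_std_l = sfin(lt$cycle), cycle_duration_std_r = sfin(rt$cycle),
    stance_l = mfin(lt$stance), stance_r = mfin(rt$stance),
    stance_pct_l = mfin(lt$stance / lt$cycle), stance_pct_r = mfin(rt$stance / rt$cycle),
    swing_l = mfin(lt$swing), swing_r = mfin(rt$swing),
    # single support of a foot = the contralateral foot's swing
    single_support_l = mfin(rt$swing), single_support_r = mfin(lt$swing),
    number_of_steps = lt$n_ic + rt$n_ic)

  foot_ext <- function(rec, ev) {
    if (is.null(rec) || nrow(ev$strides) == 0L)
      return(c(gyro_energy = NA_real_, accel_energy = NA_real_,
               accel_max_energy = NA_real_, shank_range = NA_real_,
               max_rotation = NA_real_))
    d <- rec$data
    t <- d$unix_time_s
    dt <- 1 / rec$fs
    win <- bout %||% range(t)
    keep <- t >= win[1L] & t <= win[2L]
    a2 <- d$acc_x^2 + d$acc_y^2 + d$acc_z^2
    gyro_e <- sum(d$gyr_z[keep]^2) * dt
    accel_e <- sum(a2[keep]) * dt
    ic <- ev$strides$t_ic
    stride_e <- if (length(ic) >= 2L)
      vapply(seq_len(length(ic) - 1L), function(i)
        sum(a2[t >= ic[i] & t < ic[i + 1L]]) * dt, numeric(1))
    else numeric(0)
    # swing excursion of the integrated sagittal rotation, per stride
    exc <- vapply(seq_len(nrow(ev$strides)), function(i) {
      idx <- which(t >= ev$strides$t_to[i] & t <= ev$strides$t_ic[i])
      if (length(idx) < 2L) return(NA_real_)
      ang <- pracma::cumtrapz(t[idx], d$gyr_z[idx])
      diff(range(ang))
    }, numeric(1))
    c(gyro_energy = gyro_e, accel_energy = accel_e,
      accel_max_energy = if (length(stride_e)) max(stride_e) else NA_real_,
      shank_range = mean(exc, na.rm = TRUE),
      max_rotation = max(abs(d$gyr_z[keep])))
  }
  le <- foot_ext(left_rec, left_events)
  re <- foot_ext(right_rec, right_events)

  nsl_l <- le[["shank_range"]] * leg_length_factor
  nsl_r <- re[["shank_range"]] * leg_length_factor
  speed_l <- nsl_l * cad_l
  speed_r <- nsl_r * cad_r

  feats <- c(feats,
    total_gyro_energy = mean(c(le[["gyro_energy"]], re[["gyro_energy"]])),
    cumulative_accel_energy = mean(c(le[["accel_energy"]], re[["accel_energy"]])),
    accel_max_energy = mean(c(le[["accel_max_energy"]], re[["accel_max_energy"]])),
    range_of_shank_motion = mean(c(le[["shank_range"]], re[["shank_range"]])),
    normalized_stride_length = mean(c(nsl_l, nsl_r)),
    norm_walking_speed = mean(c(speed_l, speed_r)),
    max_rotation = mean(c(le[["max_rotation"]], re[["max_rotation"]])),
    asym_cadence = asym_index(cad_l, cad_r),
    asym_contact_time = asym_index(mfin(lt$stance), mfin(rt$stance)),
    asym_walking_speed = asym_index(speed_l, speed_r),
    asym_accel_max_energy = asym_index(le[["accel_max_energy"]],
                                       re[["accel_max_energy"]]))
  structure(list(session = feats,
                 strides = list(left = left_events$strides,
                                right = right_events$strides)),
            class = "imu_features")
}

#' @export
print.imu_features <- function(x, ...) {
  s <- x$session
  cat(sprintf(paste0("IMU gait features: %d steps\n",
                     "  cycle duration %.3f s, cadence %.3f cycles/s, ",
                     "stance %.1f%% / %.1f%% (R/L)\n"),
              s[["number_of_steps"]], s[["cycle_duration_avg"]],
              s[["walking_cadence"]], 100 * s[["stance_pct_r"]],
              100 * s[["stance_pct_l"]]))
  invisible(x)
}

#' One-call IMU session extraction
#'
#' Detects walking bouts (or accepts manual ones), runs gyroscope peak
#' detection on both ankles and computes the session feature vector.
#'
#' @param left_rec,right_rec left/right ankle [imu_recording()]s.
#' @param params a [peak_params()].
#' @param bouts optional manual bout table (start_s, end_s); `NULL` uses the
#'   whole recording as one bout.
#' @param ... passed to [compute_imu_features()].
#' @return an `imu_features` object.
#' @export
extract_imu_session <- function(left_rec, right_rec, params = peak_params(),
                                bouts = NULL, ...) {
  bout <- if (!is.null(bouts) && nrow(as.data.frame(bouts)) > 0L)
    c(as.data.frame(bouts)$start_s[1L],
      as.data.frame(bouts)$end_s[nrow(as.data.frame(bouts))])
  else NULL
  lev <- detect_imu_gait_events(left_rec, params, bout)
  rev_ <- detect_imu_gait_events(right_rec, params, bout)
  compute_imu_features(lev, rev_, left_rec, right_rec, bout = bout, ...)
}
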