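#' Simulation specification for the synthetic gait generator
#'
#' Bundles every tunable of the ground-truth timeline sampler and of the two
#' signal renderers. The generator produces a shared per-cycle event timeline
#' (the eight heel/toe contact events of one full gait cycle, right heel strike
#' to right heel strike) and renders it into a 100 Hz instrumented-insole
#' recording and a pair of 59.5 Hz ankle-IMU recordings, so that both
#' extraction pipelines can be validated against the same truth.
#'
#' @param n_subjects number of simulated subjects in a cohort.
#' @param cycles_per_session mean number of complete gait cycles per walking
#'   session (at normal speed).
#' @param cycles_sd per-session SD of the cycle count (0 = deterministic).
#' @param speed_cycle_factor named multiplier of the cycle count per speed
#'   class; a fixed-distance walk takes more, shorter strides at slow speed.
#' @param mean_cycle_duration_s named numeric: mean gait-cycle duration in
#'   seconds for the three instructed speeds (`slow`, `normal`, `fast`).
#' @param cycle_cv coefficient of variation of cycle duration (dimensionless).
#' @param phase_fractions named numeric in (0,1): within-cycle position of
#'   events `t02`..`t08` as fractions of the cycle (right heel strike `t01`
#'   anchors 0). Defaults follow normative gait-phase proportions.
#' @param asymmetry baseline left/right timing asymmetry (shift of the left
#'   heel-strike fraction), dimensionless, >= 0.
#' @param event_jitter_s baseline per-event Gaussian timing jitter (s).
#' @param lr_sd_s baseline jitter SD (s) of the loading-response events
#'   (`t02`, `t06`), inflated by impairment.
#' @param ps_sd_s baseline jitter SD (s) of the pre-swing-determining events
#'   (`t04`, `t07`), inflated by impairment.
#' @param impairment_effect list with `lr_gain`, `ps_gain`, `asym_gain`:
#'   per-rating-point multiplicative inflation of loading-response jitter,
#'   pre-swing jitter and left/right asymmetry. A clinician rating r (0-4)
#'   scales the loading-response SD by `1 + lr_gain * effect_scale * r`.
#' @param effect_scale global multiplier on the impairment effect (0 switches
#'   the simulated impairment off; 3 gives the strong-effect condition of
#'   roughly tripled loading-response variability at rating 1).
#' @param lead_in_s quiet time (s) before the first right heel strike.
#' @param tail_s quiet time (s) appended after the last rendered event.
#' @param ramp_s rise/fall time (s) of the rendered regional force edges.
#' @param peak_pressure_heel,peak_pressure_toe plateau pressure (N/cm^2) of
#'   heel-group and toe-group sensors during contact.
#' @param amplitude_scale global multiplier on rendered pressure amplitudes.
#' @param sensor_area_cm2 effective area (cm^2) of one pressure cell; converts
#'   pressure (N/cm^2) to regional force (N).
#' @param heel_sensors,toe_sensors integer index sets (1-16) of the rear
#'   (heel) and front (toe) pressure cells; remaining cells are mid-foot.
#' @param pressure_noise_sd additive sensor noise SD on pressures (N/cm^2).
#' @param imu_gyro_noise_sd additive noise SD on gyroscope channels (dps).
#' @param imu_accel_noise_sd additive noise SD on accelerometer channels (g).
#' @param ms_amplitude_dps peak mid-swing angular velocity (dps) of the
#'   sagittal (Z-axis) shank rotation lobe.
#' @param to_dip_dps,ic_dip_dps depth (dps) of the negative gyro-Z dips at
#'   toe-off and at initial contact.
#' @param insole_fs,imu_fs sampling rates (Hz) of the two systems.
#' @param seed master integer seed; all randomness streams from it.
#'
#' @return an object of class `simulation_spec` (a validated list).
#' @export
simulation_spec <- function(n_subjects = 19L,
                            cycles_per_session = 25L,
                            cycles_sd = 2,
                            speed_cycle_factor = c(slow = 1.15, normal = 1,
                                                   fast = 0.85),
                            mean_cycle_duration_s = c(slow = 1.3, normal = 1.1, fast = 0.9),
                            cycle_cv = 0.03,
                            phase_fractions = c(t02 = 0.12, t03 = 0.20, t04 = 0.40,
                                                t05 = 0.50, t06 = 0.62, t07 = 0.65,
                                                t08 = 0.90),
                            asymmetry = 0,
                            event_jitter_s = 0.004,
                            lr_sd_s = 0.006,
                            ps_sd_s = 0.005,
                            impairment_effect = list(lr_gain = 0.5, ps_gain = 0.25,
                                                     asym_gain = 0.002),
                            effect_scale = 1,
                            lead_in_s = 1.0,
                            tail_s = 1.0,
                            ramp_s = 0.05,
                            peak_pressure_heel = 8,
                            peak_pressure_toe = 6,
                            amplitude_scale = 1,
                            sensor_area_cm2 = 10,
                            heel_sensors = 12:16,
                            toe_sensors = 1:6,
                            pressure_noise_sd = 0.05,
                            imu_gyro_noise_sd = 2,
                            imu_accel_noise_sd = 0.02,
                            ms_amplitude_dps = 250,
                            to_dip_dps = 80,
                            ic_dip_dps = 40,
                            insole_fs = 100,
                            imu_fs = 59.5,
                            seed = 1L) {
  spec <- list(
    n_subjects = as.integer(n_subjects),
    cycles_per_session = as.integer(cycles_per_session),
    cycles_sd = cycles_sd,
    speed_cycle_factor = speed_cycle_factor,
    mean_cycle_duration_s = mean_cycle_duration_s,
    cycle_cv = cycle_cv,
    phase_fractions = phase_fractions,
    asymmetry = asymmetry,
    event_jitter_s = event_jitter_s,
    lr_sd_s = lr_sd_s,
    ps_sd_s = ps_sd_s,
    impairment_effect = impairment_effect,
    effect_scale = effect_scale,
    lead_in_s = lead_in_s,
    tail_s = tail_s,
    ramp_s = ramp_s,
    peak_pressure_heel = peak_pressure_heel,
    peak_pressure_toe = peak_pressure_toe,
    amplitude_scale = amplitude_scale,
    sensor_area_cm2 = sensor_area_cm2,
    heel_sensors = as.integer(heel_sensors),
    toe_sensors = as.integer(toe_sensors),
    pressure_noise_sd = pressure_noise_sd,
    imu_gyro_noise_sd = imu_gyro_noise_sd,
    imu_accel_noise_sd = imu_accel_noise_sd,
    ms_amplitude_dps = ms_amplitude_dps,
    to_dip_dps = to_dip_dps,
    ic_dip_dps = ic_dip_dps,
    insole_fs = insole_fs,
    imu_fs = imu_fs,
    seed = as.integer(seed)
  )
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
}

validate_simulation_spec <- function(spec) {
  if (spec$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (spec$cycles_per_session < 1L) stop("cycles_per_session must be >= 1", call. = FALSE)
  need <- c("slow", "normal", "fast")
  if (!all(need %in% names(spec$mean_cycle_duration_s)))
    stop("mean_cycle_duration_s needs entries for slow, normal, fast", call. = FALSE)
  if (spec$cycle_cv < 0) stop("cycle_cv must be >= 0", call. = FALSE)
  pf <- spec$phase_fractions
  need_pf <- paste0("t0", 2:8)
  if (!all(need_pf %in% names(pf)))
    stop("phase_fractions needs entries t02..t08", call. = FALSE)
  pf <- pf[need_pf]
  if (any(pf <= 0) || any(pf >= 1) || any(diff(pf) <= 0))
    stop("phase_fractions must lie in (0,1) and increase in event order", call. = FALSE)
  if (spec$asymmetry < 0) stop("asymmetry must be >= 0", call. = FALSE)
  if (length(intersect(spec$heel_sensors, spec$toe_sensors)) > 0L)
    stop("heel and toe sensor groups must be disjoint", call. = FALSE)
  if (any(!c(spec$heel_sensors, spec$toe_sensors) %in% 1:16))
    stop("sensor indices must lie in 1..16", call. = FALSE)
  spec
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("Synthetic gait simulation spec\n")
  cat(sprintf("  subjects: %d, cycles/session: %d, seed: %d\n",
              x$n_subjects, x$cycles_per_session, x$seed))
  cat(sprintf("  mean cycle (s): slow %.2f / normal %.2f / fast %.2f, CV %.3f\n",
              x$mean_cycle_duration_s[["slow"]], x$mean_cycle_duration_s[["normal"]],
              x$mean_cycle_duration_s[["fast"]], x$cycle_cv))
  cat(sprintf("  impairment effect scale: %g\n", x$effect_scale))
  invisible(x)
}
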