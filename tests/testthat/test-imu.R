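make_gyro <- function(peaks, amp, fs = 59.5, dur = 10, dips = NULL,
                      dip_amp = 40) {
  t <- seq(0, dur, by = 1 / fs)
  g <- numeric(length(t))
  for (p in peaks) {
    idx <- abs(t - p) < 0.15
    g[idx] <- g[idx] + amp * cos(pi * (t[idx] - p) / 0.3)^2
  }
  for (d in (dips %||% numeric(0))) {
    idx <- abs(t - d) < 0.1
    g[idx] <- g[idx] - dip_amp * exp(-(t[idx] - d)^2 / (2 * 0.02^2))
  }
  list(unix_time_s = t, gyr_z = g, fs = fs)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mid-swing height threshold follows the relative rule with a 50 dps floor", {
  # max 200 dps -> threshold max(50, 0.3 * 200) = 60
  sig <- make_gyro(c(2, 4, 6), amp = 200)
  ev <- detect_imu_gait_events(sig)
  expect_equal(ev$ms_threshold, 60)
  # max 100 dps -> floor engages: max(50, 30) = 50
  sig <- make_gyro(c(2, 4, 6), amp = 100)
  ev <- detect_imu_gait_events(sig)
  expect_equal(ev$ms_threshold, 50)
})

test_that("noise-free IMU events land within one sample of the shared truth", {
  s <- noise_free_session()
  truth <- imu_truth_events(s$timeline)
  for (side in c("left", "right")) {
    ev <- detect_imu_gait_events(s$imu[[side]])
    expect_equal(nrow(ev$strides), nrow(truth[[side]]))
    err <- abs(as.matrix(ev$strides) - as.matrix(truth[[side]]))
    expect_lt(max(err), 1 / 59.5 + 1e-9)
    expect_true(all(ev$strides$t_to < ev$strides$t_ms &
                      ev$strides$t_ms < ev$strides$t_ic))
  }
})

test_that("flat or too-short signals yield no strides", {
  t <- seq(0, 10, by = 1 / 59.5)
  flat <- list(unix_time_s = t, gyr_z = rep(0.1, length(t)), fs = 59.5)
  expect_equal(nrow(detect_imu_gait_events(flat)$strides), 0L)
  short <- make_gyro(0.1, amp = 200, dur = 0.3)
  expect_equal(nrow(detect_imu_gait_events(short)$strides), 0L)
})

test_that("raising the toe-off threshold never adds toe-off events", {
  s <- default_session()
  strides <- vapply(c(10, 15, 30, 60), function(th)
    nrow(detect_imu_gait_events(s$imu$right,
                                peak_params(to_threshold = th))$strides),
    numeric(1))
  expect_true(all(diff(strides) <= 0))
})

test_that("walking-bout detection finds one bout in a rest-walk-rest recording", {
  spec <- noise_free_spec(cycles = 18L, lead_in_s = 10, tail_s = 10,
                          imu_gyro_noise_sd = 2, imu_accel_noise_sd = 0.02)
  tl <- sample_gait_timeline(spec)
  imu <- render_imu(tl, spec)
  bouts <- detect_walking_bouts(imu$right)
  expect_equal(nrow(bouts), 1L)
  walk <- c(tl$cycles$t01[1L], tl$cycles$t02_next[nrow(tl$cycles)])
  covered <- min(bouts$end_s, walk[2]) - max(bouts$start_s, walk[1])
  expect_gte(covered / diff(walk), 0.9)
})

test_that("quiescent recordings contain no bouts and manual intervals pass through", {
  spec <- simulation_spec(seed = 6L)
  imu <- render_imu(dualgait:::empty_timeline(), spec)
  expect_equal(nrow(detect_walking_bouts(imu$left)), 0L)
  manual <- data.frame(start_s = c(1, 10), end_s = c(5, 14))
  expect_equal(detect_walking_bouts(imu$left, intervals = manual), manual)
})

test_that("temporal features match hand evaluation on a constructed stride series", {
  # IC at 0, 1, 2 s; TO at 0.62, 1.62 s -> cycle 1.0 s, stance 0.62 s, swing 0.38 s
  strides <- data.frame(t_to = c(-0.38, 0.62, 1.62),
                        t_ms = c(-0.2, 0.8, 1.8),
                        t_ic = c(0, 1, 2))
  foot <- structure(list(strides = strides, n_dropped = 0L),
                    class = "imu_gait_events")
  f <- compute_imu_features(foot, foot)$session
  expect_equal(f[["cycle_duration_l"]], 1.0)
  expect_equal(f[["stance_l"]], 0.62)
  expect_equal(f[["stance_pct_l"]], 0.62)
  expect_equal(f[["swing_l"]], 0.38)
  expect_equal(f[["single_support_l"]], 0.38)
  expect_equal(f[["walking_cadence"]], 1.0)
  expect_equal(f[["number_of_steps"]], 6)
  # identical legs -> zero asymmetry
  expect_equal(f[["asym_cadence"]], 0)
  expect_equal(f[["asym_contact_time"]], 0)
})

test_that("stance plus swing equals the cycle duration exactly", {
  s <- default_session()
  for (side in c("left", "right")) {
    st <- detect_imu_gait_events(s$imu[[side]])$strides
    n <- nrow(st)
    cyc <- diff(st$t_ic)
    stance <- st$t_to[-1L] - st$t_ic[-n]
    swing <- st$t_ic[-1L] - st$t_to[-1L]
    expect_equal(stance + swing, cyc)
  }
})

test_that("zero angular velocity gives zero gyroscope energy", {
  s <- noise_free_session()
  rec <- s$imu$left
  rec$data <- data.table::copy(rec$data)
  data.table::set(rec$data, j = "gyr_z", value = rep(0, nrow(rec$data)))
  ev <- detect_imu_gait_events(s$imu$left)  # strides from the original signal
  f <- compute_imu_features(ev, ev, rec, rec)$session
  expect_equal(f[["total_gyro_energy"]], 0)
})

test_that("leg-averaged IMU features agree with the insole pipeline on shared truth", {
  s <- noise_free_session()
  ins <- extract_insole_session(s$insole)$session
  imu <- extract_imu_session(s$imu$left, s$imu$right)$session
  rel <- function(a, b) abs(a - b) / b
  expect_lt(rel(imu[["cycle_duration_r"]], ins[["a09_mean"]]), 0.02)
  expect_lt(rel(imu[["cycle_duration_l"]], ins[["a13_mean"]]), 0.02)
  expect_lt(rel(imu[["walking_cadence"]], 1 / ins[["a09_mean"]]), 0.02)
  expect_lt(rel(imu[["stance_pct_r"]], ins[["a18_mean"]]), 0.02)
  expect_lt(rel(imu[["single_support_r"]], ins[["a01_mean"]]), 0.02)
  expect_lt(rel(imu[["single_support_l"]], ins[["a02_mean"]]), 0.02)
})
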