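test_that("noise-free insole threshold crossings land within one sample of truth", {
  s <- noise_free_session()
  forces <- heel_toe_forces(s$insole)
  ev <- detect_gait_events(forces)
  truth <- s$timeline$cycles
  expect_equal(nrow(ev$cycles), nrow(truth))
  err <- abs(as.matrix(ev$cycles) - as.matrix(truth[, names(ev$cycles)]))
  expect_lte(max(err), 0.010 + 1e-9)
})

test_that("an empty timeline renders baseline noise below detection thresholds", {
  spec <- simulation_spec(cycles_per_session = 5L, seed = 3L)
  rec <- render_insole(dualgait:::empty_timeline(), spec)
  forces <- heel_toe_forces(rec)
  # regional force stays tiny compared to any plausible contact threshold
  expect_lt(max(forces$l_heel, forces$r_heel, forces$l_toe, forces$r_toe), 20)
  ev <- detect_gait_events(forces, force_thresholds(heel_threshold = 20,
                                                    toe_threshold = 20))
  expect_equal(nrow(ev$events), 0L)
})

test_that("doubling the amplitude scale doubles peak force but not crossing times", {
  spec1 <- noise_free_spec(cycles = 4L)
  spec2 <- noise_free_spec(cycles = 4L, amplitude_scale = 2)
  tl <- sample_gait_timeline(spec1)
  r1 <- render_insole(tl, spec1)
  r2 <- render_insole(tl, spec2)
  expect_equal(max(r2$data$r_total_force) / max(r1$data$r_total_force), 2,
               tolerance = 1e-6)
  e1 <- detect_gait_events(heel_toe_forces(r1))
  e2 <- detect_gait_events(heel_toe_forces(r2))
  expect_equal(e1$events$time_s, e2$events$time_s)
})

test_that("gyro-Z mid-swing lobe peaks at the swing midpoint to one sample", {
  s <- noise_free_session()
  truth <- imu_truth_events(s$timeline)
  for (side in c("left", "right")) {
    d <- s$imu[[side]]$data
    tr <- truth[[side]]
    for (i in seq_len(nrow(tr))) {
      win <- d$unix_time_s > tr$t_to[i] & d$unix_time_s < tr$t_ic[i]
      tmax <- d$unix_time_s[win][which.max(d$gyr_z[win])]
      expect_lt(abs(tmax - tr$t_ms[i]), 1 / 59.5 + 1e-9)
    }
  }
})

test_that("a zero-cycle timeline renders only baseline gyro noise", {
  spec <- simulation_spec(seed = 4L)
  imu <- render_imu(dualgait:::empty_timeline(), spec)
  expect_lt(max(abs(imu$left$data$gyr_z), abs(imu$right$data$gyr_z)), 50)
})

test_that("with zero asymmetry and noise the two feet stride in step", {
  s <- noise_free_session()
  le <- detect_imu_gait_events(s$imu$left)
  re <- detect_imu_gait_events(s$imu$right)
  dl <- diff(le$strides$t_ic)
  dr <- diff(re$strides$t_ic)
  n <- min(length(dl), length(dr))
  expect_gt(n, 5)
  expect_lt(max(abs(dl[1:n] - dr[1:n])), 2 / 59.5 + 1e-9)
})

test_that("both renderers stay faithful to one shared timeline", {
  # event separability: every truth event recoverable from its modality
  s <- noise_free_session()
  ins <- detect_gait_events(heel_toe_forces(s$insole))
  expect_equal(nrow(ins$cycles), nrow(s$timeline$cycles))
  truth <- imu_truth_events(s$timeline)
  for (side in c("left", "right")) {
    ev <- detect_imu_gait_events(s$imu[[side]])
    expect_equal(nrow(ev$strides), nrow(truth[[side]]))
    err <- abs(as.matrix(ev$strides) - as.matrix(truth[[side]]))
    expect_lt(max(err), 1 / 59.5 + 1e-9)
  }
})
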