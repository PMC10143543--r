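test_that("preprocessing is near-identity on clean signals away from the ends", {
  s <- noise_free_session()
  pp <- preprocess_insole(s$insole)
  raw <- heel_toe_forces(s$insole)
  filt <- heel_toe_forces(pp)
  n <- length(raw$r_heel)
  interior <- 21:(n - 20)
  dev <- max(abs(filt$r_heel[interior] - raw$r_heel[interior]))
  # small passband ripple at contact edges is expected; amplitude stays <5%
  expect_lt(dev, 0.05 * max(raw$r_heel))
  expect_identical(pp$data$time_s, s$insole$data$time_s)
})

test_that("baseline correction zeroes a constant pressure offset", {
  s <- noise_free_session()
  d <- data.table::copy(s$insole$data)
  for (cn in paste0("l_", sprintf("p%02d", 1:16)))
    data.table::set(d, j = cn, value = d[[cn]] + 2)
  pp <- preprocess_insole(insole_recording(d))
  # quiescent segments (swing) should return to ~0 after median subtraction
  f <- heel_toe_forces(pp)
  q20 <- quantile(f$l_heel, 0.2, names = FALSE)
  expect_lt(q20, 0.05 * max(f$l_heel))
})

test_that("low-pass filtering attenuates added white noise", {
  s <- noise_free_session()
  sigma <- 0.3
  d <- data.table::copy(s$insole$data)
  set.seed(1)
  for (cn in paste0("r_", sprintf("p%02d", 1:16)))
    data.table::set(d, j = cn, value = d[[cn]] + rnorm(nrow(d), 0, sigma))
  pp <- preprocess_insole(insole_recording(d))
  clean <- preprocess_insole(s$insole)
  resid <- pp$data$r_p03 - clean$data$r_p03
  expect_lt(sd(resid), sigma)
})

test_that("an all-zero recording passes through with a warning", {
  d <- data.table::as.data.table(
    matrix(0, nrow = 100, ncol = 51,
           dimnames = list(NULL, dualgait:::INSOLE_COLS)))
  data.table::set(d, j = "time_s", value = seq(0, 0.99, by = 0.01))
  rec <- insole_recording(d)
  expect_warning(out <- preprocess_insole(rec), "all pressure channels")
  expect_identical(out$data, rec$data)
})

test_that("regional forces are the area-weighted group sums", {
  d <- data.table::as.data.table(
    matrix(0, nrow = 10, ncol = 51,
           dimnames = list(NULL, dualgait:::INSOLE_COLS)))
  data.table::set(d, j = "time_s", value = seq(0, 0.09, by = 0.01))
  # all pressure on heel cells only -> toe force identically zero
  for (cn in paste0("l_", sprintf("p%02d", 12:16)))
    data.table::set(d, j = cn, value = rep(2, 10))
  f <- heel_toe_forces(insole_recording(d))
  expect_equal(f$l_toe, rep(0, 10))
  expect_equal(f$l_heel, rep(2 * 5 * 10, 10))
  # uniform pressure -> force ratio equals area (cell-count) ratio
  for (cn in paste0("r_", sprintf("p%02d", 1:16)))
    data.table::set(d, j = cn, value = rep(1, 10))
  f <- heel_toe_forces(insole_recording(d))
  expect_equal(unique(f$r_heel / f$r_toe), 5 / 6)
  expect_error(heel_toe_forces(insole_recording(d), heel_sensors = 1:8,
                               toe_sensors = 8:16), "disjoint")
})

test_that("heel contact precedes toe contact within a rendered stance", {
  s <- noise_free_session()
  f <- heel_toe_forces(s$insole)
  th <- 0.05 * quantile(f$r_heel, 0.95, names = FALSE)
  heel_first <- f$time_s[which(f$r_heel > th)[1L]]
  toe_first <- f$time_s[which(f$r_toe > th)[1L]]
  expect_lt(heel_first, toe_first)
})

test_that("forces that never cross threshold yield no events", {
  t <- seq(0, 5, by = 0.01)
  flat <- list(time_s = t, fs = 100,
               l_heel = rep(1, length(t)), l_toe = rep(1, length(t)),
               r_heel = rep(1, length(t)), r_toe = rep(1, length(t)))
  ev <- detect_gait_events(flat, force_thresholds(heel_threshold = 50,
                                                  toe_threshold = 50))
  expect_equal(nrow(ev$events), 0L)
  expect_equal(ev$n_steps, 0L)
})

test_that("hysteresis suppresses threshold chatter into a single heel strike", {
  t <- seq(0, 2, by = 0.01)
  th <- 100
  # rise to the threshold then a 50 Hz square wave straddling it by +/-1%
  heel <- numeric(length(t))
  heel[t >= 0.5] <- th * (1.01 - 0.02 * (floor((t[t >= 0.5] - 0.5) * 100) %% 2))
  zero <- rep(0, length(t))
  forces <- list(time_s = t, fs = 100, l_heel = zero, l_toe = zero,
                 r_heel = heel, r_toe = zero)
  ev <- detect_gait_events(forces, force_thresholds(heel_threshold = th,
                                                    toe_threshold = th,
                                                    hysteresis = 0.2))
  expect_equal(sum(ev$events$type == "heel_strike"), 1L)
})

test_that("noise below 10% of amplitude neither breaks counts nor shifts events > 30 ms", {
  s0 <- noise_free_session()
  ev0 <- detect_gait_events(heel_toe_forces(s0$insole))
  spec_n <- noise_free_spec(pressure_noise_sd = 0.5)  # ~6% of the 8 N/cm2 plateau
  rec_n <- render_insole(s0$timeline, spec_n, seed = 88L)
  ev_n <- detect_gait_events(heel_toe_forces(preprocess_insole(rec_n)))
  expect_equal(nrow(ev_n$cycles), nrow(ev0$cycles))
  err <- abs(as.matrix(ev_n$cycles) - as.matrix(ev0$cycles))
  expect_lt(max(err), 0.030)
})
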