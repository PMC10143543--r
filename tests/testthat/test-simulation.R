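test_that("degenerate no-noise timeline puts events exactly at the phase fractions", {
  spec <- noise_free_spec(cycles = 5L,
                          mean_cycle_duration_s = c(slow = 1.3, normal = 1.0, fast = 0.9),
                          lead_in_s = 0)
  tl <- sample_gait_timeline(spec, speed_class = "normal")
  cy <- tl$cycles
  for (k in seq_len(nrow(cy))) {
    expect_equal(cy$t01[k], k - 1)
    expect_equal(cy$t02[k], k - 1 + 0.12)
    expect_equal(cy$t04[k], k - 1 + 0.40)
    expect_equal(cy$t05[k], k - 1 + 0.50)
    expect_equal(cy$t06[k], k - 1 + 0.62)
    expect_equal(cy$t07[k], k - 1 + 0.65)
    expect_equal(cy$t08[k], k - 1 + 0.90)
  }
  expect_equal(cy$t01_next, cy$t01 + 1)
})

test_that("identical spec and seed reproduce the identical timeline", {
  spec <- simulation_spec(cycles_per_session = 10L, seed = 9L)
  a <- sample_gait_timeline(spec, impairment_rating = 2L)
  b <- sample_gait_timeline(spec, impairment_rating = 2L)
  expect_identical(a, b)
})

test_that("impairment rating inflates loading-response variability", {
  spec <- simulation_spec(cycles_per_session = 200L, cycles_sd = 0, seed = 31L)
  tl0 <- sample_gait_timeline(spec, impairment_rating = 0L)
  tl4 <- sample_gait_timeline(spec, impairment_rating = 4L)
  lr0 <- sd(tl0$cycles$t02 - tl0$cycles$t01)
  lr4 <- sd(tl4$cycles$t02 - tl4$cycles$t01)
  expect_gt(lr4, lr0)
})

test_that("timeline invariants hold across speeds, ratings and seeds", {
  for (seed in 1:4) {
    spec <- simulation_spec(cycles_per_session = 12L, seed = seed)
    for (speed in c("slow", "normal", "fast")) {
      r <- (seed + match(speed, c("slow", "normal", "fast"))) %% 5L
      tl <- sample_gait_timeline(spec, speed_class = speed,
                                 impairment_rating = r)
      cy <- tl$cycles
      tm <- as.matrix(cy[, c(paste0("t0", 1:8), "t01_next", "t02_next")])
      expect_true(all(is.finite(tm)) && all(tm >= 0))
      expect_true(all(apply(tm, 1L, function(x) all(diff(x) > 0))))
      expect_equal(cy$t01_next[-nrow(cy)], cy$t01[-1L])
    }
  }
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulation_spec(n_subjects = 0), "n_subjects")
  expect_error(simulation_spec(phase_fractions = c(t02 = 0.5, t03 = 0.4,
                                                   t04 = 0.6, t05 = 0.7,
                                                   t06 = 0.8, t07 = 0.85,
                                                   t08 = 0.9)),
               "increase")
  expect_error(simulation_spec(heel_sensors = 1:5, toe_sensors = 4:9),
               "disjoint")
})

test_that("cohort manifest enumerates subject x state x speed x repetition with labels", {
  spec <- noise_free_spec(cycles = 3L, seed = 12L)
  spec$n_subjects <- 19L
  co <- generate_cohort(spec)
  expect_equal(nrow(co$manifest), 19 * 2 * 3 * 2)
  expect_identical(co$manifest$impaired, co$manifest$rating > 0)
  expect_setequal(unique(co$manifest$speed), c("slow", "normal", "fast"))
  expect_length(co$sessions, 228)
  # rating-0 sessions are labelled unimpaired
  z <- co$manifest[co$manifest$rating == 0, ]
  expect_true(nrow(z) > 0 && all(!z$impaired))
})

test_that("cohort generation is reproducible from the master seed", {
  spec <- noise_free_spec(cycles = 3L, seed = 5L)
  spec$n_subjects <- 2L
  a <- generate_cohort(spec, states = "ON", speeds = "normal", repetitions = 1L)
  b <- generate_cohort(spec, states = "ON", speeds = "normal", repetitions = 1L)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$sessions, b$sessions)
})
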