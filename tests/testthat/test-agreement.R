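test_that("low-step-count exclusion uses a strict less-than-three boundary", {
  sessions <- data.frame(session_id = c("a", "b", "c", "d"),
                         insole_steps = c(2, 3, 40, 10),
                         imu_steps = c(30, 40, 2, 10))
  out <- exclude_low_step_cases(sessions)
  expect_setequal(out$kept$session_id, c("b", "d"))
  expect_setequal(out$excluded$session_id, c("a", "c"))
  # all sessions at or above the boundary -> identity
  ok <- data.frame(session_id = 1:3, insole_steps = c(3, 5, 9),
                   imu_steps = c(3, 8, 4))
  expect_identical(exclude_low_step_cases(ok)$kept, ok)
})

test_that("min-max scaling maps endpoints and preserves Pearson correlation", {
  expect_equal(as.numeric(scale_to_reference(c(0, 1), c(10, 20))), c(10, 20))
  set.seed(2)
  x <- rnorm(50)
  expect_equal(as.numeric(scale_to_reference(x, x)), x)
  ins <- rnorm(50, 10, 2)
  imu <- 0.5 * ins + rnorm(50, 0, 0.5)
  expect_equal(cor(ins, as.numeric(scale_to_reference(imu, ins))),
               cor(ins, imu))
  expect_error(scale_to_reference(rep(1, 5), rnorm(5), "cadence"), "cadence")
})

test_that("robust outlier rule flags gross deviations only", {
  set.seed(4)
  x <- rnorm(40, 10)
  y <- x + rnorm(40, 0, 0.1)
  expect_false(any(flag_outliers(x, y)))
  y2 <- y
  y2[17] <- y2[17] + 10 * sd(x - y)
  fl <- flag_outliers(x, y2)
  expect_identical(which(fl), 17L)
  # degenerate scale (MAD = 0) engages the guard
  expect_false(any(flag_outliers(1:10, (1:10) - 2)))
})

test_that("pearson correlation matches a hand-computed covariance ratio", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 6.1, 0.7, 8.0, 7.3, 5.0)
  y <- c(2.0, 3.1, 2.9, 5.0, 5.2, 5.9, 1.5, 7.2, 6.8, 4.1)
  n <- length(x)
  r_hand <- (sum(x * y) / n - mean(x) * mean(y)) /
    (sqrt(sum(x^2) / n - mean(x)^2) * sqrt(sum(y^2) / n - mean(y)^2))
  expect_equal(pearson_r(x, y), r_hand, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "variance")
  expect_error(pearson_r(1:2, 2:3), "pairs")
})

test_that("ICC(3,1) equals the brute-force ANOVA mean squares on a 6x2 fixture", {
  x <- c(9.1, 7.8, 8.6, 10.2, 6.9, 9.5)
  y <- c(8.8, 8.1, 8.2, 10.5, 7.4, 9.0)
  d <- data.frame(v = c(x, y), subj = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  a <- summary(stats::aov(v ~ subj + rater, data = d))[[1]]
  msr <- a["subj", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  icc_oracle <- (msr - mse) / (msr + mse)
  expect_equal(icc_single_fixed(x, y)$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(icc_single_fixed(x, x)$icc, 1)
})

test_that("independent raters give near-zero ICC and standardized columns give ICC = r", {
  set.seed(11)
  x <- rnorm(200)
  y <- rnorm(200)
  expect_lt(abs(icc_single_fixed(x, y)$icc), 0.15)
  z <- rnorm(200)
  w <- 0.7 * z + rnorm(200, 0, 0.5)
  w_std <- as.numeric(scale(w)) * sd(z) + mean(z)
  expect_equal(icc_single_fixed(z, w_std)$icc, cor(z, w_std), tolerance = 1e-12)
  g <- rep(c("slow", "normal", "fast"), length.out = 200)
  res <- icc_single_fixed(z, w, groups = g)
  expect_length(res$per_group, 3)
  expect_true(all(res$per_group <= 1))
})

test_that("Bland-Altman statistics behave on degenerate and Gaussian differences", {
  x <- c(1.5, 2.5, 3.5, 4.5)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$mean_diff, 2)
  expect_equal(ba2$sd_diff, 0)
  set.seed(21)
  a <- rnorm(1000, 5)
  b <- a + rnorm(1000, 0.3, 0.7)
  ba3 <- bland_altman(a, b)
  inside <- mean(ba3$differences >= ba3$loa_low &
                   ba3$differences <= ba3$loa_high)
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
  expect_equal(ba3$loa_high - ba3$mean_diff, 1.96 * ba3$sd_diff)
})

test_that("shared-truth cohort shows the expected cross-system agreement pattern", {
  co <- agreement_cohort()
  agr <- compare_systems(co$insole, co$imu, co$manifest)
  tb <- agr$table
  key <- c("walking_cadence", "right_gait_cycle_duration",
           "left_gait_cycle_duration")
  expect_true(all(tb$pearson_r[tb$feature %in% key] >= 0.95))
  expect_true(all(tb$icc[tb$feature %in% key] >= 0.90))
  expect_true(all(tb$icc <= 1))
  expect_equal(tb$loa_low, tb$mean_diff - 1.96 * tb$sd_diff)
  expect_equal(tb$loa_high, tb$mean_diff + 1.96 * tb$sd_diff)
})
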