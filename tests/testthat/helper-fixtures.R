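# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Deterministic, noise-free conditions: every stochastic knob off.
noise_free_spec <- function(cycles = 12L, seed = 42L, ...) {
  args <- list(cycles_per_session = cycles, cycles_sd = 0, cycle_cv = 0,
               event_jitter_s = 0, lr_sd_s = 0, ps_sd_s = 0,
               pressure_noise_sd = 0, imu_gyro_noise_sd = 0,
               imu_accel_noise_sd = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_spec, args)
}

noise_free_session <- function() fixture("noise_free_session", function() {
  spec <- noise_free_spec()
  tl <- sample_gait_timeline(spec)
  list(spec = spec, timeline = tl,
       insole = render_insole(tl, spec),
       imu = render_imu(tl, spec))
})

# Default-noise session used by robustness checks.
default_session <- function() fixture("default_session", function() {
  spec <- simulation_spec(cycles_per_session = 12L, seed = 7L)
  tl <- sample_gait_timeline(spec)
  list(spec = spec, timeline = tl,
       insole = render_insole(tl, spec),
       imu = render_imu(tl, spec))
})

# The shared-truth comparison cohort: 19 subjects x 3 speeds x 2 repetitions,
# one medication state, default noise.
agreement_cohort <- function() fixture("agreement_cohort", function() {
  spec <- simulation_spec(seed = 101L)
  extract_cohort_features(spec, states = "ON", repetitions = 2L)
})

# Normal-speed classification cohorts (19 subjects x 2 states x 2 reps = 76
# sessions) at the default and the strong impairment effect.
ml_cohort <- function(effect = 1) {
  name <- paste0("ml_cohort_", effect)
  fixture(name, function() {
    spec <- simulation_spec(seed = 202L, effect_scale = effect)
    extract_cohort_features(spec, speeds = "normal")
  })
}

# A separable toy classification problem: the label is the sign of the first
# feature, whose values cluster tightly at +/-1 so every training fold covers
# both sides of the margin (keeps tree split points near zero).
toy_matrix <- function(n = 60, p = 5, seed = 8) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- sample(c(-1, 1), n, replace = TRUE) + rnorm(n, 0, 0.1)
  structure(list(x = x, y = x[, 1] > 0,
                 groups = paste0("G", rep(seq_len(n / 2), each = 2)),
                 session_id = as.character(seq_len(n)), set = "toy"),
            class = "feature_matrix")
}

# The worked single-cycle time points used by the feature-formula tests.
worked_cycle <- function() {
  data.frame(t01 = 0, t02 = 0.12, t03 = 0.20, t04 = 0.40, t05 = 0.50,
             t06 = 0.62, t07 = 0.65, t08 = 0.90, t01_next = 1.00,
             t02_next = 1.12)
}
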