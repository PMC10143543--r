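# Clinician gait-item rating pools mirroring the study cohort's rating
# distribution per medication state (ON therapy vs overnight withdrawal).
# The two pump-treated subjects, unratable OFF in the study, are assigned
# mid-range OFF ratings here so every synthetic session carries a label.
rating_pools <- function(n) {
  on_pool <- rep(0:3, times = c(4, 11, 2, 2))
  off_pool <- rep(c(0, 1, 2, 4), times = c(1, 11, 5, 2))
  resize <- function(pool) {
    if (n == length(pool)) return(sort(pool))
    sort(pool[(seq_len(n) - 1L) %% length(pool) + 1L])
  }
  # pair by severity rank so a subject's ON rating tracks their OFF rating
  list(ON = resize(on_pool), OFF = resize(off_pool))
}

session_grid <- function(spec, states, speeds, repetitions) {
  g <- expand.grid(repetition = seq_len(repetitions), speed = speeds,
                   state = states, subject = seq_len(spec$n_subjects),
                   stringsAsFactors = FALSE)
  g <- g[, c("subject", "state", "speed", "repetition")]
  pools <- rating_pools(spec$n_subjects)
  # subject order within the severity-ranked pools is shuffled by the seed
  perm <- with_seed(child_seed(spec$seed, 0L), sample.int(spec$n_subjects))
  g$subject_id <- sprintf("S%02d", g$subject)
  g$rating <- ifelse(g$state == "ON", pools$ON[perm[g$subject]],
                     pools$OFF[perm[g$subject]])
  g$impaired <- g$rating > 0
  g$session_id <- sprintf("%s_%s_%s_r%d", g$subject_id, g$state, g$speed,
                          g$repetition)
  g
}

simulate_session <- function(spec, row, idx) {
  sseed <- child_seed(spec$seed, idx)
  timeline <- sample_gait_timeline(spec, subject_id = row$subject_id,
                                   speed_class = row$speed,
                                   impairment_rating = row$rating,
                                   state = row$state,
                                   seed = child_seed(sseed, 1L))
  insole <- render_insole(timeline, spec, seed = child_seed(sseed, 2L))
  imu <- render_imu(timeline, spec, seed = child_seed(sseed, 3L))
  list(timeline = timeline, insole = insole, imu_left = imu$left,
       imu_right = imu$right)
}

#' Generate a synthetic cohort
#'
#' Produces one ground-truth timeline plus one insole recording and one pair
#' of ankle-IMU recordings for every subject x medication state x speed x
#' repetition combination, together with a manifest table carrying the
#' impairment label (clinician rating > 0). All randomness streams from the
#' spec's master seed, one child stream per session, so identical spec + seed
#' reproduce the cohort exactly and subsetting sessions does not change the
#' remaining ones.
#'
#' @param spec a [simulation_spec()].
#' @param states medication states to simulate.
#' @param speeds instructed speed classes.
#' @param repetitions repetitions per condition.
#' @param out_dir if given, recordings are written as delimited text under
#'   this directory (paths recorded in the manifest) and not kept in memory.
#' @return list with `manifest` (data.frame) and, when `out_dir` is `NULL`,
#'   `sessions` (named list of timeline + recordings per session).
#' @export
generate_cohort <- function(spec, states = c("ON", "OFF"),
                            speeds = c("slow", "normal", "fast"),
                            repetitions = 2L, out_dir = NULL) {
  validate_simulation_spec(spec)
  g <- session_grid(spec, states, speeds, repetitions)
  keep <- is.null(out_dir)
  if (!keep) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sessions <- if (keep) vector("list", nrow(g))
  g$insole_file <- NA_character_
  g$imu_left_file <- NA_character_
  g$imu_right_file <- NA_character_
  for (i in seq_len(nrow(g))) {
    ses <- simulate_session(spec, g[i, ], i)
    if (keep) sessions[[i]] <- ses
    else {
      g$insole_file[i] <- file.path(out_dir, paste0(g$session_id[i], "_insole.csv"))
      g$imu_left_file[i] <- file.path(out_dir, paste0(g$session_id[i], "_imu_left.csv"))
      g$imu_right_file[i] <- file.path(out_dir, paste0(g$session_id[i], "_imu_right.csv"))
      write_insole_csv(ses$insole, g$insole_file[i])
      write_imu_csv(ses$imu_left, g$imu_left_file[i])
      write_imu_csv(ses$imu_right, g$imu_right_file[i])
    }
  }
  if (keep) names(sessions) <- g$session_id
  out <- list(manifest = g)
  if (keep) out$sessions <- sessions
  out
}

#' Simulate a cohort and extract features from both pipelines
#'
#' The streaming workhorse behind the agreement and classification stages:
#' simulates each session, runs the insole pipeline (preprocess, regional
#' forces, event detection, per-cycle features) and the IMU pipeline (peak
#' detection on both ankles, single-sensor features), and keeps only the
#' session-level feature vectors. Sessions whose insole extraction finds no
#' complete cycle yield NA features with a zero step count (they are later
#' removed by the low-step-count filter).
#'
#' @param spec a [simulation_spec()].
#' @inheritParams generate_cohort
#' @param thresholds a [force_thresholds()] for the insole detector.
#' @param params a [peak_params()] for the IMU detector.
#' @param preprocess logical; run the insole low-pass/baseline step.
#' @return list with `manifest`, `insole` and `imu` data.frames (one row per
#'   session, `session_id` key).
#' @export
extract_cohort_features <- function(spec, states = c("ON", "OFF"),
                                    speeds = c("slow", "normal", "fast"),
                                    repetitions = 2L,
                                    thresholds = force_thresholds(),
                                    params = peak_params(),
                                    preprocess = TRUE) {
  validate_simulation_spec(spec)
  g <- session_grid(spec, states, speeds, repetitions)
  ins_rows <- vector("list", nrow(g))
  imu_rows <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    ses <- simulate_session(spec, g[i, ], i)
    ins <- tryCatch(
      extract_insole_session(ses$insole, thresholds, preprocess = preprocess),
      error = function(e) NULL)
    ins_rows[[i]] <- if (is.null(ins))
      c(number_of_steps = 0, n_cycles = 0) else ins$session
    imu <- extract_imu_session(ses$imu_left, ses$imu_right, params)
    imu_rows[[i]] <- imu$session
  }
  bind_named <- function(rows) {
    nms <- unique(unlist(lapply(rows, names)))
    m <- do.call(rbind, lapply(rows, function(r) {
      out <- stats::setNames(rep(NA_real_, length(nms)), nms)
      out[names(r)] <- r
      out
    }))
    data.frame(session_id = g$session_id, m, row.names = NULL,
               check.names = FALSE)
  }
  list(manifest = g, insole = bind_named(ins_rows), imu = bind_named(imu_rows))
}
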