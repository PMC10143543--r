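#' Peak-detection parameters for ankle-gyroscope gait events
#'
#' Mid-swing (MS) peaks are detected on the gyroscope Z axis with a relative
#' height threshold `max(ms_floor, ms_fraction * max(sz))`, a minimum peak
#' distance and a minimum peak width. Toe-off (TO) and initial-contact (IC)
#' events are negative-going dips, detected on the inverted signal with fixed
#' depth thresholds (TO deeper than IC): TO is the nearest qualifying dip
#' preceding each MS, IC the nearest qualifying dip following it, each within
#' `assign_window_s`.
#'
#' @param ms_floor MS height floor (dps), default 50.
#' @param ms_fraction fraction of the bout's signal maximum, default 0.3.
#' @param ms_min_distance_s minimum MS peak spacing (s), default 0.5.
#' @param ms_min_width_s minimum MS peak width at half height (s), default 0.1.
#' @param to_threshold TO dip depth threshold (dps), default 15.
#' @param ic_threshold IC dip depth threshold (dps), default 5.
#' @param assign_window_s search window around MS for TO/IC assignment (s).
#' @return object of class `peak_params`.
#' @export
peak_params <- function(ms_floor = 50, ms_fraction = 0.3,
                        ms_min_distance_s = 0.5, ms_min_width_s = 0.1,
                        to_threshold = 15, ic_threshold = 5,
                        assign_window_s = 0.5) {
  vals <- c(ms_floor, ms_fraction, ms_min_distance_s, ms_min_width_s,
            to_threshold, ic_threshold, assign_window_s)
  if (any(vals <= 0)) stop("all peak parameters must be positive", call. = FALSE)
  if (ms_fraction >= 1) stop("ms_fraction must lie in (0, 1)", call. = FALSE)
  structure(list(ms_floor = ms_floor, ms_fraction = ms_fraction,
                 ms_min_distance_s = ms_min_distance_s,
                 ms_min_width_s = ms_min_width_s,
                 to_threshold = to_threshold, ic_threshold = ic_threshold,
                 assign_window_s = assign_window_s),
            class = "peak_params")
}

#' Detect walking bouts from an IMU recording
#'
#' Manual mode returns the supplied intervals verbatim (the study setting,
#' where bout boundaries come from the test-protocol time log). Automatic
#' mode thresholds the 1 s moving RMS of the gyroscope magnitude, merges gaps
#' shorter than `merge_gap_s` and drops bouts shorter than `min_bout_s`.
#'
#' @param recording an [imu_recording()].
#' @param intervals optional data.frame/matrix with columns start_s, end_s;
#'   when given it is passed through unchanged (manual mode).
#' @param rms_threshold_dps activity threshold on the moving RMS (dps).
#' @param window_s moving-RMS window (s).
#' @param merge_gap_s merge sub-threshold gaps shorter than this (s).
#' @param min_bout_s drop bouts shorter than this (s).
#' @return data.frame with columns start_s, end_s (possibly 0 rows).
#' @export
detect_walking_bouts <- function(recording, intervals = NULL,
                                 rms_threshold_dps = 20, window_s = 1,
                                 merge_gap_s = 1, min_bout_s = 3) {
  if (!is.null(intervals)) {
    iv <- as.data.frame(intervals)
    names(iv)[1:2] <- c("start_s", "end_s")
    return(iv)
  }
  stopifnot(inherits(recording, "imu_recording"))
  d <- recording$data
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (nrow(d) == 0L) return(empty)
  t <- d$unix_time_s
  fs <- recording$fs
  mag2 <- d$gyr_x^2 + d$gyr_y^2 + d$gyr_z^2
  w <- max(1L, round(window_s * fs))
  rms <- sqrt(stats::filter(mag2, rep(1 / w, w), sides = 2))
  rms[is.na(rms)] <- sqrt(mag2[is.na(rms)])
  active <- rms > rms_threshold_dps
  r <- rle(as.vector(active))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- data.frame(start_s = t[starts[r$values]], end_s = t[ends[r$values]])
  if (nrow(segs) == 0L) return(empty)
  # merge gaps < merge_gap_s
  merged <- segs[1L, , drop = FALSE]
  if (nrow(segs) > 1L) for (i in 2:nrow(segs)) {
    if (segs$start_s[i] - merged$end_s[nrow(merged)] < merge_gap_s)
      merged$end_s[nrow(merged)] <- segs$end_s[i]
    else merged <- rbind(merged, segs[i, ])
  }
  merged <- merged[merged$end_s - merged$start_s >= min_bout_s, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

# findpeaks wrapper returning peak times/heights honouring a minimum width at
# half height (pracma::findpeaks exposes no width argument).
find_qualifying_peaks <- function(t, x, min_height, min_distance_s = NULL,
                                  min_width_s = NULL, fs) {
  if (length(x) < 3L || max(x) < min_height) return(numeric(0))
  args <- list(x, minpeakheight = min_height)
  if (!is.null(min_distance_s))
    args$minpeakdistance <- max(1L, round(min_distance_s * fs))
  pk <- do.call(pracma::findpeaks, args)
  if (is.null(pk)) return(numeric(0))
  idx <- pk[, 2L]
  if (!is.null(min_width_s)) {
    need <- max(1L, round(min_width_s * fs))
    keep <- vapply(seq_len(nrow(pk)), function(i) {
      half <- pk[i, 1L] / 2
      lo <- hi <- idx[i]
      while (lo > 1L && x[lo - 1L] > half) lo <- lo - 1L
      while (hi < length(x) && x[hi + 1L] > half) hi <- hi + 1L
      (hi - lo + 1L) >= need
    }, logical(1))
    idx <- idx[keep]
  }
  sort(t[idx])
}

#' Detect gait events from one ankle gyroscope
#'
#' Thresholded peak detection on the gyroscope Z axis of a single ankle
#' within one walking bout. Mid-swing peaks use the relative height rule
#' `max(ms_floor, ms_fraction * max(sz))` with minimum distance and width;
#' toe-off and initial-contact dips are found on the inverted signal at the
#' fixed depth thresholds and assigned to the nearest mid-swing peak (TO
#' before, IC after, within the assignment window). Strides missing either
#' dip are dropped and counted.
#'
#' @param recording an [imu_recording()], or a list with `unix_time_s`/`gyr_z`.
#' @param params a [peak_params()].
#' @param bout optional c(start_s, end_s) restricting the analysis window.
#' @return object of class `imu_gait_events`: list with `strides` (data.frame
#'   t_to, t_ms, t_ic, seconds), `ms_threshold` (dps) and `n_dropped`.
#' @export
detect_imu_gait_events <- function(recording, params = peak_params(),
                                   bout = NULL) {
  stopifnot(inherits(params, "peak_params"))
  if (inherits(recording, "imu_recording")) {
    t <- recording$data$unix_time_s
    gz <- recording$data$gyr_z
    fs <- recording$fs
  } else {
    t <- recording$unix_time_s
    gz <- recording$gyr_z
    fs <- recording$fs %||% (1 / stats::median(diff(t)))
  }
  if (!is.null(bout)) {
    keep <- t >= bout[1L] & t <= bout[2L]
    t <- t[keep]; gz <- gz[keep]
  }
  empty <- structure(list(strides = data.frame(t_to = numeric(0),
                                               t_ms = numeric(0),
                                               t_ic = numeric(0)),
                          ms_threshold = NA_real_, n_dropped = 0L),
                     class = "imu_gait_events")
  if (length(gz) < 2L || diff(range(t)) < params$ms_min_distance_s ||
      max(gz) <= 0 || diff(range(gz)) < 1e-12)
    return(empty)

  ms_th <- max(params$ms_floor, params$ms_fraction * max(gz))
  ms <- find_qualifying_peaks(t, gz, ms_th, params$ms_min_distance_s,
                              params$ms_min_width_s, fs)
  if (!length(ms)) { empty$ms_threshold <- ms_th; return(empty) }
  inv <- -gz
  to_cand <- find_qualifying_peaks(t, inv, params$to_threshold, fs = fs)
  ic_cand <- find_qualifying_peaks(t, inv, params$ic_threshold, fs = fs)

  n_dropped <- 0L
  rows <- list()
  for (m in ms) {
    to_ok <- to_cand[to_cand < m & to_cand >= m - params$assign_window_s]
    ic_ok <- ic_cand[ic_cand > m & ic_cand <= m + params$assign_window_s]
    if (!length(to_ok) || !length(ic_ok)) { n_dropped <- n_dropped + 1L; next }
    rows[[length(rows) + 1L]] <- c(max(to_ok), m, min(ic_ok))
  }
  if (!length(rows)) { empty$ms_threshold <- ms_th; empty$n_dropped <- n_dropped; return(empty) }
  st <- as.data.frame(do.call(rbind, rows))
  names(st) <- c("t_to", "t_ms", "t_ic")
  # enforce non-overlapping, increasing strides
  keep <- c(TRUE, diff(st$t_ms) > 0 & st$t_to[-1L] >= st$t_ic[-nrow(st)])
  n_dropped <- n_dropped + sum(!keep)
  st <- st[keep, , drop = FALSE]
  rownames(st) <- NULL
  structure(list(strides = st, ms_threshold = ms_th, n_dropped = n_dropped),
            class = "imu_gait_events")
}

#' @export
print.imu_gait_events <- function(x, ...) {
  cat(sprintf("IMU gait events: %d strides (MS threshold %.1f dps, %d dropped)\n",
              nrow(x$strides), x$ms_threshold, x$n_dropped))
  invisible(x)
}
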