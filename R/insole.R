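#' Force thresholds for insole gait-event detection
#'
#' The detector compares regional heel and toe forces against thresholds with
#' a hysteresis band (Schmitt trigger): a region turns "in contact" when its
#' force rises above the threshold and releases only when it falls below
#' `threshold * (1 - hysteresis)`, which suppresses chatter from signals that
#' straddle the threshold. Absolute thresholds in Newtons may be given; by
#' default thresholds are relative, `auto_fraction` times the session's 95th
#' percentile of the respective regional force, so they scale with signal
#' amplitude.
#'
#' @param heel_threshold,toe_threshold absolute thresholds in N, or `NULL`
#'   (default) for the relative rule.
#' @param auto_fraction fraction of the 95th-percentile regional force used
#'   when thresholds are relative.
#' @param hysteresis release-band fraction in [0, 0.5).
#' @param min_event_gap_s minimum spacing between successive events of the
#'   same region (s); shorter contact/release runs are ignored.
#' @return object of class `force_thresholds`.
#' @export
force_thresholds <- function(heel_threshold = NULL, toe_threshold = NULL,
                             auto_fraction = 0.05, hysteresis = 0.2,
                             min_event_gap_s = 0) {
  if (hysteresis < 0 || hysteresis >= 0.5)
    stop("hysteresis must lie in [0, 0.5)", call. = FALSE)
  if (min_event_gap_s < 0) stop("min_event_gap_s must be >= 0", call. = FALSE)
  for (th in list(heel_threshold, toe_threshold))
    if (!is.null(th) && th <= 0) stop("thresholds must be > 0", call. = FALSE)
  structure(list(heel_threshold = heel_threshold, toe_threshold = toe_threshold,
                 auto_fraction = auto_fraction, hysteresis = hysteresis,
                 min_event_gap_s = min_event_gap_s),
            class = "force_thresholds")
}

#' Preprocess an insole recording
#'
#' Normalisation and noise removal ahead of event detection: pressure
#' channels are zero-phase low-pass filtered (Butterworth, order
#' `filter_order`, cutoff `cutoff_hz`) and baseline-corrected by subtracting
#' each channel's median (a robust estimate of the quiescent level, since
#' every pressure cell is out of contact for most of each gait cycle). The
#' default cutoff of 20 Hz sits well above the gait band but low enough to
#' attenuate broadband sensor noise; sharper filtering visibly distorts the
#' 50 ms contact edges that event timing depends on. Optional normalisation
#' rescales pressures by the session peak total force or by body weight.
#' Timestamps and non-pressure channels are unchanged; the choices are
#' recorded in the returned object's `provenance` attribute.
#'
#' @param recording an [insole_recording()].
#' @param cutoff_hz low-pass cutoff (Hz).
#' @param filter_order Butterworth order.
#' @param normalization `"none"`, `"session_peak"` or `"body_weight"`.
#' @param body_weight_n body weight in N (required for `"body_weight"`).
#' @return a filtered `insole_recording` with a `provenance` attribute.
#' @export
preprocess_insole <- function(recording, cutoff_hz = 20, filter_order = 4,
                              normalization = c("none", "session_peak", "body_weight"),
                              body_weight_n = NULL) {
  stopifnot(inherits(recording, "insole_recording"))
  normalization <- match.arg(normalization)
  fs <- recording$fs
  bf <- signal::butter(filter_order, cutoff_hz / (fs / 2), type = "low")
  data <- data.table::copy(recording$data)
  pcols <- c(paste0("l_", sprintf("p%02d", 1:16)), paste0("r_", sprintf("p%02d", 1:16)))
  allzero <- TRUE
  for (cn in pcols) {
    x <- data[[cn]]
    if (any(x != 0)) allzero <- FALSE
    x <- signal::filtfilt(bf, x)
    x <- x - stats::median(x)
    data.table::set(data, j = cn, value = pmax(x, 0))
  }
  if (allzero) {
    warning("all pressure channels are zero; recording passed through")
    return(recording)
  }
  scale <- switch(normalization,
    none = 1,
    session_peak = {
      tf <- rowSums(data[, pcols, with = FALSE])
      1 / max(tf, 1e-9)
    },
    body_weight = {
      if (is.null(body_weight_n)) stop("body_weight_n required", call. = FALSE)
      1 / body_weight_n
    })
  if (scale != 1)
    for (cn in pcols) data.table::set(data, j = cn, value = data[[cn]] * scale)
  out <- insole_recording(data, fs = fs)
  attr(out, "provenance") <- list(filter = sprintf("butterworth order %d, %g Hz, zero-phase",
                                                   filter_order, cutoff_hz),
                                  baseline = "per-channel median subtraction",
                                  normalization = normalization)
  out
}

#' Regional heel and toe force series
#'
#' Sums the configured heel-group and toe-group pressure cells, weighted by
#' cell area, into four regional force series (left/right x heel/toe) on the
#' recording's sampling grid.
#'
#' @param recording an [insole_recording()].
#' @param heel_sensors,toe_sensors disjoint cell index sets within 1..16
#'   (defaults: rear five cells = heel, front six = toe).
#' @param sensor_area_cm2 effective cell area (cm^2).
#' @return list with `time_s` and numeric series `l_heel`, `l_toe`,
#'   `r_heel`, `r_toe` (N).
#' @export
heel_toe_forces <- function(recording, heel_sensors = 12:16, toe_sensors = 1:6,
                            sensor_area_cm2 = 10) {
  stopifnot(inherits(recording, "insole_recording"))
  if (length(intersect(heel_sensors, toe_sensors)) > 0L)
    stop("heel and toe sensor groups must be disjoint", call. = FALSE)
  if (any(!c(heel_sensors, toe_sensors) %in% 1:16))
    stop("sensor indices must lie in 1..16", call. = FALSE)
  out <- list(time_s = recording$data$time_s, fs = recording$fs)
  for (foot in c("l", "r")) {
    p <- foot_pressure(recording, foot)
    out[[paste0(foot, "_heel")]] <- rowSums(p[, heel_sensors, drop = FALSE]) * sensor_area_cm2
    out[[paste0(foot, "_toe")]] <- rowSums(p[, toe_sensors, drop = FALSE]) * sensor_area_cm2
  }
  out
}

# Schmitt-trigger contact state: TRUE while force > on-threshold, released
# when force < on * (1 - hysteresis). Vectorised last-observation fill.
schmitt_contact <- function(force, th_on, hysteresis) {
  th_off <- th_on * (1 - hysteresis)
  s <- rep(NA_real_, length(force))
  s[force > th_on] <- 1
  s[force < th_off] <- 0
  if (is.na(s[1L])) s[1L] <- 0
  idx <- cummax(seq_along(s) * !is.na(s))
  s[idx] > 0
}

resolve_threshold <- function(force, abs_th, thresholds) {
  if (!is.null(abs_th)) return(abs_th)
  thresholds$auto_fraction * stats::quantile(force, 0.95, names = FALSE)
}

#' Detect insole gait events
#'
#' Runs the per-foot four-state contact machine {swing, heel-only, foot-flat,
#' toe-only} on thresholded heel and toe regional forces. Each state entry
#' from its canonical predecessor emits one event: heel strike (swing ->
#' heel-only), toe strike (heel-only -> foot-flat), heel off (foot-flat ->
#' toe-only), toe off (toe-only -> swing). The merged left/right event stream
#' is then assembled into complete gait cycles - eight events in canonical
#' order from one right heel strike to the next - discarding partial cycles at
#' session edges and counting out-of-order cycles in diagnostics.
#'
#' @param forces output of [heel_toe_forces()].
#' @param thresholds a [force_thresholds()].
#' @return object of class `gait_events`: list with `events` (data.frame of
#'   time_s, foot, type), `cycles` (data.frame t01..t08, t01_next, t02_next),
#'   `n_steps` (count of heel strikes, both feet), and diagnostics.
#' @export
detect_gait_events <- function(forces, thresholds = force_thresholds()) {
  stopifnot(inherits(thresholds, "force_thresholds"))
  t <- forces$time_s
  fs <- forces$fs %||% (1 / stats::median(diff(t)))
  min_gap <- max(1L, round(thresholds$min_event_gap_s * fs))

  ev_list <- list()
  for (foot in c("l", "r")) {
    heel <- forces[[paste0(foot, "_heel")]]
    toe <- forces[[paste0(foot, "_toe")]]
    th_h <- resolve_threshold(heel, thresholds$heel_threshold, thresholds)
    th_t <- resolve_threshold(toe, thresholds$toe_threshold, thresholds)
    if (max(heel) <= th_h && max(toe) <= th_t) next  # no contact at all
    hc <- schmitt_contact(heel, th_h, thresholds$hysteresis)
    tc <- schmitt_contact(toe, th_t, thresholds$hysteresis)
    # state code: 0 swing, 1 heel-only, 2 foot-flat, 3 toe-only
    state <- ifelse(hc & tc, 2L, ifelse(hc, 1L, ifelse(tc, 3L, 0L)))
    chg <- which(diff(state) != 0L) + 1L
    if (thresholds$min_event_gap_s > 0 && length(chg) > 1L)
      chg <- chg[c(TRUE, diff(chg) >= min_gap)]
    prev <- state[pmax(chg - 1L, 1L)]
    cur <- state[chg]
    type <- rep(NA_character_, length(chg))
    type[prev == 0L & cur == 1L] <- "heel_strike"
    type[prev == 1L & cur == 2L] <- "toe_strike"
    type[prev == 2L & cur == 3L] <- "heel_off"
    type[prev == 3L & cur == 0L] <- "toe_off"
    keep <- !is.na(type)
    if (any(keep))
      ev_list[[foot]] <- data.frame(time_s = t[chg[keep]], foot = foot,
                                    type = type[keep], stringsAsFactors = FALSE)
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(time_s = numeric(0), foot = character(0), type = character(0))
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  assembled <- assemble_cycles(events)
  n_steps <- sum(events$type == "heel_strike")
  structure(list(events = events, cycles = assembled$cycles, n_steps = n_steps,
                 n_invalid_cycles = assembled$n_invalid),
            class = "gait_events")
}

# Scan the merged event stream for the canonical eight-event cycle pattern
# starting at each right heel strike; successful matches yield t01..t08 plus
# the successor t01' and t02'.
assemble_cycles <- function(events) {
  pattern <- data.frame(
    foot = c("r", "l", "r", "r", "l", "r", "l", "l"),
    type = c("heel_strike", "toe_off", "toe_strike", "heel_off",
             "heel_strike", "toe_off", "toe_strike", "heel_off"))
  empty <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = 10,
    dimnames = list(NULL, c(paste0("t0", 1:8), "t01_next", "t02_next"))))
  if (nrow(events) < 10L) return(list(cycles = empty, n_invalid = 0L))
  key <- paste(events$foot, events$type)
  pkey <- paste(pattern$foot, pattern$type)
  starts <- which(key == pkey[1L])
  rows <- list()
  n_invalid <- 0L
  for (s in starts) {
    if (s + 8L > nrow(events)) next
    seg <- key[s:(s + 7L)]
    if (!identical(seg, pkey)) { n_invalid <- n_invalid + 1L; next }
    if (key[s + 8L] != pkey[1L]) { n_invalid <- n_invalid + 1L; next }
    t01n <- events$time_s[s + 8L]
    # t02' = first left toe off after t01'
    after <- which(events$time_s > t01n & key == "l toe_off")
    if (!length(after)) next  # trailing partial cycle, silently dropped
    rows[[length(rows) + 1L]] <- c(events$time_s[s:(s + 7L)], t01n,
                                   events$time_s[after[1L]])
  }
  if (!length(rows)) return(list(cycles = empty, n_invalid = n_invalid))
  cycles <- as.data.frame(do.call(rbind, rows))
  names(cycles) <- c(paste0("t0", 1:8), "t01_next", "t02_next")
  list(cycles = cycles, n_invalid = n_invalid)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("Insole gait events: %d events, %d complete cycles, %d heel strikes",
              nrow(x$events), nrow(x$cycles), x$n_steps))
  if (x$n_invalid_cycles > 0L)
    cat(sprintf(" (%d invalid cycles skipped)", x$n_invalid_cycles))
  cat("\n")
  invisible(x)
}
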