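#' Compute temporal gait features from insole events
#'
#' Evaluates the canonical per-cycle feature set from the detected event
#' times. Durations (seconds): a01 right single support, a02 left single
#' support, a03 double support (= a06 + a10), a04/a05 right/left side stance,
#' a06/a10 right/left loading response, a07/a11 right/left terminal stance,
#' a08/a12 right/left pre-swing, a09/a13 right/left gait cycle duration, and
#' a14 walking cadence = 1/(t02' - t01) in cycles per second. a15..a25 are
#' the corresponding fractions of the right gait cycle a09.
#'
#' The published right-single-support formula duplicates the left-side-stance
#' one (t02' - t05); the default here uses the biomechanically consistent
#' mirror of a02, namely a01 = t05 - t02 (the interval when only the right
#' foot is on the ground). Set `paper_literal = TRUE` to evaluate the printed
#' formula instead.
#'
#' @param events a [detect_gait_events()] result, or a data.frame of cycle
#'   times with columns t01..t08, t01_next, t02_next.
#' @param paper_literal use the printed a01 formula (t02' - t05).
#' @return object of class `insole_features`: list with `per_cycle`
#'   (data.frame a01..a25), `session` (named numeric of mean/sd aggregates,
#'   `number_of_steps`, `n_cycles`, `pre_swing_variability`), and the
#'   `paper_literal` flag.
#' @export
compute_insole_features <- function(events, paper_literal = FALSE) {
  if (inherits(events, "gait_events")) {
    cy <- events$cycles
    n_steps <- events$n_steps
  } else {
    cy <- as.data.frame(events)
    n_steps <- 2L * nrow(cy)
  }
  if (nrow(cy) == 0L)
    stop("no steps detected: zero complete gait cycles", call. = FALSE)

  f <- data.frame(
    a01 = if (paper_literal) cy$t02_next - cy$t05 else cy$t05 - cy$t02,
    a02 = cy$t01_next - cy$t06,
    a04 = cy$t06 - cy$t01,
    a05 = cy$t02_next - cy$t05,
    a06 = cy$t02 - cy$t01,
    a07 = cy$t04 - cy$t02,
    a08 = cy$t05 - cy$t04,
    a09 = cy$t01_next - cy$t01,
    a10 = cy$t06 - cy$t05,
    a11 = cy$t07 - cy$t06,
    a12 = cy$t01_next - cy$t07,
    a13 = cy$t02_next - cy$t02,
    a14 = 1 / (cy$t02_next - cy$t01))
  f$a03 <- f$a06 + f$a10
  pct_map <- c(a15 = "a01", a16 = "a02", a17 = "a03", a18 = "a04", a19 = "a05",
               a20 = "a06", a21 = "a07", a22 = "a08", a23 = "a10", a24 = "a11",
               a25 = "a12")
  for (p in names(pct_map)) f[[p]] <- f[[pct_map[[p]]]] / f$a09
  f <- f[, c(sprintf("a%02d", 1:14), names(pct_map))]

  means <- colMeans(f)
  sds <- vapply(f, stats::sd, numeric(1))
  session <- c(stats::setNames(means, paste0(names(means), "_mean")),
               stats::setNames(sds, paste0(names(sds), "_std")),
               number_of_steps = n_steps,
               n_cycles = nrow(f),
               pre_swing_variability = stats::sd(c(f$a08, f$a12)))
  structure(list(per_cycle = f, session = session,
                 paper_literal = paper_literal),
            class = "insole_features")
}

#' @export
print.insole_features <- function(x, ...) {
  s <- x$session
  cat(sprintf(paste0("Insole gait features: %d cycles, %d steps\n",
                     "  cycle duration %.3f s, cadence %.3f cycles/s, ",
                     "stance %.1f%% / %.1f%% (R/L)\n"),
              s[["n_cycles"]], s[["number_of_steps"]], s[["a09_mean"]],
              s[["a14_mean"]], 100 * s[["a18_mean"]], 100 * s[["a19_mean"]]))
  invisible(x)
}

#' One-call insole session extraction
#'
#' Convenience wrapper: preprocess, regional forces, event detection, feature
#' computation. Returns the session-level named feature vector used by the
#' agreement and classification stages.
#'
#' @param recording an [insole_recording()].
#' @param thresholds a [force_thresholds()].
#' @param preprocess logical; low-pass filter + baseline-correct first.
#' @param ... passed to [compute_insole_features()].
#' @return an `insole_features` object.
#' @export
extract_insole_session <- function(recording, thresholds = force_thresholds(),
                                   preprocess = TRUE, ...) {
  if (preprocess) recording <- preprocess_insole(recording)
  forces <- heel_toe_forces(recording)
  ev <- detect_gait_events(forces, thresholds)
  compute_insole_features(ev, ...)
}
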