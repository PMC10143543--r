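#' Sample a ground-truth gait event timeline
#'
#' Draws one walking session as a sequence of contiguous gait cycles. Each
#' cycle starts at a right heel strike (`t01`) and carries the eight
#' heel/toe contact events of a full stride in their canonical order:
#' `t01` right heel strike, `t02` left toe off, `t03` right toe strike,
#' `t04` right heel off, `t05` left heel strike, `t06` right toe off,
#' `t07` left toe strike, `t08` left heel off. Successor events `t01'`
#' (next right heel strike) and `t02'` (next left toe off), required by
#' cycle-spanning features such as cycle duration and cadence, are stored
#' per cycle as `t01_next` / `t02_next`.
#'
#' Cycle durations are Gaussian around the speed-class mean. Within a cycle,
#' events sit at fixed phase fractions with sequential (random-walk) jitter:
#' each sub-phase duration t(j-1) -> t(j) receives an independent Gaussian
#' perturbation and event times accumulate them, the way real sub-phase
#' timing variability propagates through a stride. A clinician impairment
#' rating (0-4) inflates the jitter of the two loading-response intervals
#' (t01->t02 and t05->t06) and of the right pre-swing interval (t04->t05),
#' and shifts the left heel-strike fraction (step-time asymmetry). Because
#' later events inherit the accumulated perturbations, pre-swing and
#' double-support variability rise as a consequence of loading-response
#' variability - the timing signature the downstream classifier is asked to
#' detect.
#'
#' @param spec a [simulation_spec()].
#' @param subject_id subject identifier string.
#' @param speed_class one of `"slow"`, `"normal"`, `"fast"`.
#' @param impairment_rating integer 0-4 (clinician gait item rating).
#' @param state medication state label, `"ON"` or `"OFF"`.
#' @param seed integer seed; defaults to `spec$seed`.
#' @param n_cycles number of cycles; `NULL` (default) draws it around
#'   `cycles_per_session * speed_cycle_factor[speed_class]` with SD
#'   `cycles_sd` (floor 3), emulating fixed-distance walks whose stride
#'   count varies with speed and day.
#' @return an object of class `gait_timeline`: list with `cycles` (data.frame
#'   of `t01`..`t08`, `t01_next`, `t02_next` in seconds from session start)
#'   plus the identifying metadata.
#' @export
sample_gait_timeline <- function(spec, subject_id = "S01",
                                 speed_class = c("normal", "slow", "fast"),
                                 impairment_rating = 0L,
                                 state = c("ON", "OFF"),
                                 seed = spec$seed, n_cycles = NULL) {
  speed_class <- match.arg(speed_class)
  state <- match.arg(state)
  stopifnot(impairment_rating %in% 0:4)
  n <- if (!is.null(n_cycles)) as.integer(n_cycles) else {
    fac <- (spec$speed_cycle_factor %||% c(slow = 1, normal = 1, fast = 1))[[speed_class]]
    max(1L, with_seed(child_seed(seed, 99L),
      as.integer(round(spec$cycles_per_session * fac +
                         stats::rnorm(1, 0, spec$cycles_sd %||% 0)))))
  }
  m <- spec$mean_cycle_duration_s[[speed_class]]
  eff <- spec$impairment_effect
  sc <- spec$effect_scale
  r <- impairment_rating
  lr_sd <- spec$lr_sd_s * (1 + eff$lr_gain * sc * r)
  ps_sd <- spec$ps_sd_s * (1 + eff$ps_gain * sc * r)
  base_sd <- spec$event_jitter_s
  asym_shift <- spec$asymmetry + eff$asym_gain * sc * r

  pf <- spec$phase_fractions[paste0("t0", 2:8)]
  # asymmetry moves left heel strike (and with it the left step time) while
  # keeping the ordering margins around t04 and t06
  pf[["t05"]] <- min(max(pf[["t05"]] + asym_shift, pf[["t04"]] + 0.02),
                     pf[["t06"]] - 0.02)
  # jitter SD per sub-phase interval t01->t02, t02->t03, ..., t07->t08:
  # loading-response intervals (t01->t02, t05->t06) and the right pre-swing
  # interval (t04->t05) carry the impairment-inflated variability
  sds <- c(t02 = lr_sd, t03 = base_sd, t04 = base_sd, t05 = ps_sd,
           t06 = lr_sd, t07 = base_sd, t08 = base_sd)

  cyc <- with_seed(seed, {
    dur <- stats::rnorm(n + 1L, mean = m, sd = spec$cycle_cv * m)
    dur <- pmin(pmax(dur, 0.5 * m), 1.5 * m)
    t01 <- spec$lead_in_s + c(0, cumsum(dur))  # length n+2 anchor times
    ev <- matrix(NA_real_, nrow = n + 1L, ncol = 8L,
                 dimnames = list(NULL, paste0("t0", 1:8)))
    for (k in seq_len(n + 1L)) {
      ok <- FALSE
      for (try in 1:100) {
        eps <- cumsum(stats::rnorm(7L, 0, sds))
        tk <- c(t01[k], t01[k] + pf * dur[k] + eps)
        if (all(diff(tk) > 0) && tk[8] < t01[k + 1L]) { ok <- TRUE; break }
      }
      if (!ok) stop("could not sample a valid cycle (event ordering violated ",
                    "after 100 retries); reduce jitter or asymmetry", call. = FALSE)
      ev[k, ] <- tk
    }
    ev
  })

  cycles <- as.data.frame(cyc[seq_len(n), , drop = FALSE])
  cycles$t01_next <- cyc[2:(n + 1L), "t01"]
  cycles$t02_next <- cyc[2:(n + 1L), "t02"]
  out <- list(cycles = cycles, subject_id = subject_id, speed_class = speed_class,
              impairment_rating = as.integer(impairment_rating), state = state)
  class(out) <- "gait_timeline"
  validate_gait_timeline(out)
}

#' Validate a gait timeline
#'
#' Checks the ordering and contiguity invariants: within every cycle the eight
#' events strictly increase, `t01_next` of cycle k equals `t01` of cycle k+1,
#' and all times are finite non-negative seconds.
#' @param timeline a `gait_timeline`.
#' @return the timeline, invisibly-validated (errors on violation).
#' @export
validate_gait_timeline <- function(timeline) {
  cy <- timeline$cycles
  if (nrow(cy) == 0L) return(timeline)
  tm <- as.matrix(cy[, c(paste0("t0", 1:8), "t01_next", "t02_next")])
  if (!all(is.finite(tm)) || any(tm < 0))
    stop("timeline contains non-finite or negative times", call. = FALSE)
  ord <- cbind(tm[, 1:8], tm[, "t01_next"], tm[, "t02_next"])
  if (any(t(apply(ord, 1L, diff)) <= 0))
    stop("event times must strictly increase in order t01..t08, t01', t02'",
         call. = FALSE)
  if (nrow(cy) > 1L &&
      any(abs(cy$t01_next[-nrow(cy)] - cy$t01[-1L]) > 1e-9))
    stop("cycles are not contiguous: t01' of cycle k must equal t01 of k+1",
         call. = FALSE)
  timeline
}

#' @export
print.gait_timeline <- function(x, ...) {
  cat(sprintf("Gait timeline: %d cycles, subject %s, %s speed, rating %d, state %s\n",
              nrow(x$cycles), x$subject_id, x$speed_class,
              x$impairment_rating, x$state))
  if (nrow(x$cycles) > 0L)
    cat(sprintf("  span %.2f - %.2f s, mean cycle %.3f s\n",
                x$cycles$t01[1L], x$cycles$t02_next[nrow(x$cycles)],
                mean(x$cycles$t01_next - x$cycles$t01)))
  invisible(x)
}

# An empty timeline (0 cycles) used by renderer edge-case tests.
empty_timeline <- function(subject_id = "S00", speed_class = "normal",
                           impairment_rating = 0L, state = "ON") {
  cycles <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = 10,
    dimnames = list(NULL, c(paste0("t0", 1:8), "t01_next", "t02_next"))))
  structure(list(cycles = cycles, subject_id = subject_id,
                 speed_class = speed_class,
                 impairment_rating = as.integer(impairment_rating), state = state),
            class = "gait_timeline")
}
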