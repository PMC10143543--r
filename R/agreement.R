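#' Exclude sessions with too few steps
#'
#' Sessions in which either system counted fewer than `min_steps` steps are
#' removed before the cross-system comparison (a session with no or very few
#' steps carries no usable gait information). The boundary is strict: exactly
#' `min_steps` steps is retained.
#'
#' @param sessions data.frame with columns `insole_steps` and `imu_steps`
#'   (plus any identifiers).
#' @param min_steps minimum step count, default 3.
#' @return list with `kept` (filtered data.frame) and `excluded` (the removed
#'   rows plus a `reason` column).
#' @export
exclude_low_step_cases <- function(sessions, min_steps = 3) {
  stopifnot(all(c("insole_steps", "imu_steps") %in% names(sessions)))
  ins_low <- sessions$insole_steps < min_steps
  imu_low <- sessions$imu_steps < min_steps
  drop <- ins_low | imu_low
  excluded <- sessions[drop, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(ins_low[drop] & imu_low[drop], "both systems",
                              ifelse(ins_low[drop], "insole", "imu"))
    excluded$reason <- paste0("< ", min_steps, " steps (", excluded$reason, ")")
  } else excluded$reason <- character(0)
  list(kept = sessions[!drop, , drop = FALSE], excluded = excluded)
}

#' Scale IMU feature values to the insole range
#'
#' Affine min-max map sending the observed [min, max] of the IMU sample onto
#' the observed [min, max] of the insole sample (the insoles act as the
#' reference axis). Affine maps leave Pearson correlation untouched; the
#' rescaling only puts the two systems on one scale for the reliability and
#' Bland-Altman analyses.
#'
#' @param imu_values numeric vector to be rescaled.
#' @param insole_values numeric reference vector.
#' @param feature feature name used in error messages.
#' @return the rescaled vector, with the map's `offset`/`slope` as attributes.
#' @export
scale_to_reference <- function(imu_values, insole_values, feature = "feature") {
  ri <- range(imu_values, na.rm = TRUE)
  rr <- range(insole_values, na.rm = TRUE)
  if (diff(ri) <= 0)
    stop(sprintf("cannot scale '%s': IMU sample is constant", feature),
         call. = FALSE)
  if (length(insole_values[is.finite(insole_values)]) < 2L || diff(rr) <= 0)
    stop(sprintf("cannot scale '%s': need >= 2 distinct insole values", feature),
         call. = FALSE)
  slope <- diff(rr) / diff(ri)
  out <- rr[1L] + (imu_values - ri[1L]) * slope
  attr(out, "slope") <- slope
  attr(out, "offset") <- rr[1L] - ri[1L] * slope
  out
}

#' Flag outlying paired differences
#'
#' Default rule: a pair is an outlier when its difference lies more than
#' `threshold` robust z-units (median/MAD) from the median difference. With a
#' degenerate scale (MAD = 0) nothing is flagged. Flagged pairs are excluded
#' from the correlation and reliability coefficients but kept, marked, for
#' Bland-Altman display.
#'
#' @param x,y paired numeric vectors (reference, comparison).
#' @param threshold robust z threshold, default 3.
#' @return logical mask, `TRUE` = outlier.
#' @export
flag_outliers <- function(x, y, threshold = 3) {
  d <- x - y
  med <- stats::median(d, na.rm = TRUE)
  s <- stats::mad(d, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(d)))
  z <- abs(d - med) / s
  !is.na(z) & z > threshold
}

#' Pearson correlation between paired system outputs
#'
#' Standard product-moment correlation with explicit guards: at least three
#' pairs and non-zero variance on both sides.
#'
#' @param x,y paired numeric vectors.
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("zero variance in one of the series", call. = FALSE)
  stats::cor(x[ok], y[ok])
}

#' Intraclass correlation for single fixed raters
#'
#' Two-way mixed-effects, consistency, single-rater form:
#' ICC(3,1) = (MSR - MSE) / (MSR + (k - 1) MSE), with MSR the between-subject
#' and MSE the residual mean square of the two-way (subject x rater) ANOVA
#' without interaction. Here the two "raters" are the two sensing systems.
#' When `groups` (the instructed speed classes) are supplied, per-group ICCs
#' are reported alongside the pooled headline value.
#'
#' @param x,y paired numeric vectors (the two raters).
#' @param groups optional factor (e.g. speed class) for stratified reporting.
#' @return list with `icc` (pooled), `per_group` (named vector or NULL),
#'   `msr`, `mse`, `n`, `k`.
#' @export
icc_single_fixed <- function(x, y, groups = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(groups)) groups <- groups[ok]
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs for the ICC", call. = FALSE)
  icc_core <- function(x, y) {
    m <- cbind(x, y)
    n <- nrow(m); k <- 2L
    grand <- mean(m)
    ssr <- k * sum((rowMeans(m) - grand)^2)
    ssc <- n * sum((colMeans(m) - grand)^2)
    sse <- sum((m - grand)^2) - ssr - ssc
    msr <- ssr / (n - 1)
    mse <- sse / ((n - 1) * (k - 1))
    list(icc = (msr - mse) / (msr + (k - 1) * mse), msr = msr, mse = mse)
  }
  pooled <- icc_core(x, y)
  per_group <- NULL
  if (!is.null(groups)) {
    gl <- split(seq_len(n), groups)
    per_group <- vapply(gl, function(i)
      if (length(i) >= 3L) icc_core(x[i], y[i])$icc else NA_real_, numeric(1))
  }
  list(icc = pooled$icc, per_group = per_group, msr = pooled$msr,
       mse = pooled$mse, n = n, k = 2L)
}

#' Bland-Altman limits of agreement
#'
#' Differences (reference minus comparison) against pair means; the limits of
#' agreement are `mean difference +/- 1.96 * SD` of the differences.
#'
#' @param x,y paired numeric vectors (reference, comparison).
#' @return list with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`, and
#'   the per-pair `differences` and `means`.
#' @export
bland_altman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  d <- x[ok] - y[ok]
  m <- (x[ok] + y[ok]) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md, sd_diff = sdd,
       loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
       n = length(d), differences = d, means = m)
}

# Mapping between the session-level feature columns of the two systems for
# the common-feature comparison.
COMMON_FEATURES <- data.frame(
  feature = c("walking_cadence", "right_gait_cycle_duration",
              "left_gait_cycle_duration", "right_single_support",
              "left_single_support", "right_stance_phase",
              "left_stance_phase", "number_of_steps"),
  insole_col = c("a14_mean", "a09_mean", "a13_mean", "a01_mean", "a02_mean",
                 "a04_mean", "a05_mean", "number_of_steps"),
  imu_col = c("walking_cadence", "cycle_duration_r", "cycle_duration_l",
              "single_support_r", "single_support_l", "stance_r", "stance_l",
              "number_of_steps"),
  stringsAsFactors = FALSE)

#' Cross-system agreement analysis
#'
#' Reproduces the full comparison between the insole- and IMU-derived session
#' features: low-step-count exclusion, min-max scaling of the IMU values to
#' the insole range, robust outlier flagging, Pearson correlation, ICC(3,1)
#' (pooled and per speed class) and Bland-Altman limits of agreement, for
#' each common feature (walking cadence, left/right gait cycle duration,
#' left/right single support, left/right stance phase, number of steps).
#'
#' @param insole_features,imu_features per-session feature tables from
#'   [extract_cohort_features()] (must share `session_id`).
#' @param manifest the cohort manifest (for speed classes).
#' @param min_steps low-step-count exclusion threshold.
#' @param outlier_z robust z threshold of the outlier rule.
#' @return object of class `agreement_result`: `table` (one row per feature:
#'   r, ICC, Bland-Altman stats, case counts), `per_speed_icc`, and the
#'   exclusion log.
#' @export
compare_systems <- function(insole_features, imu_features, manifest,
                            min_steps = 3, outlier_z = 3) {
  df <- merge(merge(manifest[, c("session_id", "speed")],
                    insole_features, by = "session_id"),
              imu_features, by = "session_id",
              suffixes = c("_ins", "_imu"))
  steps <- data.frame(session_id = df$session_id,
                      insole_steps = df$number_of_steps_ins,
                      imu_steps = df$number_of_steps_imu)
  steps$insole_steps[is.na(steps$insole_steps)] <- 0
  steps$imu_steps[is.na(steps$imu_steps)] <- 0
  filt <- exclude_low_step_cases(steps, min_steps)
  df <- df[df$session_id %in% filt$kept$session_id, , drop = FALSE]

  rows <- list()
  per_speed <- list()
  for (i in seq_len(nrow(COMMON_FEATURES))) {
    feat <- COMMON_FEATURES$feature[i]
    icol <- COMMON_FEATURES$insole_col[i]
    mcol <- COMMON_FEATURES$imu_col[i]
    icol_df <- if (icol %in% names(df)) icol else paste0(icol, "_ins")
    mcol_df <- if (mcol %in% names(df)) mcol else paste0(mcol, "_imu")
    ins <- df[[icol_df]]
    imu <- df[[mcol_df]]
    ok <- is.finite(ins) & is.finite(imu)
    ins <- ins[ok]; imu <- imu[ok]
    spd <- df$speed[ok]
    scaled <- scale_to_reference(imu, ins, feature = feat)
    out <- flag_outliers(ins, scaled, threshold = outlier_z)
    r <- pearson_r(ins[!out], scaled[!out])
    icc <- icc_single_fixed(ins[!out], scaled[!out], groups = spd[!out])
    ba <- bland_altman(ins[!out], scaled[!out])
    per_speed[[feat]] <- icc$per_group
    rows[[feat]] <- data.frame(
      feature = feat, pearson_r = r, icc = icc$icc,
      mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      n_cases = sum(!out), n_outliers = sum(out),
      n_excluded_low_steps = nrow(filt$excluded),
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 per_speed_icc = per_speed, exclusions = filt$excluded),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, digits = 3, ...) {
  cat("Cross-system agreement (insole vs IMU, scaled):\n")
  tb <- x$table
  tb$pearson_r <- round(tb$pearson_r, digits)
  tb$icc <- round(tb$icc, digits)
  print(tb[, c("feature", "pearson_r", "icc", "mean_diff", "loa_low",
               "loa_high", "n_cases", "n_outliers")], row.names = FALSE)
  invisible(x)
}
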