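# Method-agreement validation battery: Bland-Altman bias and 95% limits of
# agreement with the repeatability coefficient RPC = 1.96 * Sd, ordinary
# least squares of the reference on the sensor signal, MAE/RMSE, and paired
# t-tests comparing every metric between the two session timepoints.

BA_METRICS <- c("m_dif", "rpc", "ula", "lla", "r2", "m", "b", "mae", "rmse")

paired_values <- function(sensor, reference, what, min_n = 1L) {
  sv <- series_values(sensor); rv <- series_values(reference)
  if (length(sv) != length(rv)) {
    stop(sprintf("%s: length mismatch (%d vs %d); align and crop first",
                 what, length(sv), length(rv)), call. = FALSE)
  }
  if (length(sv) < min_n) {
    stop(sprintf("%s: need at least %d paired samples", what, min_n), call. = FALSE)
  }
  list(sensor = sv, reference = rv)
}

#' Bland-Altman agreement between sensor and reference
#'
#' Differences are `sensor - reference`. The bias `m_dif` is their mean,
#' `sd` their sample (n-1) standard deviation, the repeatability
#' coefficient `rpc = 1.96 * sd`, and the 95% limits of agreement are
#' `m_dif +/- rpc`.
#'
#' @param sensor,reference Time-aligned [joint_angle_series()] (or numeric
#'   vectors) of equal length >= 2.
#' @return A `"bland_altman"` list: `m_dif`, `sd`, `rpc`, `ula`, `lla`, `n`.
#' @export
bland_altman <- function(sensor, reference) {
  p <- paired_values(sensor, reference, "bland_altman", min_n = 2L)
  d <- p$sensor - p$reference
  m_dif <- mean(d)
  s <- stats::sd(d)
  rpc <- 1.96 * s
  structure(list(m_dif = m_dif, sd = s, rpc = rpc,
                 ula = m_dif + rpc, lla = m_dif - rpc, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d  bias %.3f deg, RPC %.3f, LA [%.3f, %.3f]\n",
              x$n, x$m_dif, x$rpc, x$lla, x$ula))
  invisible(x)
}

#' Linear regression between sensor and reference
#'
#' Ordinary least squares with the sensor signal as predictor:
#' `reference = m * sensor + b` (so a knee slope below 1 reads as the
#' sensors overestimating knee flexion excursion). `r2` is the squared
#' Pearson correlation. Set `orientation = "sensor_on_ref"` to swap the
#' roles.
#'
#' @param sensor,reference Time-aligned series of equal length >= 3.
#' @param orientation Which signal is the predictor.
#' @return A `"regression_result"` list: `r2`, `m`, `b`, `n`.
#' @export
linear_fit <- function(sensor, reference,
                       orientation = c("ref_on_sensor", "sensor_on_ref")) {
  orientation <- match.arg(orientation)
  p <- paired_values(sensor, reference, "linear_fit", min_n = 3L)
  x <- if (orientation == "ref_on_sensor") p$sensor else p$reference
  y <- if (orientation == "ref_on_sensor") p$reference else p$sensor
  if (stats::sd(x) == 0) {
    stop("linear_fit: zero-variance predictor; slope is undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  structure(list(r2 = r^2, m = unname(stats::coef(fit)[2]),
                 b = unname(stats::coef(fit)[1]), n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n=%d  y = %.4f x + %.4f, r2 = %.4f\n",
              x$n, x$m, x$b, x$r2))
  invisible(x)
}

#' Mean absolute and root-mean-square error
#'
#' @param sensor,reference Time-aligned series of equal length >= 1.
#' @return An `"error_metrics"` list: `mae`, `rmse`, `n` (degrees).
#' @export
error_metrics <- function(sensor, reference) {
  p <- paired_values(sensor, reference, "error_metrics", min_n = 1L)
  d <- p$sensor - p$reference
  structure(list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), n = length(d)),
            class = "error_metrics")
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("<error_metrics> n=%d  MAE %.3f deg, RMSE %.3f deg\n",
              x$n, x$mae, x$rmse))
  invisible(x)
}

#' Full agreement battery for one aligned series pair
#'
#' Convenience wrapper computing [bland_altman()], [linear_fit()] and
#' [error_metrics()] at once.
#'
#' @inheritParams linear_fit
#' @return A list `bland_altman`, `regression`, `errors`, plus a flat
#'   named vector `row` with the nine Table-style metrics
#'   (`m_dif, rpc, ula, lla, r2, m, b, mae, rmse`).
#' @export
agreement_metrics <- function(sensor, reference,
                              orientation = c("ref_on_sensor", "sensor_on_ref")) {
  ba <- bland_altman(sensor, reference)
  reg <- linear_fit(sensor, reference, orientation)
  err <- error_metrics(sensor, reference)
  row <- c(m_dif = ba$m_dif, rpc = ba$rpc, ula = ba$ula, lla = ba$lla,
           r2 = reg$r2, m = reg$m, b = reg$b, mae = err$mae, rmse = err$rmse)
  list(bland_altman = ba, regression = reg, errors = err, row = row)
}

#' Paired t-tests of agreement metrics between timepoints
#'
#' For each of the nine agreement metrics, performs a two-tailed paired
#' t-test of the per-participant values at the later timepoint against the
#' earlier one (differences are T2 - T1). No multiple-testing correction
#' is applied across the nine metrics.
#'
#' When the paired differences have zero variance the t statistic is
#' undefined; by convention the test reports `p = 0` (significant) when the
#' mean difference is non-zero and `p = 1` when it is zero, with a warning.
#'
#' @param t1,t2 Data frames of per-participant metrics with a
#'   `participant` column and the metric columns
#'   `m_dif, rpc, ula, lla, r2, m, b, mae, rmse` (as produced by
#'   [validate_cohort()]'s per-participant table, one row per participant).
#' @param alpha Two-sided significance level (default 0.05).
#' @param metrics Metric columns to test.
#' @return A data frame with one row per metric: `metric`, `mean_diff`
#'   (T2 - T1), `sd_diff`, `t_stat`, `p_value`, `significant`.
#' @export
compare_timepoints <- function(t1, t2, alpha = 0.05, metrics = BA_METRICS) {
  if (!all(c("participant", metrics) %in% names(t1)) ||
      !all(c("participant", metrics) %in% names(t2))) {
    stop("metric tables need 'participant' plus the nine metric columns",
         call. = FALSE)
  }
  if (!setequal(t1$participant, t2$participant)) {
    miss <- c(setdiff(t1$participant, t2$participant),
              setdiff(t2$participant, t1$participant))
    stop("participant sets differ between timepoints: ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(t1$participant) || anyDuplicated(t2$participant)) {
    stop("one row per participant expected in each metric table", call. = FALSE)
  }
  t2 <- t2[match(t1$participant, t2$participant), , drop = FALSE]
  n <- nrow(t1)
  if (n < 2L) stop("paired t-test needs at least 2 participants", call. = FALSE)
  rows <- lapply(metrics, function(mt) {
    d <- t2[[mt]] - t1[[mt]]
    md <- mean(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      warning(sprintf("zero-variance paired differences for '%s'; degenerate t-test",
                      mt), call. = FALSE)
      p <- if (md == 0) 1 else 0
      tt <- if (md == 0) 0 else sign(md) * Inf
    } else {
      ht <- stats::t.test(t2[[mt]], t1[[mt]], paired = TRUE)
      tt <- unname(ht$statistic)
      p <- ht$p.value
    }
    data.frame(metric = mt, mean_diff = md, sd_diff = sdd,
               t_stat = tt, p_value = p, significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "n_participants") <- n
  out
}

#' Cohort summary of per-participant agreement metrics
#'
#' Produces (a) the across-participant mean and standard deviation of every
#' metric, stratified by joint, timepoint and reference-zeroing variant
#' (the per-participant summary surface), and (b) optionally a pooled
#' analysis over all participants' concatenated aligned samples (the
#' scatter-plot surface).
#'
#' @param per_participant Data frame with columns `participant`, `joint`,
#'   `timepoint`, `variant` and the nine metric columns.
#' @param pooled_pairs Optional named list of `list(sensor=, reference=)`
#'   numeric-pair lists (one per joint/timepoint cell) to pool; each cell's
#'   sensor/reference vectors are concatenated participant-wise before a
#'   single [bland_altman()] + [linear_fit()] run.
#' @return A list with `cohort` (data frame of mean/sd per metric per
#'   stratum) and `pooled` (list of per-cell agreement results, or NULL).
#' @export
summarize_cohort <- function(per_participant, pooled_pairs = NULL) {
  stopifnot(is.data.frame(per_participant), nrow(per_participant) >= 1L)
  strata <- interaction(per_participant$joint, per_participant$timepoint,
                        per_participant$variant, drop = TRUE)
  rows <- lapply(split(per_participant, strata), function(sub) {
    out <- data.frame(joint = sub$joint[1], timepoint = sub$timepoint[1],
                      variant = sub$variant[1], n_participants = nrow(sub))
    for (mt in BA_METRICS) {
      out[[paste0(mt, "_mean")]] <- mean(sub[[mt]])
      out[[paste0(mt, "_sd")]] <- if (nrow(sub) > 1) stats::sd(sub[[mt]]) else 0
    }
    out
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  pooled <- NULL
  if (!is.null(pooled_pairs)) {
    pooled <- lapply(pooled_pairs, function(cell) {
      sensor <- unlist(lapply(cell, `[[`, "sensor"), use.names = FALSE)
      reference <- unlist(lapply(cell, `[[`, "reference"), use.names = FALSE)
      agreement_metrics(sensor, reference)
    })
  }
  list(cohort = cohort, pooled = pooled)
}
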