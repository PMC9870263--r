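# Pipeline configuration and the end-to-end validation run: sensor streams
# -> roll extraction -> joint model -> static zeroing -> time alignment ->
# analysis window -> agreement battery -> cohort summary and T1/T2
# comparisons.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with the protocol defaults:
#' 60 Hz sampling, intrinsic ZYX Euler convention (roll about the
#' longitudinal axis), 5-s lag search, the second 20-s period of the trial
#' as analysis window, and a two-sided 0.05 significance level.
#'
#' @param rate_hz Sampling rate, Hz.
#' @param euler_convention `"ZYX"` or `"ZXY"`.
#' @param max_lag_s Cross-correlation lag search half-width, seconds.
#' @param alpha Significance level for the timepoint comparisons, in (0,1).
#' @param regression_orientation `"ref_on_sensor"` (reference = m*sensor+b,
#'   default) or `"sensor_on_ref"`.
#' @param analysis_window_s Length-2 start/end (seconds) of the analyzed
#'   segment of each aligned trial; `NULL` analyzes the full overlap.
#' @param calibration_window,central_fraction Passed to [compute_offsets()].
#' @param hip_sign_flip,knee_sign_flip Negate a joint's sensor-derived
#'   angle (the model's operand order is hip = sacrum - thigh,
#'   knee = thigh - shank; flip if a mounting convention reverses a sign).
#' @param align_mode `"knee"`: one lag per trial estimated on the knee
#'   signal (largest excursion) and applied to both joints; `"per_joint"`:
#'   estimate separately per joint.
#' @param seed Seed recorded for provenance.
#' @return A `"run_config"` object.
#' @export
run_config <- function(rate_hz = 60, euler_convention = c("ZYX", "ZXY"),
                       max_lag_s = 5, alpha = 0.05,
                       regression_orientation = c("ref_on_sensor", "sensor_on_ref"),
                       analysis_window_s = c(20, 40),
                       calibration_window = c("full", "central"),
                       central_fraction = 0.8,
                       hip_sign_flip = FALSE, knee_sign_flip = FALSE,
                       align_mode = c("knee", "per_joint"), seed = NULL) {
  euler_convention <- match.arg(euler_convention)
  regression_orientation <- match.arg(regression_orientation)
  calibration_window <- match.arg(calibration_window)
  align_mode <- match.arg(align_mode)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (max_lag_s <= 0) stop("max_lag_s must be > 0", call. = FALSE)
  if (!is.null(analysis_window_s)) {
    if (length(analysis_window_s) != 2L || analysis_window_s[1] < 0 ||
        diff(analysis_window_s) <= 0) {
      stop("analysis_window_s must be c(start, end) with end > start >= 0",
           call. = FALSE)
    }
  }
  structure(list(rate_hz = rate_hz, euler_convention = euler_convention,
                 max_lag_s = max_lag_s, alpha = alpha,
                 regression_orientation = regression_orientation,
                 analysis_window_s = analysis_window_s,
                 calibration_window = calibration_window,
                 central_fraction = central_fraction,
                 hip_sign_flip = hip_sign_flip, knee_sign_flip = knee_sign_flip,
                 align_mode = align_mode, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  win <- if (is.null(x$analysis_window_s)) "full overlap"
         else sprintf("%g-%g s", x$analysis_window_s[1], x$analysis_window_s[2])
  cat(sprintf("<run_config> %g Hz, %s, max lag %g s, window %s, alpha %g, regression %s, align %s\n",
              x$rate_hz, x$euler_convention, x$max_lag_s, win, x$alpha,
              x$regression_orientation, x$align_mode))
  invisible(x)
}

#' Joint angles for one simulated (or loaded) session
#'
#' Runs the sensor half of the pipeline: roll extraction from the three
#' orientation streams, the single-axis joint model, static-trial offsets
#' from the calibration streams, and zeroing. Reference joint angles are
#' returned both raw and zeroed against the reference's own calibration
#' means.
#'
#' @param session List with `sensors` (named list of three
#'   [orientation_series()]), `reference_hip`, `reference_knee` (may be
#'   `NULL` when no reference exists).
#' @param calibration List with the same fields recorded during the
#'   standing trial.
#' @param config A [run_config()].
#' @return List: zeroed `hip_sensor`/`knee_sensor`, raw and zeroed
#'   reference variants, and the two [calibration_offsets()] objects.
#' @export
session_joint_angles <- function(session, calibration, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  conv <- config$euler_convention
  sensor_joints <- function(streams) {
    rolls <- lapply(streams[c("sacrum", "thigh", "shank")], extract_roll_series, conv)
    list(hip = hip_flexion(rolls$sacrum, rolls$thigh, config$hip_sign_flip),
         knee = knee_flexion(rolls$thigh, rolls$shank, config$knee_sign_flip))
  }
  walk <- sensor_joints(session$sensors)
  cal <- sensor_joints(calibration$sensors)
  offsets <- compute_offsets(cal$hip, cal$knee, window = config$calibration_window,
                             central_fraction = config$central_fraction)
  out <- list(
    hip_sensor = apply_zeroing(walk$hip, offsets),
    knee_sensor = apply_zeroing(walk$knee, offsets),
    sensor_offsets = offsets
  )
  if (!is.null(session$reference_hip)) {
    ref_offsets <- compute_offsets(calibration$reference_hip,
                                   calibration$reference_knee,
                                   window = config$calibration_window,
                                   central_fraction = config$central_fraction)
    out$hip_ref_raw <- session$reference_hip
    out$knee_ref_raw <- session$reference_knee
    out$hip_ref_zeroed <- apply_zeroing(session$reference_hip, ref_offsets)
    out$knee_ref_zeroed <- apply_zeroing(session$reference_knee, ref_offsets)
    out$reference_offsets <- ref_offsets
  }
  out
}

window_indices <- function(overlap_n, config) {
  if (is.null(config$analysis_window_s)) return(seq_len(overlap_n))
  i0 <- round(config$analysis_window_s[1] * config$rate_hz) + 1L
  i1 <- round(config$analysis_window_s[2] * config$rate_hz)
  if (i1 > overlap_n) {
    stop(sprintf("analysis window ends at sample %d but aligned overlap has only %d",
                 i1, overlap_n), call. = FALSE)
  }
  i0:i1
}

#' Validate a cohort of sessions against their reference streams
#'
#' The full method-agreement pipeline. Per participant and timepoint:
#' compute zeroed sensor joint angles, align against the raw reference by
#' cross-correlation (one lag per trial from the knee signal by default),
#' crop to the aligned overlap, cut the analysis window, and run the
#' agreement battery for each joint against both the raw and the zeroed
#' reference variant. Then: across-participant summary, pooled analysis
#' over concatenated samples, and paired t-tests of every metric between
#' timepoints (skipped with a message when only one timepoint exists).
#'
#' @param cohort A [simulate_cohort()] result, or any list with the same
#'   shape (`participants`, each with `calibration`, `T1` and/or `T2`).
#' @param config A [run_config()].
#' @return A `"validation_report"` object: `per_participant` (metric
#'   table), `alignment`, `cohort` (across-participant mean/sd), `pooled`
#'   (per joint/timepoint/variant over concatenated samples),
#'   `comparisons` (T1-vs-T2 paired t-tests per joint/variant), `config`.
#' @export
validate_cohort <- function(cohort, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  rows <- list(); align_rows <- list()
  pooled_acc <- list()
  for (pt in cohort$participants) {
    for (tp in intersect(c("T1", "T2"), names(pt))) {
      session <- pt[[tp]]
      if (is.null(session)) next
      ang <- session_joint_angles(session, pt$calibration, config)
      lag_knee <- align_by_xcorr(ang$knee_sensor, ang$knee_ref_raw,
                                 config$max_lag_s, config$rate_hz)
      for (joint in c("hip", "knee")) {
        r <- if (config$align_mode == "per_joint") {
          align_by_xcorr(ang[[paste0(joint, "_sensor")]],
                         ang[[paste0(joint, "_ref_raw")]],
                         config$max_lag_s, config$rate_hz)
        } else lag_knee
        for (variant in c("raw", "zeroed")) {
          pair <- crop_to_overlap(ang[[paste0(joint, "_sensor")]],
                                  ang[[paste0(joint, "_ref_", variant)]], r)
          idx <- window_indices(r$overlap_length, config)
          sv <- pair$a$values_deg[idx]; rv <- pair$b$values_deg[idx]
          am <- agreement_metrics(sv, rv, config$regression_orientation)
          key <- paste(joint, tp, variant, sep = ".")
          pooled_acc[[key]] <- c(pooled_acc[[key]],
                                 list(list(sensor = sv, reference = rv)))
          rows[[length(rows) + 1L]] <- data.frame(
            participant = pt$id, joint = joint, timepoint = tp,
            variant = variant, n = am$errors$n,
            lag_samples = r$lag_samples, as.list(am$row))
        }
        align_rows[[length(align_rows) + 1L]] <- data.frame(
          participant = pt$id, timepoint = tp, joint = joint,
          lag_samples = r$lag_samples, lag_seconds = r$lag_seconds,
          peak_correlation = r$peak_correlation,
          overlap_length = r$overlap_length)
      }
    }
  }
  per_participant <- do.call(rbind, rows)
  alignment <- do.call(rbind, align_rows)
  summary <- summarize_cohort(per_participant, pooled_acc)
  pooled_rows <- lapply(names(summary$pooled), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    data.frame(joint = parts[1], timepoint = parts[2], variant = parts[3],
               n = summary$pooled[[key]]$errors$n,
               as.list(summary$pooled[[key]]$row))
  })
  pooled <- do.call(rbind, pooled_rows)
  timepoints <- unique(per_participant$timepoint)
  comparisons <- NULL
  if (all(c("T1", "T2") %in% timepoints)) {
    comp_rows <- list()
    for (joint in c("hip", "knee")) {
      for (variant in c("raw", "zeroed")) {
        sel <- per_participant$joint == joint & per_participant$variant == variant
        t1 <- per_participant[sel & per_participant$timepoint == "T1", ]
        t2 <- per_participant[sel & per_participant$timepoint == "T2", ]
        cmp <- compare_timepoints(t1, t2, alpha = config$alpha)
        cmp$joint <- joint; cmp$variant <- variant
        comp_rows[[length(comp_rows) + 1L]] <- cmp
      }
    }
    comparisons <- do.call(rbind, comp_rows)
    rownames(comparisons) <- NULL
  } else {
    message("single timepoint present: T1-vs-T2 comparisons omitted")
  }
  structure(list(per_participant = per_participant, alignment = alignment,
                 cohort = summary$cohort, pooled = pooled,
                 comparisons = comparisons, config = config),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d participants, %d metric rows\n",
              length(unique(x$per_participant$participant)),
              nrow(x$per_participant)))
  cat("\nAcross-participant means (bias / RPC / r2 / MAE):\n")
  c <- x$cohort
  for (i in seq_len(nrow(c))) {
    cat(sprintf("  %-5s %-3s %-7s  Mdif %6.2f  RPC %5.2f  r2 %5.3f  MAE %5.2f deg\n",
                c$joint[i], c$timepoint[i], c$variant[i],
                c$m_dif_mean[i], c$rpc_mean[i], c$r2_mean[i], c$mae_mean[i]))
  }
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$significant, ]
    cat(sprintf("\n%d of %d T1-vs-T2 metric comparisons significant at alpha=%g\n",
                nrow(sig), nrow(x$comparisons), x$config$alpha))
  }
  invisible(x)
}

#' Write a validation report as JSON
#'
#' Nested participant -> joint -> timepoint -> variant structure plus the
#' cohort summary, pooled analysis and timepoint comparisons. Numbers are
#' written with 6 decimal digits so identical runs produce byte-identical
#' files.
#'
#' @param report A [validate_cohort()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  pp <- report$per_participant
  nested <- list()
  for (id in unique(pp$participant)) {
    jl <- list()
    for (joint in unique(pp$joint[pp$participant == id])) {
      tl <- list()
      for (tp in unique(pp$timepoint[pp$participant == id & pp$joint == joint])) {
        vl <- list()
        for (variant in c("raw", "zeroed")) {
          row <- pp[pp$participant == id & pp$joint == joint &
                    pp$timepoint == tp & pp$variant == variant, ]
          if (nrow(row) != 1L) next
          vl[[variant]] <- list(
            bland_altman = list(m_dif = row$m_dif, rpc = row$rpc,
                                ula = row$ula, lla = row$lla),
            regression = list(r2 = row$r2, m = row$m, b = row$b),
            errors = list(mae = row$mae, rmse = row$rmse),
            n = row$n, lag_samples = row$lag_samples)
        }
        tl[[tp]] <- vl
      }
      jl[[joint]] <- tl
    }
    nested[[id]] <- jl
  }
  out <- list(participants = nested, cohort = report$cohort,
              pooled = report$pooled,
              comparisons = report$comparisons,
              alpha = report$config$alpha)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 6,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Write the across-participant summary table as CSV
#'
#' One row per joint/timepoint/variant with the mean and sd across
#' participants of Mdif, RPC, Upper LA, Lower LA, r2, m, b, MAE, RMSE.
#'
#' @param report A [validate_cohort()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table1_csv <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  utils::write.csv(report$cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the T1-vs-T2 comparison table as CSV
#'
#' @param report A [validate_cohort()] result (two timepoints required).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons_csv <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  if (is.null(report$comparisons)) {
    stop("report has no timepoint comparisons (single timepoint)", call. = FALSE)
  }
  utils::write.csv(report$comparisons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
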