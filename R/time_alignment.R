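# Cross-correlation time alignment between the sensor-derived and
# camera-based joint-angle streams.  The two systems are started
# independently, so a variable integer-sample offset is estimated by
# maximizing the normalized (Pearson) correlation over a bounded lag range.

#' Align two joint-angle streams by cross-correlation
#'
#' Finds the integer lag in `[-max_lag, +max_lag]` samples that maximizes
#' the Pearson correlation between the overlapping, mean-removed parts of
#' the two series. A positive lag means `a` (the sensor stream) lags `b`
#' (the reference): `a[i]` lines up with `b[i - lag]`.
#'
#' Ties in the correlation peak are broken toward the smallest `|lag|`,
#' then toward the negative lag, so degenerate periodic inputs resolve
#' deterministically.
#'
#' @param a,b [joint_angle_series()] (or plain numeric vectors) at the
#'   same sampling rate.
#' @param max_lag_s Half-width of the lag search window, seconds.
#' @param rate_hz Sampling rate; taken from the series when omitted.
#' @return An `"alignment_result"` list: `lag_samples`, `lag_seconds`,
#'   `peak_correlation`, `overlap_length`.
#' @export
align_by_xcorr <- function(a, b, max_lag_s = 5, rate_hz = NULL) {
  av <- series_values(a); bv <- series_values(b)
  if (is.null(rate_hz)) {
    rate_hz <- if (inherits(a, "joint_angle_series")) a$rate_hz else 60
  }
  if (inherits(a, "joint_angle_series") && inherits(b, "joint_angle_series") &&
      a$rate_hz != b$rate_hz) {
    stop("align_by_xcorr: sampling rates differ", call. = FALSE)
  }
  if (!all(is.finite(av)) || !all(is.finite(bv))) {
    stop("align_by_xcorr: non-finite values", call. = FALSE)
  }
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop("align_by_xcorr: zero-variance (constant) input; lag is undefined",
         call. = FALSE)
  }
  max_lag <- as.integer(floor(max_lag_s * rate_hz))
  if (min(length(av), length(bv)) <= max_lag + 1L) {
    stop("align_by_xcorr: series shorter than the lag search window", call. = FALSE)
  }
  lags <- seq.int(-max_lag, max_lag)
  cors <- vapply(lags, function(L) lagged_cor(av, bv, L), numeric(1))
  best <- max(cors, na.rm = TRUE)
  cand <- which(!is.na(cors) & cors >= best - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  pick <- cand[1]
  lag <- lags[pick]
  structure(list(
    lag_samples = lag,
    lag_seconds = lag / rate_hz,
    peak_correlation = cors[pick],
    overlap_length = overlap_len(length(av), length(bv), lag)
  ), class = "alignment_result")
}

# Pearson correlation of a[i] against b[i - L] over the overlap
lagged_cor <- function(a, b, L) {
  n_a <- length(a); n_b <- length(b)
  ia <- max(1L, 1L + L):min(n_a, n_b + L)
  if (length(ia) < 3L) return(NA_real_)
  ib <- ia - L
  sa <- a[ia]; sb <- b[ib]
  if (stats::sd(sa) == 0 || stats::sd(sb) == 0) return(NA_real_)
  stats::cor(sa, sb)
}

overlap_len <- function(n_a, n_b, lag) {
  min(n_a, n_b + lag) - max(1L, 1L + lag) + 1L
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> lag %+d samples (%+.4f s), peak r = %.4f, overlap %d\n",
              x$lag_samples, x$lag_seconds, x$peak_correlation, x$overlap_length))
  invisible(x)
}

#' Crop two series to their aligned overlap
#'
#' After alignment, drops the non-overlapping edges so that sample `i` of
#' each output corresponds to the same physical instant.
#'
#' @param a,b The two [joint_angle_series()] passed to [align_by_xcorr()],
#'   in the same order.
#' @param r The [align_by_xcorr()] result.
#' @return A list of the two cropped series (`a`, `b`), equal length
#'   `r$overlap_length`.
#' @export
crop_to_overlap <- function(a, b, r) {
  stopifnot(inherits(r, "alignment_result"))
  av <- series_values(a); bv <- series_values(b)
  L <- r$lag_samples
  if (abs(L) >= min(length(av), length(bv))) {
    stop("crop_to_overlap: lag leaves no overlap", call. = FALSE)
  }
  ia <- max(1L, 1L + L):min(length(av), length(bv) + L)
  ib <- ia - L
  if (length(ia) < 1L) stop("crop_to_overlap: empty overlap", call. = FALSE)
  list(a = subset_series(a, ia), b = subset_series(b, ib))
}

series_values <- function(x) {
  if (inherits(x, "joint_angle_series")) x$values_deg
  else if (is.numeric(x)) as.numeric(x)
  else stop("expected a joint_angle_series or numeric vector", call. = FALSE)
}

subset_series <- function(x, idx) {
  if (inherits(x, "joint_angle_series")) {
    joint_angle_series(x$joint, x$source, x$values_deg[idx], x$rate_hz,
                       zeroed = x$zeroed)
  } else {
    x[idx]
  }
}
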