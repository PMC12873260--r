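# Pupil diameter from four tracked cardinal points, likelihood filtering,
# normalized time courses, and pupil-EEG correlation.

#' Compute pupil diameter from cardinal keypoints
#'
#' Diameter = (|N - S| + |E - W|) / 2, computed only for frames where all
#' four keypoint likelihoods reach `min_likelihood` (default 0.99, the
#' "confidence above 99%" cut); other frames are missing.
#'
#' @param trace a [vs_pupil_trace]
#' @param min_likelihood minimum per-point likelihood
#' @return the trace with a `diameter` column added to `$frames`
#' @export
compute_diameter <- function(trace, min_likelihood = 0.99) {
  stopifnot(inherits(trace, "vs_pupil_trace"))
  fr <- trace$frames
  d_ns <- sqrt((fr$north_x - fr$south_x)^2 + (fr$north_y - fr$south_y)^2)
  d_ew <- sqrt((fr$east_x - fr$west_x)^2 + (fr$east_y - fr$west_y)^2)
  ok <- fr$north_likelihood >= min_likelihood &
    fr$south_likelihood >= min_likelihood &
    fr$east_likelihood >= min_likelihood &
    fr$west_likelihood >= min_likelihood
  fr$diameter <- ifelse(ok, (d_ns + d_ew) / 2, NA_real_)
  trace$frames <- fr
  trace
}

#' Binned pupil time course as percent of baseline
#'
#' Per-bin mean of non-missing diameters, expressed as percent of the mean
#' diameter over the baseline window (so 175% corresponds to a +75%
#' dilation).
#'
#' @param trace a [vs_pupil_trace] with diameters ([compute_diameter()])
#' @param bin_s bin width (s)
#' @param baseline_window numeric(2), time window (s) defining 100%
#' @param interpolate_max_gap_s if positive, linearly interpolate missing
#'   frames across gaps up to this long before binning (off by default)
#' @return data frame: `t_mid` (s), `pct`, `n_frames`; empty bins are `NA`
#' @export
bin_timecourse <- function(trace, bin_s = 60, baseline_window = NULL,
                           interpolate_max_gap_s = 0) {
  stopifnot(inherits(trace, "vs_pupil_trace"))
  fr <- trace$frames
  if (!("diameter" %in% names(fr))) stop("run compute_diameter() first")
  d <- fr$diameter
  if (interpolate_max_gap_s > 0 && anyNA(d) && any(!is.na(d))) {
    filled <- stats::approx(fr$t[!is.na(d)], d[!is.na(d)], xout = fr$t,
                            rule = 1)$y
    gap_runs <- rle(is.na(d))
    ends <- cumsum(gap_runs$lengths)
    for (i in seq_along(gap_runs$lengths)) {
      if (!gap_runs$values[i]) next
      s <- ends[i] - gap_runs$lengths[i] + 1
      if (fr$t[ends[i]] - fr$t[s] <= interpolate_max_gap_s)
        d[s:ends[i]] <- filled[s:ends[i]]
    }
  }
  if (is.null(baseline_window)) baseline_window <- c(0, min(300, max(fr$t)))
  base_sel <- fr$t >= baseline_window[1] & fr$t < baseline_window[2] & !is.na(d)
  if (!any(base_sel)) stop("baseline window contains no valid frames")
  base <- mean(d[base_sel])
  bin <- floor(fr$t / bin_s)
  bins <- 0:max(bin)
  val <- vapply(bins, function(b) {
    s <- bin == b & !is.na(d)
    if (!any(s)) NA_real_ else mean(d[s])
  }, 0)
  nn <- vapply(bins, function(b) sum(bin == b & !is.na(d)), 0L)
  data.frame(t_mid = (bins + 0.5) * bin_s, pct = 100 * val / base,
             n_frames = nn)
}

#' Ordinary least-squares correlation between pupil and EEG band power
#'
#' Pairs are dropped where either series is missing; requires n >= 3 and
#' non-zero variance in both variables.
#'
#' @param pupil_bins,band_power_bins paired numeric vectors (e.g. per-minute
#'   means)
#' @return list of class `vs_correlation`: `r_squared`, `slope`,
#'   `intercept`, `p_value`, `n`
#' @export
correlate_pupil_eeg <- function(pupil_bins, band_power_bins) {
  stopifnot(length(pupil_bins) == length(band_power_bins))
  ok <- !is.na(pupil_bins) & !is.na(band_power_bins)
  x <- band_power_bins[ok]
  y <- pupil_bins[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the variables")
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- r^2
  p <- if (r2 >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(r_squared = r2, slope = slope, intercept = intercept,
                 p_value = p, n = n),
            class = "vs_correlation")
}

#' @export
print.vs_correlation <- function(x, ...) {
  cat(sprintf("<vs_correlation> r^2 = %.3f (slope %.4g, p = %.3g, n = %d)\n",
              x$r_squared, x$slope, x$p_value, x$n))
  invisible(x)
}
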