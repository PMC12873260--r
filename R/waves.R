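# LFP slow-wave detection and peri-wave multi-unit OFF-period profiling.
#
# Waves are detected on the 0.5-4 Hz zero-phase Chebyshev type II filtered
# LFP as maximal positive excursions bounded by zero crossings, accepted only
# when both the preceding and following excursions dip below zero.  All
# detected waves feed the amplitude/duration distributions; only the
# mean + 2 SD high-amplitude subset feeds the multi-unit analysis.

# cached filter designs keyed by sampling rate
.vs_filter_cache <- new.env(parent = emptyenv())

#' Slow-wave band-pass filter (0.5-4 Hz passband, 0.2/8 Hz stopband edges)
#'
#' Zero-phase Chebyshev type II design of the minimum order reaching 40 dB
#' stopband attenuation at the stated edges.  Being zero-phase, the peak of a
#' symmetric input is preserved in time.
#'
#' @param x LFP signal (µV)
#' @param fs sampling rate (Hz)
#' @return filtered signal, same length
#' @export
filter_swa <- function(x, fs = 256) {
  key <- paste0("swa_", fs)
  filt <- .vs_filter_cache[[key]]
  if (is.null(filt)) {
    filt <- design_bandpass(fs, c(0.5, 4), c(0.2, 8))
    .vs_filter_cache[[key]] <- filt
  }
  ord <- sum(vapply(filt$stages, function(s) 2L * length(s$sos), 1L))
  if (length(x) < 3 * ord) stop("signal shorter than 3x the filter order")
  apply_filter(filt, x)
}

#' Detect slow waves on a filtered signal
#'
#' A wave is a maximal run of strictly positive samples whose neighbouring
#' excursions on both sides dip below zero.  Onset/offset are placed at the
#' bounding zero crossings, the peak at the maximum within the excursion, and
#' the amplitude is that maximum.  Events are non-overlapping and
#' time-ordered; sample `i` is at time `(i-1)/fs`.
#'
#' @param x filtered signal (e.g. from [filter_swa()])
#' @param fs sampling rate (Hz)
#' @return data frame of class `vs_waves`: `onset_t`, `peak_t`, `offset_t`
#'   (s), `amplitude` (µV), `duration` (s)
#' @export
detect_waves <- function(x, fs = 256) {
  n <- length(x)
  pos <- x > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  seg_min <- vapply(seq_len(k), function(i) min(x[starts[i]:ends[i]]), 0)
  keep <- which(r$values)
  keep <- keep[keep > 1 & keep < k]
  if (length(keep)) {
    ok <- seg_min[keep - 1L] < 0 & seg_min[keep + 1L] < 0
    keep <- keep[ok]
  }
  if (length(keep) == 0) {
    return(structure(data.frame(onset_t = numeric(0), peak_t = numeric(0),
                                offset_t = numeric(0), amplitude = numeric(0),
                                duration = numeric(0)),
                     class = c("vs_waves", "data.frame")))
  }
  onset <- (starts[keep] - 1) / fs
  offset <- ends[keep] / fs
  pk <- vapply(keep, function(i) {
    j <- starts[i]:ends[i]
    j[which.max(x[j])]
  }, 1L)
  structure(data.frame(onset_t = onset, peak_t = (pk - 1) / fs,
                       offset_t = offset, amplitude = x[pk],
                       duration = offset - onset),
            class = c("vs_waves", "data.frame"))
}

#' Select high-amplitude waves (mean + 2 SD criterion)
#'
#' Keeps events whose peak amplitude strictly exceeds the mean plus two
#' (population) standard deviations of the amplitude across all detected
#' waves.
#'
#' @param events a `vs_waves` data frame with >= 2 events
#' @return the selected subset, same columns
#' @export
select_high_amplitude <- function(events) {
  if (nrow(events) < 2) stop("need at least 2 events for the amplitude criterion")
  a <- events$amplitude
  sd_pop <- sqrt(mean((a - mean(a))^2))
  events[a > mean(a) + 2 * sd_pop, , drop = FALSE]
}

#' Normalized amplitude and duration histograms of detected waves
#'
#' @param events non-empty `vs_waves` data frame
#' @param amp_edges,dur_edges histogram break points (µV, s); values outside
#'   are pooled into the end bins
#' @return list with `amplitude` and `duration` data frames
#'   (`lo`, `hi`, `prop`); proportions sum to 1
#' @export
wave_distributions <- function(events,
                               amp_edges = seq(0, 500, by = 25),
                               dur_edges = seq(0, 1, by = 0.05)) {
  if (nrow(events) == 0) stop("no events to histogram")
  hist1 <- function(v, edges) {
    v <- pmin(pmax(v, edges[1]), edges[length(edges)])
    ct <- graphics::hist(v, breaks = edges, plot = FALSE)$counts
    data.frame(lo = edges[-length(edges)], hi = edges[-1], prop = ct / sum(ct))
  }
  list(amplitude = hist1(events$amplitude, amp_edges),
       duration = hist1(events$duration, dur_edges))
}

#' Peri-event multi-unit activity profile (OFF-period profile)
#'
#' Spike counts in lag bins relative to each wave's positive peak, averaged
#' over events and converted to a rate.  The trough is the minimum-rate bin;
#' the trough width is the span of contiguous bins around it with rate below
#' half the baseline (mean rate at lags beyond +/-300 ms).
#'
#' @param events a `vs_waves` data frame (typically [select_high_amplitude()]
#'   output) or a numeric vector of peak times (s)
#' @param spike_times sorted spike times (s)
#' @param window_ms half-width of the lag window (ms)
#' @param bin_ms lag bin width (ms)
#' @return object of class `vs_off_profile`: `lag_ms` (bin centres),
#'   `rate_hz`, `n_events`, `trough_lag_ms`, `trough_rate_hz`,
#'   `trough_width_ms`, `baseline_hz`
#' @export
peri_event_mua <- function(events, spike_times, window_ms = 500, bin_ms = 10) {
  peaks <- if (is.data.frame(events)) events$peak_t else as.numeric(events)
  if (length(peaks) == 0) stop("no events for the peri-event profile")
  if (is.unsorted(spike_times)) stop("spike times must be sorted")
  w <- window_ms / 1000
  b <- bin_ms / 1000
  edges <- seq(-w, w, by = b)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  for (p in peaks) {
    lo <- findInterval(p - w, spike_times) + 1L
    hi <- findInterval(p + w, spike_times)
    if (hi >= lo) {
      lag <- spike_times[lo:hi] - p
      bi <- pmin(pmax(floor((lag + w) / b) + 1L, 1L), nb)
      tb <- tabulate(bi, nbins = nb)
      counts <- counts + tb
    }
  }
  rate <- counts / (length(peaks) * b)
  lag_mid <- (edges[-1] + edges[-length(edges)]) / 2 * 1000
  cand <- which(rate <= min(rate) + 1e-12)
  ti <- cand[which.min(abs(lag_mid[cand]))]  # tie-break toward zero lag
  outer_sel <- abs(lag_mid) > 300
  baseline <- if (any(outer_sel)) mean(rate[outer_sel]) else mean(rate)
  below <- rate < baseline / 2
  width <- 0
  if (below[ti]) {
    lo <- ti; while (lo > 1 && below[lo - 1]) lo <- lo - 1
    hi <- ti; while (hi < nb && below[hi + 1]) hi <- hi + 1
    width <- (hi - lo + 1) * bin_ms
  }
  structure(list(lag_ms = lag_mid, rate_hz = rate, n_events = length(peaks),
                 trough_lag_ms = lag_mid[ti], trough_rate_hz = rate[ti],
                 trough_width_ms = width, baseline_hz = baseline),
            class = "vs_off_profile")
}

#' @export
print.vs_off_profile <- function(x, ...) {
  cat(sprintf(paste0("<vs_off_profile> %d events: trough %.1f Hz at %+.0f ms, ",
                     "width %.0f ms (baseline %.1f Hz)\n"),
              x$n_events, x$trough_rate_hz, x$trough_lag_ms,
              x$trough_width_ms, x$baseline_hz))
  invisible(x)
}

#' Attribute detected waves to hypnogram states
#'
#' Each wave takes the state of the epoch containing its peak.
#'
#' @param events a `vs_waves` data frame
#' @param hypnogram a [vs_hypnogram]
#' @return `events` with an added `state` column
#' @export
attribute_wave_states <- function(events, hypnogram) {
  ep <- floor(events$peak_t / hypnogram$epoch_s) + 1
  ep[ep > length(hypnogram$labels)] <- NA
  events$state <- hypnogram$labels[ep]
  events
}
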