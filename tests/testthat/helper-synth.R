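# Shared fixtures and independent oracles used across the suite.

# a short study configuration that keeps unit tests fast; the drug window
# spans the second half of the recording
quick_config <- function(seed = 1, duration_h = 0.25, ...) {
  synth_config(seed = seed, duration_h = duration_h,
               injection_t = duration_h * 1800,
               drug_window = c(duration_h * 1800, duration_h * 3600), ...)
}

# brute-force slow-wave oracle: explicit scan over sign-change segments,
# independent of the rle-based detector
oracle_detect_waves <- function(x, fs) {
  n <- length(x)
  segs <- list()
  start <- 1L
  for (k in 2:n) {
    if ((x[k] > 0) != (x[k - 1] > 0)) {
      segs[[length(segs) + 1L]] <- c(start, k - 1L)
      start <- k
    }
  }
  segs[[length(segs) + 1L]] <- c(start, n)
  ev <- list()
  if (length(segs) >= 3) {
    for (j in 2:(length(segs) - 1)) {
      s <- segs[[j]]
      prev <- segs[[j - 1]]
      nxt <- segs[[j + 1]]
      if (x[s[1]] > 0 && min(x[prev[1]:prev[2]]) < 0 && min(x[nxt[1]:nxt[2]]) < 0) {
        seg <- s[1]:s[2]
        pk <- seg[which.max(x[seg])]
        ev[[length(ev) + 1L]] <- c(onset = (s[1] - 1) / fs, peak = (pk - 1) / fs,
                                   offset = s[2] / fs, amp = x[pk])
      }
    }
  }
  if (length(ev) == 0)
    return(data.frame(onset = numeric(0), peak = numeric(0),
                      offset = numeric(0), amp = numeric(0)))
  as.data.frame(do.call(rbind, ev))
}

# random hypnogram with valid labels (for conservation-style properties)
random_hypnogram <- function(n, epoch_s = 4) {
  vs_hypnogram(sample(c("WAKE", "NREM", "REM", "MICRO_AROUSAL"), n,
                      replace = TRUE, prob = c(0.4, 0.4, 0.1, 0.1)),
               epoch_s = epoch_s)
}

# fraction of injected waves whose peak is recovered by the detector
match_fraction <- function(truth_peaks, detected_peaks, tol = 0.15) {
  if (length(truth_peaks) == 0) return(NA_real_)
  mean(vapply(truth_peaks, function(p) any(abs(detected_peaks - p) < tol), TRUE))
}

# synthetic coupled signal: slow phase rhythm modulating a fast carrier
coupled_signal <- function(fs, dur_s, depth, f_phase = 5, f_amp = 60,
                           noise_sd = 0.5) {
  t <- (0:(fs * dur_s - 1)) / fs
  sin(2 * pi * f_phase * t) +
    (1 + depth * cos(2 * pi * f_phase * t)) * 0.3 * sin(2 * pi * f_amp * t) +
    stats::rnorm(length(t), 0, noise_sd)
}
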