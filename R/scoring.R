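# Rule-based vigilance-state scoring on 4-s epochs.
#
# The scoring criteria mirror standard rodent practice: wake = high EMG tone;
# NREM = low EMG with high-amplitude frontal slow activity (0.5-4 Hz);
# REM = low EMG with occipital theta (7-12.5 Hz) dominance.  Brief waking
# intrusions between sleep epochs are relabelled micro-arousals unless five
# or more consecutive epochs qualify.  Thresholds are auto-calibrated per
# recording from epoch-feature percentiles so the qualitative criteria become
# reproducible numbers.

#' Per-epoch scoring features
#'
#' @param recording a preprocessed 256 Hz [vs_recording] containing at least
#'   `frontal`, `occipital` and `emg` channels
#' @param epoch_s epoch length (s)
#' @return data frame, one row per epoch: `emg_rms` (µV), `frontal_swa_amp`
#'   (µV, amplitude of the 0.5–4 Hz envelope), `occ_theta_power` and
#'   `occ_delta_power` (µV², 7–12.5 and 0.5–4 Hz), `theta_dominance`
#'   (theta/delta ratio) and `peak_amp` per derivation
#' @export
compute_epoch_features <- function(recording, epoch_s = 4) {
  stopifnot(inherits(recording, "vs_recording"))
  need <- c("frontal", "occipital", "emg")
  miss <- setdiff(need, names(recording$channels))
  if (length(miss)) stop("recording lacks channels: ", paste(miss, collapse = ", "))
  fs <- recording$fs

  emg_m <- epoch_matrix(recording$channels$emg, fs, epoch_s)
  emg_rms <- sqrt(colMeans(emg_m^2))

  swa <- filter_swa(recording$channels$frontal, fs)
  swa_m <- epoch_matrix(swa, fs, epoch_s)
  frontal_swa_amp <- sqrt(2) * sqrt(colMeans(swa_m^2))

  occ <- epoch_spectra_matrix(recording$channels$occipital, fs, epoch_s)
  th <- band_power_of(occ$power, occ$freq, c(7, 12.5))
  de <- band_power_of(occ$power, occ$freq, c(0.5, 4))

  n_ep <- length(emg_rms)
  peak <- sapply(recording$channels, function(x)
    apply(abs(epoch_matrix(x, fs, epoch_s)), 2, max))
  data.frame(epoch = seq_len(n_ep), emg_rms = emg_rms,
             frontal_swa_amp = frontal_swa_amp,
             occ_theta_power = th[seq_len(n_ep)],
             occ_delta_power = de[seq_len(n_ep)],
             theta_dominance = (th / pmax(de, .Machine$double.eps))[seq_len(n_ep)],
             peak = I(peak))
}

#' Auto-calibrated scoring thresholds
#'
#' The waking/sleeping EMG boundary is found by a two-class variance split
#' (Otsu's criterion) on log epoch EMG RMS, which separates the high-tone
#' waking cluster from the low-tone sleep cluster irrespective of how much
#' of the recording is spent in each state; `emg_hi`/`emg_lo` sit 2% above
#' and below that boundary.  `swa_amp_min` is the median frontal SWA
#' envelope amplitude, `theta_dominance_min` a fixed ratio of 1.5,
#' `artefact_z` a robust-z cutoff.
#'
#' @param features from [compute_epoch_features()]
#' @param theta_dominance_min minimum occipital theta/delta ratio for REM
#' @param artefact_z robust-z cutoff on epoch peak amplitude
#' @return a list of class `vs_thresholds`
#' @export
auto_thresholds <- function(features, theta_dominance_min = 1.5, artefact_z = 8) {
  split <- exp(otsu_threshold(log(pmax(features$emg_rms,
                                       .Machine$double.eps))))
  structure(list(
    emg_hi = split * 1.02,
    emg_lo = split * 0.98,
    swa_amp_min = stats::median(features$frontal_swa_amp),
    theta_dominance_min = theta_dominance_min,
    artefact_z = artefact_z), class = "vs_thresholds")
}

# threshold maximising between-class variance over a 128-bin histogram
otsu_threshold <- function(x, n_bins = 128) {
  br <- seq(min(x), max(x), length.out = n_bins + 1)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Classify epochs from features and thresholds
#'
#' Precedence: WAKE when EMG RMS >= `emg_hi`; otherwise REM when EMG RMS
#' <= `emg_lo` and theta dominance >= `theta_dominance_min` (the REM check
#' runs before the NREM check); remaining low/intermediate-EMG epochs are
#' NREM.
#'
#' @param features from [compute_epoch_features()]
#' @param thresholds from [auto_thresholds()] (or hand-built)
#' @return character vector of labels
#' @export
classify_epochs <- function(features, thresholds) {
  lab <- rep("NREM", nrow(features))
  rem <- features$emg_rms <= thresholds$emg_lo &
    features$theta_dominance >= thresholds$theta_dominance_min
  lab[rem] <- "REM"
  lab[features$emg_rms >= thresholds$emg_hi] <- "WAKE"
  lab
}

#' Micro-arousal refinement
#'
#' Runs of 1–4 consecutive waking epochs flanked on the left by a sleep epoch
#' (NREM or REM) and on the right by NREM are relabelled `MICRO_AROUSAL`;
#' runs of 5 or more stay `WAKE`.  The rule is re-applied until a fixpoint so
#' that earlier relabelling cannot leave an inconsistent run (micro-arousal
#' epochs count as waking when run lengths are measured).
#'
#' @param labels character vector from [classify_epochs()]
#' @return relabelled character vector (same length; only WAKE <->
#'   MICRO_AROUSAL changes)
#' @export
refine_microarousals <- function(labels) {
  n <- length(labels)
  repeat {
    out <- labels
    wk <- labels %in% c("WAKE", "MICRO_AROUSAL")
    r <- rle(wk)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in seq_along(r$lengths)) {
      if (!r$values[i]) next
      s <- starts[i]; e <- ends[i]
      sandwiched <- s > 1 && e < n &&
        labels[s - 1] %in% c("NREM", "REM") && labels[e + 1] == "NREM"
      out[s:e] <- if (r$lengths[i] <= 4 && sandwiched) "MICRO_AROUSAL" else "WAKE"
    }
    if (identical(out, labels)) return(out)
    labels <- out
  }
}

#' Flag artefactual epochs per derivation
#'
#' An epoch is flagged for a derivation when its peak absolute amplitude has
#' a robust z-score (median/MAD) above `artefact_z`, or when it contains a
#' run of 5 or more identical extreme samples (amplifier saturation).  Flags
#' never alter state labels.
#'
#' @param recording a [vs_recording]
#' @param thresholds a `vs_thresholds` (only `artefact_z` is used)
#' @param epoch_s epoch length (s)
#' @return logical matrix, epochs x derivations
#' @export
mark_artefacts <- function(recording, thresholds, epoch_s = 4) {
  fs <- recording$fs
  flags <- sapply(names(recording$channels), function(nm) {
    m <- epoch_matrix(recording$channels[[nm]], fs, epoch_s)
    peak <- apply(abs(m), 2, max)
    med <- stats::median(peak)
    madv <- stats::mad(peak)
    z <- if (madv > 0) (peak - med) / madv else rep(0, length(peak))
    # saturation scan only where the epoch peak approaches the channel max
    ch_max <- max(peak)
    sat <- logical(length(peak))
    for (e in which(peak >= 0.999 * ch_max)) {
      r <- rle(m[, e])
      sat[e] <- any(r$lengths >= 5 &
                      abs(r$values) >= 0.999 * max(ch_max, .Machine$double.eps))
    }
    z > thresholds$artefact_z | sat
  })
  flags <- as.matrix(flags)
  colnames(flags) <- names(recording$channels)
  flags
}

#' Score a recording end to end
#'
#' Features -> auto thresholds -> rule classification -> micro-arousal
#' refinement -> artefact flagging.
#'
#' @param recording a preprocessed 256 Hz [vs_recording]
#' @param thresholds optional `vs_thresholds`; auto-calibrated if `NULL`
#' @param epoch_s epoch length (s)
#' @return a [vs_hypnogram] with artefact flags
#' @export
score_recording <- function(recording, thresholds = NULL, epoch_s = 4) {
  feat <- compute_epoch_features(recording, epoch_s)
  thr <- thresholds %||% auto_thresholds(feat)
  lab <- refine_microarousals(classify_epochs(feat, thr))
  art <- mark_artefacts(recording, thr, epoch_s)
  vs_hypnogram(lab, epoch_s = epoch_s, artefact = art[seq_along(lab), , drop = FALSE])
}
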