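# Per-epoch power spectra, band-power time courses, aperiodic slope, and
# phase-amplitude modulation index.

# Hanning-window periodogram of consecutive epochs.  Power is scaled so the
# one-sided band sum equals the signal variance (window power correction):
# P_k = 2|X_k|^2 / (N * sum(w^2)), with no doubling at DC/Nyquist.
epoch_spectra_matrix <- function(x, fs, epoch_s = 4, f_max = 120,
                                 chunk = 4096L) {
  ns <- as.integer(round(fs * epoch_s))
  if (abs(fs * epoch_s - ns) > 1e-9) stop("non-integer samples per epoch")
  m <- epoch_matrix(x, fs, epoch_s)
  ne <- ncol(m)
  w <- 0.5 * (1 - cos(2 * pi * (0:(ns - 1)) / ns))   # periodic Hann
  wss <- sum(w^2)
  n_keep <- as.integer(round(f_max * ns / fs)) + 1L
  freq <- (0:(n_keep - 1)) * fs / ns
  power <- matrix(0, nrow = n_keep, ncol = ne)
  for (i0 in seq(1L, ne, by = chunk)) {
    ii <- i0:min(ne, i0 + chunk - 1L)
    X <- stats::mvfft(m[, ii, drop = FALSE] * w)
    p <- 2 * Mod(X[seq_len(n_keep), , drop = FALSE])^2 / (ns * wss)
    p[1, ] <- p[1, ] / 2
    if (n_keep - 1L == ns %/% 2L) p[n_keep, ] <- p[n_keep, ] / 2
    power[, ii] <- p
  }
  list(power = power, freq = freq)
}

#' Per-epoch power spectra (Hanning window, 0.25 Hz resolution, 0-120 Hz)
#'
#' Epochs of `epoch_s` seconds at 256 Hz give 1024-point FFTs, hence a
#' 0.25 Hz bin spacing and 481 exported bins from 0 to 120 Hz.  Power is
#' window-corrected so that the band-summed power of a sinusoid equals its
#' variance.
#'
#' @param recording a preprocessed 256 Hz [vs_recording]
#' @param derivation channel name to analyse
#' @param epoch_s epoch length (s)
#' @return object of class `vs_spectra`: `power` (epochs x bins, µV²),
#'   `freq` (Hz), `derivation`, `epoch_s`
#' @export
epoch_spectra <- function(recording, derivation = "frontal", epoch_s = 4) {
  stopifnot(inherits(recording, "vs_recording"))
  if (recording$fs != 256) stop("epoch spectra require a 256 Hz recording")
  x <- recording$channels[[derivation]]
  if (is.null(x)) stop("no such derivation: ", derivation)
  sp <- epoch_spectra_matrix(x, recording$fs, epoch_s)
  structure(list(power = t(sp$power), freq = sp$freq, derivation = derivation,
                 epoch_s = epoch_s), class = "vs_spectra")
}

#' @export
print.vs_spectra <- function(x, ...) {
  cat(sprintf("<vs_spectra> %s: %d epochs x %d bins (%.2f-%.2f Hz, %.2f Hz spacing)\n",
              x$derivation, nrow(x$power), ncol(x$power), min(x$freq),
              max(x$freq), diff(x$freq[1:2])))
  invisible(x)
}

# band power = sum of bin powers with both edges inclusive
band_power_of <- function(power, freq, band) {
  sel <- freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9
  if (!any(sel)) stop("band contains no frequency bins")
  colSums(power[sel, , drop = FALSE])
}

#' Per-epoch band power from a `vs_spectra`
#' @param spectra a [epoch_spectra()] result
#' @param band numeric(2), band edges in Hz (inclusive)
#' @return numeric vector, one value per epoch (µV²)
#' @export
band_power <- function(spectra, band) {
  stopifnot(inherits(spectra, "vs_spectra"))
  if (band[1] < 0 || band[2] > max(spectra$freq) + 1e-9)
    stop("band outside the exported frequency range")
  as.numeric(band_power_of(t(spectra$power), spectra$freq, band))
}

#' Band-power time course over states
#'
#' Mean band power over artefact-free epochs of the given state per time bin,
#' optionally expressed as percent of a reference value.
#'
#' @param spectra a [epoch_spectra()] result
#' @param hypnogram a [vs_hypnogram] aligned with the spectra
#' @param band numeric(2) band edges (Hz)
#' @param state state to include (`NULL` for all states)
#' @param bin_minutes time-bin width (minutes)
#' @param reference reference power for normalisation to percent (`NULL`
#'   leaves absolute µV²)
#' @return data frame: `t_min` (bin centre), `value`, `n_epochs`; bins with
#'   no qualifying epoch are `NA`
#' @export
band_power_timecourse <- function(spectra, hypnogram, band, state = "NREM",
                                  bin_minutes = 10, reference = NULL) {
  stopifnot(inherits(spectra, "vs_spectra"), inherits(hypnogram, "vs_hypnogram"))
  bp <- band_power(spectra, band)
  n <- min(length(bp), length(hypnogram$labels))
  bp <- bp[seq_len(n)]
  lab <- hypnogram$labels[seq_len(n)]
  ok <- if (is.null(state)) rep(TRUE, n) else lab == state
  if (!is.null(hypnogram$artefact)) {
    art <- apply(hypnogram$artefact[seq_len(n), , drop = FALSE], 1, any)
    ok <- ok & !art
  }
  ep_min <- (seq_len(n) - 1) * hypnogram$epoch_s / 60
  bin <- floor(ep_min / bin_minutes)
  bins <- 0:max(bin)
  val <- vapply(bins, function(b) {
    sel <- ok & bin == b
    if (!any(sel)) NA_real_ else mean(bp[sel])
  }, 0)
  nn <- vapply(bins, function(b) sum(ok & bin == b), 0L)
  if (!is.null(reference)) val <- 100 * val / reference
  data.frame(t_min = (bins + 0.5) * bin_minutes, value = val, n_epochs = nn)
}

#' Aperiodic spectral slope
#'
#' Ordinary least squares of log10(power) against frequency over the fit
#' range — the linear–log convention used for aperiodic slopes in the
#' 20–120 Hz range.  With `log_freq = TRUE` the regressor is log10(frequency)
#' instead (log–log space), in which case `-slope` estimates the exponent chi
#' of a 1/f^chi background.
#'
#' @param power numeric vector of spectral power (µV²), one value per bin
#' @param freq frequency axis (Hz), same length
#' @param range numeric(2) fit range in Hz, default 20-120
#' @param log_freq fit against log10(frequency) instead of frequency
#' @return list of class `vs_slopefit`: `slope`, `intercept`, `range`,
#'   `residual_rms`, `log_freq`
#' @export
fit_spectral_slope <- function(power, freq, range = c(20, 120),
                               log_freq = FALSE) {
  sel <- freq >= range[1] - 1e-9 & freq <= range[2] + 1e-9
  if (sum(sel) < 3) stop("fewer than 3 bins in the fit range")
  p <- power[sel]
  f <- freq[sel]
  if (any(p <= 0)) stop("non-positive power in the fit range")
  y <- log10(p)
  x <- if (log_freq) log10(f) else f
  cf <- stats::lm.fit(cbind(1, x), y)$coefficients
  res <- y - (cf[1] + cf[2] * x)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 range = range, residual_rms = sqrt(mean(res^2)),
                 log_freq = log_freq),
            class = "vs_slopefit")
}

#' @export
print.vs_slopefit <- function(x, ...) {
  cat(sprintf("<vs_slopefit> slope=%.4g intercept=%.4g over %g-%g Hz (%s)\n",
              x$slope, x$intercept, x$range[1], x$range[2],
              if (x$log_freq) "log-log" else "linear-log"))
  invisible(x)
}

#' Tort modulation index from phase and amplitude series
#'
#' Mean amplitude per phase bin is normalised to a distribution P over
#' `n_bins` bins; MI = (log n - H(P)) / log n, the Kullback-Leibler distance
#' from uniformity scaled to [0, 1].
#'
#' @param phase instantaneous phase (radians, wrapped to any 2*pi interval)
#' @param amplitude instantaneous amplitude envelope, same length
#' @param n_bins number of phase bins (18 by convention)
#' @return MI in [0, 1]
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18) {
  stopifnot(length(phase) == length(amplitude), n_bins >= 2)
  b <- floor((phase %% (2 * pi)) / (2 * pi) * n_bins) + 1
  b[b > n_bins] <- n_bins
  m <- vapply(seq_len(n_bins), function(k) {
    s <- amplitude[b == k]
    if (length(s)) mean(s) else 0
  }, 0)
  if (sum(m) <= 0) return(0)
  p <- m / sum(m)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

#' Phase-amplitude modulation index of a signal
#'
#' Band-passes the slow and fast bands (third-order Butterworth, zero-phase),
#' extracts the slow band's instantaneous phase and the fast band's amplitude
#' envelope via the analytic signal, and computes the Tort MI.
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param phase_band numeric(2), slow band (Hz)
#' @param amp_band numeric(2), fast band (Hz)
#' @param n_bins number of phase bins
#' @return MI in [0, 1]
#' @export
modulation_index <- function(x, fs, phase_band, amp_band, n_bins = 18) {
  if (max(phase_band, amp_band) >= fs / 2) stop("band overlaps Nyquist frequency")
  if (length(x) < 10 * fs / phase_band[1])
    stop("signal shorter than 10 cycles of the phase frequency")
  ph <- Arg(analytic_signal(butter_bandpass(x, fs, phase_band[1], phase_band[2])))
  am <- Mod(analytic_signal(butter_bandpass(x, fs, amp_band[1], amp_band[2])))
  tort_mi(ph, am, n_bins)
}

#' Comodulogram over a phase x amplitude frequency grid
#'
#' MI evaluated for every combination of phase-band centre (default
#' 1.5-10.5 Hz) and amplitude-band centre (default spanning up to 100.5 Hz).
#'
#' @param x signal
#' @param fs sampling rate (Hz)
#' @param phase_centers,amp_centers grid centres (Hz)
#' @param phase_bw,amp_bw full bandwidths (Hz) around each centre
#' @param n_bins phase bins
#' @return object of class `vs_comodulogram`: matrix `mi`
#'   (phase x amplitude), plus the grids
#' @export
comodulogram <- function(x, fs,
                         phase_centers = seq(1.5, 10.5, by = 1),
                         amp_centers = seq(10.25, 100.5, by = 10.025),
                         phase_bw = 2, amp_bw = 20, n_bins = 18) {
  if (length(x) < 60 * fs) stop("comodulogram requires at least 60 s of signal")
  amp_env <- lapply(amp_centers, function(fc) {
    lo <- max(fc - amp_bw / 2, 0.1)
    hi <- min(fc + amp_bw / 2, fs / 2 - 1)
    Mod(analytic_signal(butter_bandpass(x, fs, lo, hi)))
  })
  mi <- matrix(0, nrow = length(phase_centers), ncol = length(amp_centers),
               dimnames = list(phase_centers, amp_centers))
  for (i in seq_along(phase_centers)) {
    fc <- phase_centers[i]
    lo <- max(fc - phase_bw / 2, 0.1)
    ph <- Arg(analytic_signal(butter_bandpass(x, fs, lo, fc + phase_bw / 2)))
    for (j in seq_along(amp_centers))
      mi[i, j] <- tort_mi(ph, amp_env[[j]], n_bins)
  }
  structure(list(mi = mi, phase_centers = phase_centers,
                 amp_centers = amp_centers, n_bins = n_bins),
            class = "vs_comodulogram")
}

#' @export
print.vs_comodulogram <- function(x, ...) {
  pk <- which(x$mi == max(x$mi), arr.ind = TRUE)[1, ]
  cat(sprintf("<vs_comodulogram> %d x %d grid, max MI %.4f at (%.2f, %.2f) Hz\n",
              nrow(x$mi), ncol(x$mi), max(x$mi),
              x$phase_centers[pk[1]], x$amp_centers[pk[2]]))
  invisible(x)
}
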