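# ---- Chebyshev type II design helpers -------------------------------------
#
# r-signal ships cheby2() but no order selector, so the minimum order is
# computed here from the analog-prototype inequality with bilinear
# prewarping (Omega = tan(pi * f / fs)).  Filtering is performed as a cascade
# of zero-phase biquads derived from the zero-pole-gain form: direct
# transfer-function filtering is numerically unreliable for narrow bands at
# low normalised frequency.

#' Minimum Chebyshev type II order for a low/high-pass specification
#'
#' @param fpass,fstop passband and stopband edge (Hz)
#' @param fs sampling rate (Hz)
#' @param rp maximum passband attenuation (dB) at the passband edge
#' @param rs minimum stopband attenuation (dB)
#' @return integer filter order
#' @keywords internal
cheby2_order <- function(fpass, fstop, fs, rp = 1, rs = 40) {
  wp <- tan(pi * fpass / fs)
  ws <- tan(pi * fstop / fs)
  sel <- max(ws / wp, wp / ws)  # selectivity > 1 for both LP and HP specs
  d <- sqrt((10^(rs / 10) - 1) / (10^(rp / 10) - 1))
  max(1L, as.integer(ceiling(acosh(d) / acosh(sel))))
}

# Pair zeros and poles of a Zpg object into second-order sections.
# Conjugate pairs are grouped explicitly; pole pairs are ordered with poles
# farthest from the unit circle first and each takes the zero pair nearest in
# angle — the usual sos pairing rule.
zpg_to_sos <- function(zpg) {
  group_pairs <- function(v, tol = 1e-3) {
    # designed roots are only near-conjugate numerically: pair each root with
    # the remaining root closest to its conjugate, provided it genuinely is
    # one; (near-)real leftovers become first-order factors
    pairs <- list()
    while (length(v) >= 1) {
      if (length(v) >= 2) {
        d <- abs(v[-1] - Conj(v[1]))
        j <- 1L + which.min(d)
      } else {
        d <- Inf
        j <- NA_integer_
      }
      if (min(d) < tol * (1 + abs(v[1]))) {
        pairs[[length(pairs) + 1L]] <- v[c(1L, j)]
        v <- v[-c(1L, j)]
      } else if (abs(Im(v[1])) < tol * (1 + abs(v[1]))) {
        # real root: pair with another real root if one remains
        re <- which(abs(Im(v[-1])) < tol * (1 + abs(v[-1]))) + 1L
        if (length(re) > 0) {
          pairs[[length(pairs) + 1L]] <- v[c(1L, re[1])]
          v <- v[-c(1L, re[1])]
        } else {
          pairs[[length(pairs) + 1L]] <- c(v[1], NA)
          v <- v[-1L]
        }
      } else {
        stop("internal error: unpaired complex root in filter design")
      }
    }
    pairs
  }
  zp <- group_pairs(zpg$zero)
  pp <- group_pairs(zpg$pole)
  while (length(zp) < length(pp)) zp[[length(zp) + 1L]] <- c(0 + 0i, NA)
  stopifnot(length(zp) == length(pp))

  # poles farthest from the unit circle first; matched zero pair by angle
  pp <- pp[order(abs(sapply(pp, function(p) abs(p[1]))))]
  pang <- sapply(pp, function(p) abs(Arg(p[1])))
  zang <- sapply(zp, function(z) abs(Arg(z[1])))
  sos <- vector("list", length(pp))
  used <- logical(length(zp))
  for (i in seq_along(pp)) {
    j <- which(!used)[which.min(abs(zang[!used] - pang[i]))]
    used[j] <- TRUE
    sos[[i]] <- list(b = pair_poly(zp[[j]]), a = pair_poly(pp[[i]]))
  }
  list(sos = sos, gain = Re(zpg$gain))
}

# monic polynomial coefficients for a root pair (second element may be NA
# for a first-order factor)
pair_poly <- function(pr) {
  if (is.na(pr[2])) Re(c(1, -pr[1], 0)) else
    Re(c(1, -(pr[1] + pr[2]), pr[1] * pr[2]))
}

#' Zero-phase filtering through cascaded second-order sections
#'
#' Applies `signal::filtfilt` section by section so the overall response is
#' the squared magnitude of the designed filter with no phase distortion.
#' @keywords internal
sos_filtfilt <- function(sos, x) {
  y <- x * sos$gain^2  # filtfilt applies the filter twice
  for (s in sos$sos) {
    y <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), y)
  }
  y
}

#' Design a zero-phase Chebyshev type II band-pass as HP + LP cascade
#'
#' @param fs sampling rate (Hz)
#' @param fpass numeric(2) passband edges (Hz); `NA` disables that edge
#' @param fstop numeric(2) stopband edges (Hz)
#' @param rs stopband attenuation (dB), single pass
#' @param rp passband deviation (dB) used for order selection
#' @return an object of class `vs_filter` usable with [apply_filter()]
#' @export
design_bandpass <- function(fs, fpass, fstop, rs = 40, rp = 1) {
  stopifnot(length(fpass) == 2, length(fstop) == 2, fs > 0)
  stages <- list()
  nyq <- fs / 2
  if (!is.na(fpass[1])) {
    if (fstop[1] <= 0 || fstop[1] >= fpass[1])
      stop("high-pass stopband edge must lie in (0, fpass_lo)")
    n <- cheby2_order(fpass[1], fstop[1], fs, rp, rs)
    f <- signal::cheby2(n, rs, fstop[1] / nyq, type = "high")
    stages[[length(stages) + 1L]] <- zpg_to_sos(signal::as.Zpg(f))
  }
  if (!is.na(fpass[2])) {
    if (fstop[2] <= fpass[2] || fstop[2] >= nyq)
      stop("low-pass stopband edge must lie in (fpass_hi, fs/2)")
    n <- cheby2_order(fpass[2], fstop[2], fs, rp, rs)
    f <- signal::cheby2(n, rs, fstop[2] / nyq, type = "low")
    stages[[length(stages) + 1L]] <- zpg_to_sos(signal::as.Zpg(f))
  }
  structure(list(stages = stages, fs = fs, fpass = fpass, fstop = fstop),
            class = "vs_filter")
}

#' Apply a designed zero-phase filter to a signal
#' @param filt a `vs_filter` from [design_bandpass()]
#' @param x numeric signal sampled at `filt$fs`
#' @export
apply_filter <- function(filt, x) {
  stopifnot(inherits(filt, "vs_filter"))
  for (st in filt$stages) x <- sos_filtfilt(st, x)
  x
}

#' Zero-phase Butterworth band-pass (order 3), used for narrow-band envelopes
#' @keywords internal
butter_bandpass <- function(x, fs, lo, hi, order = 3) {
  nyq <- fs / 2
  if (hi >= nyq) stop("band overlaps Nyquist frequency")
  f <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  sos <- zpg_to_sos(signal::as.Zpg(f))
  sos_filtfilt(sos, x)
}

#' Analytic signal via frequency-domain Hilbert transform
#'
#' @param x real signal
#' @return complex vector; `Arg` gives instantaneous phase, `Mod` the envelope
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
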