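# Sleep-architecture and condition-contrast endpoints.

#' Time in state per interval
#'
#' Epoch-count accounting: minutes spent in each state (micro-arousals as
#' their own category) per consecutive interval.
#'
#' @param hypnogram a [vs_hypnogram]
#' @param interval_s interval length (s), a multiple of the epoch length
#' @return data frame: `interval` (0-based), `t_start_s`, and minutes per
#'   state (`WAKE`, `NREM`, `REM`, `MICRO_AROUSAL`); per-interval minutes sum
#'   to the interval length covered
#' @export
state_time_per_interval <- function(hypnogram, interval_s = 3600) {
  stopifnot(inherits(hypnogram, "vs_hypnogram"))
  n <- length(hypnogram$labels)
  if (n == 0) stop("empty hypnogram")
  ep <- hypnogram$epoch_s
  if (abs(interval_s / ep - round(interval_s / ep)) > 1e-9)
    stop("interval must be a multiple of the epoch length")
  iv <- floor(((seq_len(n) - 1) * ep) / interval_s)
  tab <- table(interval = iv,
               state = factor(hypnogram$labels, levels = VS_STATES))
  out <- as.data.frame.matrix(tab) * ep / 60
  data.frame(interval = as.integer(rownames(out)),
             t_start_s = as.integer(rownames(out)) * interval_s, out,
             row.names = NULL)
}

#' REM sleep latency from injection
#'
#' Time from the injection to the start of the first REM epoch beginning at
#' or after it; `NA` when no such epoch exists.
#'
#' @param hypnogram a [vs_hypnogram]
#' @param injection_t injection time (s from recording start)
#' @return latency in seconds, or `NA`
#' @export
rem_latency <- function(hypnogram, injection_t) {
  stopifnot(inherits(hypnogram, "vs_hypnogram"))
  ep <- hypnogram$epoch_s
  n <- length(hypnogram$labels)
  if (injection_t > n * ep) stop("injection beyond recording end")
  starts <- (seq_len(n) - 1) * ep
  hit <- which(hypnogram$labels == "REM" & starts >= injection_t)
  if (length(hit) == 0) return(NA_real_)
  starts[hit[1]] - injection_t
}

#' Cumulative time-in-state curve
#'
#' Running sum of minutes in `state`, sampled at the end of each interval up
#' to the horizon.
#'
#' @param hypnogram a [vs_hypnogram]
#' @param state state label
#' @param horizon_h horizon (hours), capped at the recording length
#' @param interval_s sampling interval (s)
#' @return data frame: `t_h` (interval end, hours), `minutes`
#'   (non-decreasing)
#' @export
cumulative_state <- function(hypnogram, state = "REM", horizon_h = 24,
                             interval_s = 3600) {
  stopifnot(inherits(hypnogram, "vs_hypnogram"))
  ep <- hypnogram$epoch_s
  n <- length(hypnogram$labels)
  horizon_s <- min(horizon_h * 3600, n * ep)
  t_end <- seq(interval_s, horizon_s, by = interval_s)
  if (length(t_end) == 0) t_end <- horizon_s
  ep_min_in_state <- cumsum(hypnogram$labels == state) * ep / 60
  idx <- pmin(pmax(floor(t_end / ep), 1), n)
  data.frame(t_h = t_end / 3600, minutes = ep_min_in_state[idx])
}

#' Locate the first NREM episode after injection and track SWA from its onset
#'
#' An episode is a run of at least `episode_min_epochs` NREM epochs tolerating
#' at most one interrupting epoch.  The output is the slow-wave-activity
#' (band power) of every subsequent NREM epoch, as percent of `reference`.
#'
#' @param spectra a [epoch_spectra()] result (frontal derivation)
#' @param hypnogram a [vs_hypnogram] aligned with the spectra
#' @param injection_t injection time (s)
#' @param episode_min_epochs minimum NREM epochs for a qualifying episode
#' @param reference reference band power (µV²) defining 100%; defaults to the
#'   mean NREM SWA over the whole recording
#' @param band SWA band (Hz)
#' @return list of class `vs_swa_dynamics`: `onset_s`, `t_s` (epoch starts
#'   from onset), `swa_pct`; `NULL` (invisibly, with a diagnostic message)
#'   when no qualifying episode exists
#' @export
swa_dynamics_from_first_nrem <- function(spectra, hypnogram, injection_t,
                                         episode_min_epochs = 15,
                                         reference = NULL, band = c(0.5, 4)) {
  stopifnot(inherits(hypnogram, "vs_hypnogram"))
  ep <- hypnogram$epoch_s
  lab <- hypnogram$labels
  n <- length(lab)
  first_ep <- ceiling(injection_t / ep) + 1
  onset_ep <- NA_integer_
  if (first_ep > n) {
    message("injection at or beyond recording end")
    return(invisible(NULL))
  }
  for (i in seq(first_ep, n)) {
    if (lab[i] != "NREM") next
    miss <- 0L; len <- 0L; j <- i
    while (j <= n && miss <= 1L) {
      if (lab[j] == "NREM") len <- len + 1L else miss <- miss + 1L
      j <- j + 1L
    }
    if (len >= episode_min_epochs) { onset_ep <- i; break }
  }
  if (is.na(onset_ep)) {
    message("no qualifying NREM episode after injection")
    return(invisible(NULL))
  }
  bp <- band_power(spectra, band)
  nrem_after <- which(lab == "NREM" & seq_len(n) >= onset_ep)
  nrem_after <- nrem_after[nrem_after <= length(bp)]
  ref <- reference %||% mean(bp[lab[seq_len(min(n, length(bp)))] == "NREM"])
  structure(list(onset_s = (onset_ep - 1) * ep,
                 t_s = (nrem_after - onset_ep) * ep,
                 swa_pct = 100 * bp[nrem_after] / ref),
            class = "vs_swa_dynamics")
}

#' Per-bin paired spectral contrast between two conditions
#'
#' Within-subject mean spectra are compared bin by bin with a paired
#' two-sided test, uncorrected (matching the per-frequency post-hoc
#' convention of plotting significance runs under spectra); maximal runs of
#' contiguous significant bins are reported.
#'
#' @param spectra_a,spectra_b matrices (subjects x frequency bins) of mean
#'   power per subject under each condition, paired by row
#' @param freq frequency axis (Hz) for the columns
#' @param alpha significance level
#' @param method `"t"` for paired t-tests, `"permutation"` for sign-flip
#'   permutation p-values
#' @param n_perm permutations when `method = "permutation"`
#' @return object of class `vs_contrast`: per-bin data frame `bins`
#'   (`freq`, `mean_a`, `mean_b`, `statistic`, `p`, `significant`) and
#'   data frame `runs` of maximal significant runs
#' @export
spectra_contrast <- function(spectra_a, spectra_b, freq = NULL, alpha = 0.05,
                             method = c("t", "permutation"), n_perm = 1000) {
  method <- match.arg(method)
  spectra_a <- as.matrix(spectra_a)
  spectra_b <- as.matrix(spectra_b)
  stopifnot(all(dim(spectra_a) == dim(spectra_b)))
  ns <- nrow(spectra_a)
  if (ns < 3) stop("need at least 3 paired subjects")
  if (is.null(freq)) freq <- seq_len(ncol(spectra_a))
  d <- spectra_a - spectra_b
  md <- colMeans(d)
  sdd <- apply(d, 2, stats::sd)
  tstat <- ifelse(sdd > 0, md / (sdd / sqrt(ns)), 0)
  if (method == "t") {
    p <- 2 * stats::pt(-abs(tstat), df = ns - 1)
  } else {
    p <- perm_sign_p(d, tstat, n_perm)
  }
  sig <- p < alpha
  bins <- data.frame(freq = freq, mean_a = colMeans(spectra_a),
                     mean_b = colMeans(spectra_b), statistic = tstat,
                     p = p, significant = sig)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start_hz = freq[starts[r$values]],
                     end_hz = freq[ends[r$values]],
                     n_bins = r$lengths[r$values])
  structure(list(bins = bins, runs = runs, alpha = alpha, method = method),
            class = "vs_contrast")
}

perm_sign_p <- function(d, tstat, n_perm) {
  ns <- nrow(d)
  count <- rep(1, ncol(d))  # add-one correction
  for (k in seq_len(n_perm)) {
    s <- sample(c(-1, 1), ns, replace = TRUE)
    dp <- d * s
    md <- colMeans(dp)
    sdd <- apply(dp, 2, stats::sd)
    tp <- ifelse(sdd > 0, md / (sdd / sqrt(ns)), 0)
    count <- count + (abs(tp) >= abs(tstat))
  }
  count / (n_perm + 1)
}

#' @export
print.vs_contrast <- function(x, ...) {
  cat(sprintf("<vs_contrast> %d bins, %d significant (alpha = %g, %s), %d run(s)\n",
              nrow(x$bins), sum(x$bins$significant), x$alpha, x$method,
              nrow(x$runs)))
  invisible(x)
}
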