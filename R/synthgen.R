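# Synthetic study generator.
#
# Emulates the statistical structure the analysis pipeline assumes: a
# semi-Markov wake/NREM/REM hypnogram in 4-s epochs, 1/f^chi background EEG
# with state-conditioned delta and theta oscillations, EMG tone graded
# wake > NREM > REM, LFP slow waves with time-locked multi-unit OFF periods,
# and a post-injection drug window with wake slow waves, occipital theta
# suppression and a transient pupil dilation.  Every draw is deterministic
# under the configured seed.

#' Configuration for the synthetic study generator
#'
#' Defaults describe a plausible adult-mouse light-period recording; per-state
#' magnitudes are free parameters of the generator, not measured values.
#'
#' @param seed master RNG seed (all stages derive sub-seeds from it)
#' @param duration_h recording length (hours)
#' @param epoch_s scoring epoch (s)
#' @param fs sampling rate (Hz); `fs * epoch_s` must be an integer
#' @param mean_bout_s named mean bout lengths (s) for `wake`, `nrem`, `rem`
#' @param p_nrem_to_rem probability a NREM bout ends in a REM transition
#' @param p_rem_to_wake probability a REM bout ends in waking (else NREM)
#' @param background_exponent chi of the 1/f^chi spectral background
#' @param background_rms background RMS (µV) for `frontal`, `occipital`, `lfp`
#' @param delta_amp_nrem peak amplitude (µV) of NREM delta on the frontal EEG
#' @param theta_amp_rem peak amplitude (µV) of REM theta on the occipital EEG
#' @param theta_amp_wake_occ peak amplitude (µV) of active-wake occipital theta
#' @param emg_rms named per-state EMG RMS (µV), graded wake > NREM > REM
#' @param wave_rate_nrem LFP slow-wave rate during NREM (events/min)
#' @param wave_amp_meanlog,wave_amp_sdlog lognormal parameters of injected
#'   slow-wave peak amplitudes (µV)
#' @param off_duration_ms mean and SD (ms) of OFF-period durations
#' @param baseline_spike_rate multi-unit firing rate outside OFF periods (Hz)
#' @param injection_t injection time (s from start)
#' @param drug_window numeric(2), start/end (s) of the acute drug effect
#' @param drug_swa_gain multiplicative gain on wake 0.5–4 Hz content in the
#'   window (1 = no effect)
#' @param drug_theta_gain multiplicative gain (<= 1) on occipital theta in the
#'   window
#' @param drug_pupil_peak_frac fractional peak pupil dilation (0.75 = +75%)
#' @param drug_pupil_duration_s duration (s) of the pupil transient
#' @param pupil_fps pupil camera frame rate (frames/s)
#' @param pupil_baseline_px baseline pupil diameter (pixels)
#' @param pupil_jitter_px SD (pixels) of keypoint jitter
#' @param dropout_frac fraction of frames given a sub-threshold likelihood
#' @return a validated list of class `vs_synth_config`
#' @export
synth_config <- function(seed = 1,
                         duration_h = 2,
                         epoch_s = 4,
                         fs = 256,
                         mean_bout_s = c(wake = 200, nrem = 280, rem = 80),
                         p_nrem_to_rem = 0.4,
                         p_rem_to_wake = 0.8,
                         background_exponent = 2,
                         background_rms = c(frontal = 15, occipital = 15, lfp = 10),
                         delta_amp_nrem = 60,
                         theta_amp_rem = 40,
                         theta_amp_wake_occ = 30,
                         emg_rms = c(wake = 40, nrem = 15, rem = 8),
                         wave_rate_nrem = 6,
                         wave_amp_meanlog = log(250),
                         wave_amp_sdlog = 0.3,
                         off_duration_ms = c(mean = 150, sd = 25),
                         baseline_spike_rate = 30,
                         injection_t = 1800,
                         drug_window = c(1800, 4500),
                         drug_swa_gain = 2,
                         drug_theta_gain = 0.4,
                         drug_pupil_peak_frac = 0.75,
                         drug_pupil_duration_s = 720,
                         pupil_fps = 50,
                         pupil_baseline_px = 40,
                         pupil_jitter_px = 0.2,
                         dropout_frac = 0.05) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(duration_h > 0, epoch_s > 0, fs > 0)
    if (abs(fs * epoch_s - round(fs * epoch_s)) > 1e-9)
      stop("fs incompatible with epoch_s: non-integer samples per epoch")
    if (any(mean_bout_s <= 0)) stop("bout means must be positive")
    stopifnot(all(c("wake", "nrem", "rem") %in% names(mean_bout_s)))
    stopifnot(p_nrem_to_rem >= 0, p_nrem_to_rem <= 1,
              p_rem_to_wake >= 0, p_rem_to_wake <= 1)
    if (any(c(background_rms, delta_amp_nrem, theta_amp_rem,
              theta_amp_wake_occ, emg_rms, wave_rate_nrem,
              baseline_spike_rate, pupil_fps, pupil_baseline_px) < 0))
      stop("rates and amplitudes must be non-negative")
    if (any(emg_rms <= 0)) stop("EMG RMS must be positive")
    if (!(emg_rms["wake"] > emg_rms["nrem"] && emg_rms["nrem"] > emg_rms["rem"]))
      stop("EMG RMS must be graded wake > NREM > REM")
    if (dropout_frac < 0 || dropout_frac >= 1) stop("dropout_frac must be in [0, 1)")
    dur <- duration_h * 3600
    if (drug_window[1] < 0 || drug_window[2] > dur || drug_window[1] >= drug_window[2])
      stop("drug_window must lie within the recording")
    if (off_duration_ms["mean"] <= 0) stop("OFF duration mean must be positive")
    if (drug_swa_gain < 1) stop("drug_swa_gain must be >= 1")
    if (drug_theta_gain < 0 || drug_theta_gain > 1)
      stop("drug_theta_gain must lie in [0, 1]")
  })
  structure(cfg, class = "vs_synth_config")
}

#' @export
print.vs_synth_config <- function(x, ...) {
  cat(sprintf("<vs_synth_config> seed=%d, %g h @ %g Hz, drug window %g-%g s\n",
              x$seed, x$duration_h, x$fs, x$drug_window[1], x$drug_window[2]))
  invisible(x)
}

#' Generate a ground-truth hypnogram from the semi-Markov state chain
#'
#' Bout lengths are exponential around the configured means (rounded up to
#' whole epochs); REM is entered only from NREM.
#'
#' @param config a [synth_config()]
#' @return character vector of per-epoch labels
#' @export
generate_hypnogram <- function(config) {
  stopifnot(inherits(config, "vs_synth_config"))
  n_ep <- floor(config$duration_h * 3600 / config$epoch_s)
  if (n_ep < 1) stop("duration shorter than one epoch")
  with_seed(sub_seed(config$seed, "hypnogram"), {
    labels <- character(0)
    state <- "wake"
    while (length(labels) < n_ep) {
      len <- max(1L, ceiling(stats::rexp(1, 1 / config$mean_bout_s[state]) /
                               config$epoch_s))
      len <- min(len, n_ep - length(labels))  # cap at the epochs still needed
      labels <- c(labels, rep(toupper(state), len))
      state <- switch(state,
        wake = "nrem",
        nrem = if (stats::runif(1) < config$p_nrem_to_rem) "rem" else "wake",
        rem  = if (stats::runif(1) < config$p_rem_to_wake) "wake" else "nrem")
    }
    labels[seq_len(n_ep)]
  })
}

# ---- signal synthesis ------------------------------------------------------

# 1/f^chi background by frequency-domain amplitude shaping of white noise;
# flat below f0 so the variance does not diverge at DC
colored_noise <- function(n, fs, chi, rms_target, f0 = 0.5) {
  w <- stats::rnorm(n)
  if (chi == 0) return(w * rms_target / rms(w))
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  shape <- (pmax(f, f0) / f0)^(-chi / 2)
  shape[1] <- 0
  y <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  y * rms_target / rms(y)
}

# cosine-tapered window used when adding per-epoch oscillations
edge_taper <- function(n, frac = 0.1) {
  m <- max(2L, round(n * frac))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = m)))
  c(ramp, rep(1, n - 2 * m), rev(ramp))
}

# add a per-epoch sinusoid (random frequency in f_range, random phase) to
# signal x for the given 1-based epoch indices; returns modified x
add_state_oscillation <- function(x, epochs, amp, f_range, fs, epoch_s) {
  if (length(epochs) == 0 || amp <= 0) return(x)
  ns <- as.integer(round(fs * epoch_s))
  tt <- (0:(ns - 1)) / fs
  tap <- edge_taper(ns)
  fr <- stats::runif(length(epochs), f_range[1], f_range[2])
  ph <- stats::runif(length(epochs), 0, 2 * pi)
  osc <- amp * sin(outer(tt, 2 * pi * fr) + rep(ph, each = ns)) * tap
  idx <- as.vector(outer(seq_len(ns), (epochs - 1) * ns, "+"))
  x[idx] <- x[idx] + as.vector(osc)
  x
}

# biphasic slow-wave template: 1.5 cycles of a Hann-windowed 2 Hz cosine;
# positive peak of exactly `amp` at the centre sample, sub-zero flanks either
# side, energy confined to the 0.5-4 Hz band
wave_template <- function(fs, amp = 1, f = 2) {
  half <- 0.75 / f
  tt <- seq(-half, half, by = 1 / fs)
  amp * cos(2 * pi * f * tt) * 0.5 * (1 + cos(pi * tt / half))
}

#' Synthesize the multichannel recording for a hypnogram
#'
#' Each EEG/LFP channel is a continuous 1/f^chi background plus
#' state-conditioned oscillations (frontal/occipital delta in NREM, occipital
#' theta in REM and active wake).  The LFP additionally carries discrete
#' biphasic slow waves during NREM, each with a multi-unit OFF period (a
#' spike-free interval) centred on its positive peak; spiking is otherwise
#' homogeneous Poisson.
#'
#' @param labels per-epoch state labels from [generate_hypnogram()]
#' @param config a [synth_config()]
#' @param channels which channels to synthesize
#' @return list with elements `recording` (a [vs_recording]) and `truth`
#'   (ground-truth hypnogram, injected wave table, OFF-period intervals)
#' @export
synthesize_signals <- function(labels, config,
                               channels = c("frontal", "occipital", "emg", "lfp")) {
  stopifnot(inherits(config, "vs_synth_config"), length(labels) > 0)
  fs <- config$fs
  epoch_s <- config$epoch_s
  ns <- fs * epoch_s
  if (abs(ns - round(ns)) > 1e-9)
    stop("fs incompatible with epoch_s: non-integer samples per epoch")
  ns <- as.integer(round(ns))
  ne <- length(labels)
  N <- ne * ns
  chi <- config$background_exponent

  out <- with_seed(sub_seed(config$seed, "signals"), {
    ch <- list()
    ep <- list(WAKE = which(labels == "WAKE"), NREM = which(labels == "NREM"),
               REM = which(labels == "REM"))

    if ("frontal" %in% channels) {
      x <- colored_noise(N, fs, chi, config$background_rms["frontal"])
      x <- add_state_oscillation(x, ep$NREM, config$delta_amp_nrem, c(1, 3),
                                 fs, epoch_s)
      x <- add_state_oscillation(x, ep$REM, 0.3 * config$theta_amp_rem,
                                 c(7, 9), fs, epoch_s)
      ch$frontal <- x
    }
    if ("occipital" %in% channels) {
      x <- colored_noise(N, fs, chi, config$background_rms["occipital"])
      x <- add_state_oscillation(x, ep$NREM, 0.6 * config$delta_amp_nrem,
                                 c(1, 3), fs, epoch_s)
      x <- add_state_oscillation(x, ep$REM, config$theta_amp_rem, c(7, 9),
                                 fs, epoch_s)
      x <- add_state_oscillation(x, ep$WAKE, config$theta_amp_wake_occ,
                                 c(7, 9), fs, epoch_s)
      ch$occipital <- x
    }
    if ("emg" %in% channels) {
      state_rms <- config$emg_rms[c(WAKE = "wake", NREM = "nrem",
                                    REM = "rem")[labels]]
      ch$emg <- stats::rnorm(N) * rep(as.numeric(state_rms), each = ns)
    }

    waves <- NULL
    offs <- NULL
    spikes <- NULL
    if ("lfp" %in% channels) {
      x <- colored_noise(N, fs, chi, config$background_rms["lfp"])
      x <- add_state_oscillation(x, ep$NREM, 0.3 * config$delta_amp_nrem,
                                 c(1, 3), fs, epoch_s)
      inj <- inject_waves(x, ep$NREM, config)
      x <- inj$x
      waves <- inj$waves
      offs <- off_intervals_for(waves, config)
      spikes <- poisson_spikes(N / fs, config$baseline_spike_rate, offs)
      ch$lfp <- x
    }
    list(ch = ch, waves = waves, offs = offs, spikes = spikes)
  })

  rec <- vs_recording(out$ch[channels[channels %in% names(out$ch)]], fs = fs,
                      spike_times = out$spikes,
                      condition = "vehicle",
                      injection_t = config$injection_t)
  truth <- list(hypnogram = labels, waves = out$waves, off_periods = out$offs,
                drug = FALSE)
  list(recording = rec, truth = truth)
}

# place slow-wave templates into NREM epochs of x; returns modified signal
# and the ground-truth wave table
inject_waves <- function(x, nrem_epochs, config) {
  fs <- config$fs
  epoch_s <- config$epoch_s
  ns <- as.integer(round(fs * epoch_s))
  tpl <- wave_template(fs)
  half_n <- (length(tpl) - 1L) / 2L
  margin <- (half_n + 1) / fs
  waves <- list()
  for (e in nrem_epochs) {
    n_w <- stats::rpois(1, config$wave_rate_nrem * epoch_s / 60)
    if (n_w == 0) next
    centers <- sort(stats::runif(n_w, margin, epoch_s - margin))
    if (n_w > 1) centers <- centers[c(TRUE, diff(centers) > 2 * margin)]
    amps <- stats::rlnorm(length(centers), config$wave_amp_meanlog,
                          config$wave_amp_sdlog)
    for (j in seq_along(centers)) {
      ci <- (e - 1L) * ns + as.integer(round(centers[j] * fs)) + 1L
      idx <- (ci - half_n):(ci + half_n)
      x[idx] <- x[idx] + amps[j] * tpl
      waves[[length(waves) + 1L]] <- c(peak_t = (ci - 1) / fs,
                                       amplitude = amps[j], epoch = e)
    }
  }
  waves <- if (length(waves)) as.data.frame(do.call(rbind, waves)) else
    data.frame(peak_t = numeric(0), amplitude = numeric(0), epoch = numeric(0))
  list(x = x, waves = waves)
}

# OFF intervals centred on each injected wave peak, duration drawn from the
# configured normal (clipped to a physiological floor)
off_intervals_for <- function(waves, config) {
  if (nrow(waves) == 0)
    return(data.frame(onset = numeric(0), offset = numeric(0)))
  d <- stats::rnorm(nrow(waves), config$off_duration_ms["mean"],
                    config$off_duration_ms["sd"]) / 1000
  d <- pmax(d, 0.03)
  data.frame(onset = waves$peak_t - d / 2, offset = waves$peak_t + d / 2)
}

# homogeneous Poisson spike train with OFF intervals silenced by construction
poisson_spikes <- function(duration, rate, offs) {
  n <- stats::rpois(1, rate * duration)
  t <- sort(stats::runif(n, 0, duration))
  drop_in_intervals(t, offs)
}

drop_in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0 || length(t) == 0) return(t)
  iv <- intervals[order(intervals$onset), ]
  # merge overlaps so the edge vector is sorted
  on <- iv$onset[1]; off <- iv$offset[1]
  edges <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$onset[i] <= off) {
      off <- max(off, iv$offset[i])
    } else {
      edges <- c(edges, on, off)
      on <- iv$onset[i]; off <- iv$offset[i]
    }
  }
  edges <- c(edges, on, off)
  inside <- findInterval(t, edges) %% 2 == 1
  t[!inside]
}

#' Apply acute drug effects inside the configured window
#'
#' Within `config$drug_window`, wake epochs receive added 0.5–4 Hz slow waves
#' on the EEG/LFP (existing band content scaled by `drug_swa_gain`, plus
#' discrete LFP/frontal waves with coupled OFF periods) and occipital theta
#' scaled by `drug_theta_gain`.  The EMG is untouched (behavioural wakefulness
#' is preserved) and samples outside the window are bitwise unchanged.
#'
#' @param recording a [vs_recording] from [synthesize_signals()]
#' @param labels the per-epoch ground-truth labels
#' @param config a [synth_config()]
#' @param truth optional truth list to extend with drug-injected events
#' @return list with modified `recording` and `truth`
#' @export
apply_drug_effects <- function(recording, labels, config, truth = NULL) {
  stopifnot(inherits(recording, "vs_recording"))
  fs <- recording$fs
  epoch_s <- config$epoch_s
  ns <- as.integer(round(fs * epoch_s))
  n_ep <- length(labels)
  dur <- n_ep * epoch_s
  win <- config$drug_window
  if (win[1] < 0 || win[2] > dur) stop("drug window outside recording")
  ep_start <- (seq_len(n_ep) - 1) * epoch_s
  in_win <- ep_start >= win[1] & (ep_start + epoch_s) <= win[2]
  target <- which(in_win & labels == "WAKE")
  sg <- config$drug_swa_gain
  tg <- config$drug_theta_gain
  rec <- recording
  rec$condition <- "drug"
  if (length(target) == 0 || (sg == 1 && tg == 1))
    return(list(recording = rec, truth = truth))

  runs <- split(target, cumsum(c(1, diff(target) != 1)))
  out <- with_seed(sub_seed(config$seed, "drug"), {
    if (tg != 1 && "occipital" %in% names(rec$channels)) {
      for (r in runs) {
        idx <- ((r[1] - 1L) * ns + 1L):(r[length(r)] * ns)
        seg <- rec$channels$occipital[idx]
        rec$channels$occipital[idx] <- seg +
          (tg - 1) * butter_bandpass(seg, fs, 7, 12.5)
      }
    }
    # discrete drug slow waves with coupled OFF periods; wave amplitudes are
    # rescaled so the added frontal 0.5-4 Hz power is (gain - 1) times the
    # unmodified wake level, i.e. drug_swa_gain is a band-power gain
    if (sg > 1 && "frontal" %in% names(rec$channels)) {
      tpl <- wave_template(fs)
      half_n <- (length(tpl) - 1L) / 2L
      mix <- c(frontal = 0.6, occipital = 0.4, lfp = 1)
      tgt_idx <- as.vector(vapply(target, function(e)
        ((e - 1L) * ns + 1L):(e * ns), integer(ns)))
      # per-epoch periodogram band power: the same estimator the gain is
      # measured with, and free of cross-epoch filtering transients
      sp0 <- epoch_spectra_matrix(rec$channels$frontal[tgt_idx], fs, epoch_s)
      p0 <- mean(band_power_of(sp0$power, sp0$freq, c(0.5, 4)))
      inj <- inject_waves(rec$channels$frontal * 0, target, config)
      if (nrow(inj$waves) > 0) {
        e_add <- sum((mix["frontal"] * inj$waves$amplitude)^2) * sum(tpl^2)
        s_amp <- sqrt((sg - 1) * p0 * length(tgt_idx) / e_add)
        inj$waves$amplitude <- inj$waves$amplitude * s_amp
        for (nm in intersect(names(mix), names(rec$channels))) {
          for (j in seq_len(nrow(inj$waves))) {
            ci <- as.integer(round(inj$waves$peak_t[j] * fs)) + 1L
            ii <- (ci - half_n):(ci + half_n)
            rec$channels[[nm]][ii] <- rec$channels[[nm]][ii] +
              mix[nm] * inj$waves$amplitude[j] * tpl
          }
        }
      }
      waves <- inj$waves
      offs <- off_intervals_for(waves, config)
      if (!is.null(rec$spike_times))
        rec$spike_times <- drop_in_intervals(rec$spike_times, offs)
      list(rec = rec, waves = waves, offs = offs)
    } else {
      list(rec = rec, waves = NULL, offs = NULL)
    }
  })
  rec <- out$rec
  if (!is.null(truth)) {
    if (!is.null(out$waves) && nrow(out$waves) > 0) {
      truth$drug_waves <- out$waves
      truth$off_periods <- rbind(truth$off_periods, out$offs)
      truth$off_periods <- truth$off_periods[order(truth$off_periods$onset), ]
    }
    truth$drug <- TRUE
  }
  list(recording = rec, truth = truth)
}

#' Synthesize a pupil keypoint trace
#'
#' The four cardinal points lie on a circle of the true diameter plus
#' Gaussian jitter.  Under the drug condition a smooth raised-cosine dilation
#' transient of fractional peak `drug_pupil_peak_frac` and duration
#' `drug_pupil_duration_s` starts at the drug-window onset.  A fraction
#' `dropout_frac` of frames receive one keypoint with likelihood below the
#' 0.99 confidence cut.
#'
#' @param config a [synth_config()]
#' @param condition `"vehicle"` or `"drug"`
#' @return list with `trace` (a [vs_pupil_trace]) and `true_diameter`
#' @export
synthesize_pupil <- function(config, condition = c("vehicle", "drug")) {
  condition <- match.arg(condition)
  stopifnot(config$pupil_fps > 0)
  if (config$pupil_baseline_px <= 0) stop("pupil baseline diameter must be positive")
  n <- floor(config$duration_h * 3600 * config$pupil_fps)
  t <- (seq_len(n) - 1) / config$pupil_fps
  with_seed(sub_seed(config$seed, "pupil"), {
    d <- config$pupil_baseline_px *
      (1 + 0.01 * sin(2 * pi * t / 600 + stats::runif(1, 0, 2 * pi)))
    if (condition == "drug") {
      t0 <- config$drug_window[1]
      dd <- config$drug_pupil_duration_s
      inb <- t >= t0 & t <= t0 + dd
      bump <- 0.5 * (1 - cos(2 * pi * (t[inb] - t0) / dd))
      d[inb] <- d[inb] * (1 + config$drug_pupil_peak_frac * bump)
    }
    cx <- 100; cy <- 100
    j <- config$pupil_jitter_px
    pt <- function(dx, dy) list(x = cx + dx * d / 2 + stats::rnorm(n, 0, j),
                                y = cy + dy * d / 2 + stats::rnorm(n, 0, j))
    np <- pt(0, 1); sp <- pt(0, -1); epp <- pt(1, 0); wp <- pt(-1, 0)
    lik <- matrix(stats::runif(4 * n, 0.991, 1), ncol = 4)
    n_drop <- round(config$dropout_frac * n)
    if (n_drop > 0) {
      fr <- sample.int(n, n_drop)
      lik[cbind(fr, sample.int(4, n_drop, replace = TRUE))] <-
        stats::runif(n_drop, 0.3, 0.989)
    }
    frames <- data.frame(
      t = t,
      north_x = np$x, north_y = np$y, north_likelihood = lik[, 1],
      south_x = sp$x, south_y = sp$y, south_likelihood = lik[, 2],
      east_x = epp$x, east_y = epp$y, east_likelihood = lik[, 3],
      west_x = wp$x, west_y = wp$y, west_likelihood = lik[, 4])
    list(trace = vs_pupil_trace(frames, fps = config$pupil_fps),
         true_diameter = d)
  })
}

#' Generate an on-disk synthetic study bundle (drug and vehicle arms)
#'
#' Both arms share the seed-derived baseline, emulating a crossover design:
#' pre-injection samples are identical across conditions.  Each arm directory
#' receives the EDF signals, spike list, pose CSV, ground-truth hypnogram,
#' wave/OFF-period tables, the true pupil diameter and a config snapshot.
#'
#' @param config a [synth_config()]
#' @param dir existing writable output directory
#' @param conditions arms to generate
#' @return named list of per-condition directories, invisibly
#' @export
generate_study <- function(config, dir, conditions = c("vehicle", "drug")) {
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  labels <- generate_hypnogram(config)
  base <- synthesize_signals(labels, config)
  out <- list()
  for (cond in conditions) {
    sub <- file.path(dir, cond)
    dir.create(sub, showWarnings = FALSE)
    rec <- base$recording
    truth <- base$truth
    if (cond == "drug") {
      d <- apply_drug_effects(rec, labels, config, truth)
      rec <- d$recording
      truth <- d$truth
    }
    pup <- synthesize_pupil(config, cond)
    rec$pupil <- pup$trace
    rec$condition <- cond

    write_edf(rec, file.path(sub, "signals.edf"))
    write_spikes(rec$spike_times, file.path(sub, "spikes.txt"))
    write_pose_csv(pup$trace, file.path(sub, "pose.csv"))
    write_hypnogram(vs_hypnogram(labels, config$epoch_s),
                    file.path(sub, "hypnogram.tsv"))
    utils::write.csv(truth$waves, file.path(sub, "waves_truth.csv"),
                     row.names = FALSE)
    if (!is.null(truth$drug_waves))
      utils::write.csv(truth$drug_waves, file.path(sub, "drug_waves_truth.csv"),
                       row.names = FALSE)
    utils::write.csv(truth$off_periods, file.path(sub, "off_periods_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(t = (seq_along(pup$true_diameter) - 1) /
                                  config$pupil_fps,
                                diameter = pup$true_diameter),
                     file.path(sub, "pupil_truth.csv"), row.names = FALSE)
    snap <- config[!vapply(config, is.null, TRUE)]
    write_config(c(list(condition = cond), snap), file.path(sub, "config.txt"))
    out[[cond]] <- sub
  }
  invisible(out)
}

#' Load one arm of a bundle written by [generate_study()]
#' @param dir the per-condition directory
#' @param fps pupil frame rate (read from the config snapshot by default)
#' @return list with `recording`, `hypnogram`, `truth`
#' @export
read_study <- function(dir, fps = NULL) {
  cfg <- read_config(file.path(dir, "config.txt"))
  fps <- fps %||% cfg$pupil_fps
  rec <- read_edf(file.path(dir, "signals.edf"),
                  condition = as.character(cfg$condition),
                  injection_t = cfg$injection_t)
  rec$spike_times <- read_spikes(file.path(dir, "spikes.txt"))
  rec$pupil <- read_pose_csv(file.path(dir, "pose.csv"), fps = fps)
  hyp <- read_hypnogram(file.path(dir, "hypnogram.tsv"), epoch_s = cfg$epoch_s)
  truth <- list(
    waves = utils::read.csv(file.path(dir, "waves_truth.csv")),
    off_periods = utils::read.csv(file.path(dir, "off_periods_truth.csv")),
    pupil = utils::read.csv(file.path(dir, "pupil_truth.csv")))
  dw <- file.path(dir, "drug_waves_truth.csv")
  if (file.exists(dw)) truth$drug_waves <- utils::read.csv(dw)
  list(recording = rec, hypnogram = hyp, truth = truth, config = cfg)
}
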