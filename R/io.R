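# Containers and readers/writers for the pipeline's text formats, plus the
# acquisition-side preprocessing (zero-phase Chebyshev II prefilter and
# resampling to 256 Hz).

#' Multichannel recording container
#'
#' @param channels named list of numeric vectors (µV); standard names are
#'   `frontal`, `occipital`, `emg`, `lfp`
#' @param fs sampling rate (Hz), common to all channels
#' @param spike_times optional sorted numeric vector of spike times (s)
#' @param pupil optional [vs_pupil_trace]
#' @param condition condition label (e.g. `"vehicle"`, `"drug"`)
#' @param injection_t injection time in seconds from recording start
#' @param t0_zt Zeitgeber time (h) at recording start
#' @return an object of class `vs_recording`
#' @export
vs_recording <- function(channels, fs, spike_times = NULL, pupil = NULL,
                         condition = NA_character_, injection_t = NA_real_,
                         t0_zt = NA_real_) {
  stopifnot(is.list(channels), fs > 0)
  if (length(channels) < 1) stop("recording must contain at least one channel")
  n <- sapply(channels, length)
  if (max(n) - min(n) > 1)
    stop("channels differ in duration by more than one sample")
  if (!is.null(spike_times)) {
    if (is.unsorted(spike_times)) stop("spike times must be sorted")
    dur <- max(n) / fs
    if (any(spike_times < 0 | spike_times > dur))
      stop("spike times outside [0, duration]")
  }
  structure(list(channels = channels, fs = fs, spike_times = spike_times,
                 pupil = pupil, condition = condition,
                 injection_t = injection_t, t0_zt = t0_zt),
            class = "vs_recording")
}

#' @export
print.vs_recording <- function(x, ...) {
  dur <- max(sapply(x$channels, length)) / x$fs
  cat(sprintf("<vs_recording> %d channel(s) [%s] @ %g Hz, %.1f s",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              x$fs, dur))
  if (!is.null(x$spike_times)) cat(sprintf(", %d spikes", length(x$spike_times)))
  if (!is.na(x$condition)) cat(", condition=", x$condition, sep = "")
  cat("\n")
  invisible(x)
}

#' Per-epoch hypnogram container
#'
#' @param labels character vector of per-epoch states
#'   (`WAKE`, `NREM`, `REM`, `MICRO_AROUSAL`)
#' @param epoch_s epoch length (s), default 4
#' @param artefact optional logical matrix, epochs x derivations
#' @return an object of class `vs_hypnogram`
#' @export
vs_hypnogram <- function(labels, epoch_s = 4, artefact = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), VS_STATES)
  if (length(bad) > 0) stop("unknown state label: ", paste(bad, collapse = ", "))
  if (!is.null(artefact)) {
    artefact <- as.matrix(artefact)
    stopifnot(nrow(artefact) == length(labels), is.logical(artefact))
  }
  structure(list(labels = labels, epoch_s = epoch_s, artefact = artefact),
            class = "vs_hypnogram")
}

#' @export
print.vs_hypnogram <- function(x, ...) {
  tb <- table(factor(x$labels, levels = VS_STATES))
  cat(sprintf("<vs_hypnogram> %d epochs of %g s: %s\n", length(x$labels),
              x$epoch_s, paste(names(tb), tb, sep = "=", collapse = " ")))
  invisible(x)
}

#' @export
summary.vs_hypnogram <- function(object, ...) {
  tb <- table(factor(object$labels, levels = VS_STATES))
  mins <- as.numeric(tb) * object$epoch_s / 60
  data.frame(state = names(tb), epochs = as.integer(tb), minutes = mins)
}

# ---- preprocessing ---------------------------------------------------------

#' Acquisition-side preprocessing
#'
#' Zero-phase Chebyshev type II band-pass prefiltering (0.5–120 Hz for
#' EEG/LFP, 10–45 Hz for EMG) followed by polyphase resampling to 256 Hz.
#' Stopband edges are placed at half the lower passband edge and 1.5x the
#' upper edge (capped inside Nyquist), with 40 dB stopband attenuation per
#' pass; the filter order is the minimum meeting those edges.
#'
#' @param recording a [vs_recording] at any rate >= 256 Hz
#' @param fs_out output sampling rate (Hz), default 256
#' @return the preprocessed [vs_recording] at `fs_out`
#' @export
preprocess <- function(recording, fs_out = 256) {
  stopifnot(inherits(recording, "vs_recording"))
  fs <- recording$fs
  if (fs < fs_out) stop("sampling rate below target rate")
  nyq <- fs / 2
  bands <- list(eeg = c(0.5, 120), emg = c(10, 45))
  if (fs < 2 * 120) stop("sampling rate below twice the EEG passband edge")
  filt <- lapply(bands, function(b) {
    hi_stop <- min(1.5 * b[2], b[2] + 0.5 * (nyq - b[2]))
    design_bandpass(fs, b, c(b[1] / 2, hi_stop))
  })
  out <- lapply(names(recording$channels), function(nm) {
    kind <- if (nm == "emg") "emg" else "eeg"
    y <- apply_filter(filt[[kind]], recording$channels[[nm]])
    if (fs != fs_out) y <- as.numeric(signal::resample(y, fs_out, fs))
    y
  })
  names(out) <- names(recording$channels)
  r <- recording
  r$channels <- out
  r$fs <- fs_out
  r
}

# ---- pose-estimation CSV ---------------------------------------------------

#' Read a pose-estimation keypoint CSV (DeepLabCut dialect)
#'
#' Expects the three header rows (scorer / bodyparts / coords) and x, y,
#' likelihood columns for the four cardinal pupil points.
#'
#' @param path CSV path
#' @param fps frame rate used to timestamp frames (frame k at `(k-1)/fps` s)
#' @param points bodypart names of the four cardinal points, in the order
#'   north, south, east, west
#' @return a [vs_pupil_trace]
#' @export
read_pose_csv <- function(path, fps, points = c("north", "south", "east", "west")) {
  if (!file.exists(path)) stop("pose CSV not found: ", path)
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3) stop("malformed pose CSV header: fewer than 3 header rows")
  bodyparts <- strsplit(hdr[2], ",")[[1]]
  coords <- strsplit(hdr[3], ",")[[1]]
  for (p in points) {
    if (!(p %in% bodyparts)) stop("pose CSV lacks bodypart: ", p)
  }
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  cols <- list()
  for (p in points) {
    ix <- which(bodyparts == p)
    for (cc in c("x", "y", "likelihood")) {
      j <- ix[coords[ix] == cc]
      if (length(j) != 1) stop("pose CSV lacks ", cc, " column for ", p)
      v <- dat[[j]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
        stop("non-numeric ", cc, " for ", p, " at data row ", bad)
      }
      cols[[paste(p, cc, sep = "_")]] <- v
    }
  }
  n <- nrow(dat)
  vs_pupil_trace(data.frame(t = (seq_len(n) - 1) / fps, cols,
                            check.names = FALSE), fps = fps)
}

#' Pupil trace container
#'
#' @param frames data frame with column `t` and, per cardinal point
#'   (`north`, `south`, `east`, `west`), columns `<point>_x`, `<point>_y`,
#'   `<point>_likelihood`; a `diameter` column may be present
#' @param fps nominal frame rate (Hz)
#' @export
vs_pupil_trace <- function(frames, fps) {
  stopifnot(is.data.frame(frames), "t" %in% names(frames))
  if (is.unsorted(frames$t, strictly = TRUE)) stop("timestamps must be strictly increasing")
  lik <- frames[grep("_likelihood$", names(frames))]
  if (length(lik) && (min(as.matrix(lik)) < 0 || max(as.matrix(lik)) > 1))
    stop("likelihoods must lie in [0, 1]")
  structure(list(frames = frames, fps = fps), class = "vs_pupil_trace")
}

#' @export
print.vs_pupil_trace <- function(x, ...) {
  cat(sprintf("<vs_pupil_trace> %d frames @ %g fps", nrow(x$frames), x$fps))
  if ("diameter" %in% names(x$frames))
    cat(sprintf(", %d with diameter", sum(!is.na(x$frames$diameter))))
  cat("\n")
  invisible(x)
}

#' Write a pose CSV in the same dialect [read_pose_csv()] accepts
#' @param trace a [vs_pupil_trace]
#' @param path output path
#' @param scorer scorer tag placed in the first header row
#' @export
write_pose_csv <- function(trace, path, scorer = "synthetic") {
  fr <- trace$frames
  points <- c("north", "south", "east", "west")
  cols <- as.vector(t(outer(points, c("x", "y", "likelihood"), paste, sep = "_")))
  lines <- c(
    paste(c("scorer", rep(scorer, length(cols))), collapse = ","),
    paste(c("bodyparts", rep(points, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), 4)), collapse = ","))
  writeLines(lines, path)
  m <- cbind(frame = seq_len(nrow(fr)) - 1, fr[cols])
  utils::write.table(m, path, sep = ",", append = TRUE, col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- hypnogram / spikes / config text formats ------------------------------

#' Write a hypnogram to tab-separated text
#'
#' One row per epoch: index (0-based), label, then one 0/1 artefact flag per
#' derivation.
#' @param hyp a [vs_hypnogram]
#' @param path output path
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "vs_hypnogram"))
  n <- length(hyp$labels)
  df <- data.frame(epoch = seq_len(n) - 1, label = hyp$labels)
  if (!is.null(hyp$artefact)) {
    a <- as.data.frame(hyp$artefact * 1L)
    names(a) <- paste0("artefact_", colnames(hyp$artefact) %||%
                         paste0("d", seq_len(ncol(hyp$artefact))))
    df <- cbind(df, a)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram written by [write_hypnogram()]
#' @param path file path
#' @param epoch_s epoch length (s)
#' @export
read_hypnogram <- function(path, epoch_s = 4) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  if (length(readLines(path, n = 2)) < 2)
    return(vs_hypnogram(character(0), epoch_s = epoch_s))
  df <- utils::read.delim(path)
  bad <- setdiff(unique(df$label), VS_STATES)
  if (length(bad) > 0) stop("unknown state label: ", paste(bad, collapse = ", "))
  acol <- grep("^artefact_", names(df))
  art <- NULL
  if (length(acol) > 0) {
    art <- as.matrix(df[acol]) == 1
    colnames(art) <- sub("^artefact_", "", names(df)[acol])
  }
  vs_hypnogram(df$label, epoch_s = epoch_s, artefact = art)
}

#' Read/write plain-text spike lists (one time in seconds per line)
#' @param path file path
#' @export
read_spikes <- function(path) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (is.unsorted(x)) stop("spike times not sorted in ", path)
  x
}

#' @rdname read_spikes
#' @param times numeric vector of spike times (s)
#' @export
write_spikes <- function(times, path) {
  writeLines(formatC(times, format = "f", digits = 6), path)
  invisible(path)
}

#' Read/write a flat key-value config snapshot (`key: value` lines)
#' @param x named list of scalars/vectors (vectors comma-separated)
#' @param path file path
#' @export
write_config <- function(x, path) {
  lines <- vapply(names(x), function(k)
    paste0(k, ": ", paste(x[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else v
  })
  names(out) <- vapply(kv, `[`, "", 1)
  out
}
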