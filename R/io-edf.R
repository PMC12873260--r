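# Minimal EDF (European Data Format) reader/writer for continuous
# multichannel recordings: 16-bit samples, one data record per second.
# Only the features the pipeline needs are supported (no EDF+ annotations).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

# format a physical bound into <= 8 ASCII chars and return the value that the
# stored string parses back to, so quantization uses exactly what is on disk
edf_num8 <- function(x) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  while (nchar(s) > 8) {
    s <- formatC(x, format = "g", digits = max(1, 8 - nchar(s) + 7), width = 1)
    if (nchar(s) > 8) s <- substr(s, 1, 8)
  }
  list(str = s, val = as.numeric(s))
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to 16-bit integers using a per-channel physical range
#' taken from the data and padded by 5%, maximising amplitude resolution.
#' The recording is truncated to a whole number of seconds (EDF stores one
#' data record per second here).
#'
#' @param recording a [vs_recording] object
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "vs_recording"))
  chans <- recording$channels
  if (length(chans) == 0) stop("recording has no channels")
  fs <- recording$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- min(sapply(chans, length)) %/% fs
  if (n_rec < 1) stop("recording shorter than one second")

  scal <- lapply(chans, function(x) {
    x <- x[seq_len(n_rec * fs)]
    r <- range(x)
    pad <- 0.05 * max(diff(r), 1e-6)
    pmin <- edf_num8(r[1] - pad)
    pmax <- edf_num8(r[2] + pad)
    list(pmin = pmin, pmax = pmax)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  ns <- length(chans)
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, w) writeChar(paste0(sapply(f, edf_pad, width = w),
                                           collapse = ""), con, eos = NULL)
  field(names(chans), 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)                     # physical dimension
  field(sapply(scal, function(s) s$pmin$str), 8)
  field(sapply(scal, function(s) s$pmax$str), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)                       # samples per record
  field(rep("", ns), 32)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- chans[[i]][seq_len(n_rec * fs)]
    plo <- scal[[i]]$pmin$val
    phi <- scal[[i]]$pmax$val
    d <- round((x - plo) / (phi - plo) * 65535 - 32768)
    dig[[i]] <- matrix(as.integer(pmin(pmax(d, -32768), 32767)), nrow = fs)
  }
  # interleave per record
  out <- matrix(0L, nrow = fs * ns, ncol = n_rec)
  for (i in seq_len(ns)) out[(i - 1) * fs + seq_len(fs), ] <- dig[[i]]
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF file
#' @param channel_map named character vector mapping standard roles
#'   (`frontal`, `occipital`, `emg`, `lfp`) to EDF channel labels; by default
#'   labels are matched case-insensitively against the role names.
#' @param condition,injection_t,t0_zt metadata attached to the recording
#' @return a [vs_recording]
#' @export
read_edf <- function(path, channel_map = NULL, condition = NA_character_,
                     injection_t = NA_real_, t0_zt = NA_real_) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("corrupt EDF header (bad version field)")
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header (no signals)")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))))
    stop("corrupt EDF header (non-numeric scaling fields)")

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr)) stop("EDF data shorter than header claims")
  offs <- c(0, cumsum(spr))
  chans <- vector("list", ns)
  idx_rec <- matrix(seq_len(sum(spr)), ncol = 1)
  for (i in seq_len(ns)) {
    sel <- as.vector(outer(offs[i] + seq_len(spr[i]), (0:(n_rec - 1)) * sum(spr), "+"))
    d <- raw[sel]
    chans[[i]] <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  }
  names(chans) <- labels

  fs <- spr / rec_dur
  if (length(unique(fs)) != 1) stop("channels with mismatched sampling rates")
  roles <- resolve_channel_roles(labels, channel_map)
  names(chans) <- roles
  vs_recording(channels = chans, fs = fs[1], condition = condition,
               injection_t = injection_t, t0_zt = t0_zt)
}

# map EDF labels onto standard roles; errors name any unresolvable label
resolve_channel_roles <- function(labels, channel_map = NULL) {
  roles <- c("frontal", "occipital", "emg", "lfp")
  if (!is.null(channel_map)) {
    out <- character(length(labels))
    for (i in seq_along(labels)) {
      hit <- names(channel_map)[channel_map == labels[i]]
      if (length(hit) != 1) stop("EDF channel label not in channel map: ", labels[i])
      out[i] <- hit
    }
    return(out)
  }
  out <- character(length(labels))
  for (i in seq_along(labels)) {
    hit <- roles[vapply(roles, function(r) grepl(r, labels[i], ignore.case = TRUE), TRUE)]
    if (length(hit) != 1)
      stop("cannot resolve EDF channel label to a role: ", labels[i])
    out[i] <- hit
  }
  out
}
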