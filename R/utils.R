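# Shared small helpers.

VS_STATES <- c("WAKE", "NREM", "REM", "MICRO_AROUSAL")

# evaluate expr with a locally-set RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# sub-seed derived from a master seed and a stage tag (kept under 2^31)
sub_seed <- function(seed, tag) {
  (as.numeric(seed) * 1009 + sum(utf8ToInt(tag)) * 131) %% 2147483647
}

rms <- function(x) sqrt(mean(x^2))

# number of 4-s epochs in a signal
n_epochs_of <- function(n_samples, fs, epoch_s) floor(n_samples / (fs * epoch_s))

# matrix of a signal cut into epochs (samples x epochs); trailing partial
# epoch dropped
epoch_matrix <- function(x, fs, epoch_s) {
  ns <- as.integer(round(fs * epoch_s))
  ne <- floor(length(x) / ns)
  if (ne < 1) stop("recording shorter than one epoch")
  matrix(x[seq_len(ns * ne)], nrow = ns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
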