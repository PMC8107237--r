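#' Construct an EEG recording container
#'
#' @param data channels x samples numeric matrix (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param channel_labels optional character vector, one per channel.
#' @param subject_id,session_id identifiers carried through the pipeline.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          subject_id = NA, session_id = NA) {
  data <- as.matrix(data)
  if (fs <= 0) stopf("fs must be positive")
  if (anyNA(data)) stopf("EEG data must not contain missing samples")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  stopifnot(length(channel_labels) == nrow(data))
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 subject_id = subject_id, session_id = session_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Normalize each EEG channel to zero mean and unit variance
#'
#' Per channel, over the full session, the signal is centred and scaled to
#' variance 1 (population variance, denominator n). Channel normalization
#' precedes epoching so that every lead contributes on the same scale to
#' the epoch power spectra.
#'
#' @param recording an [eeg_recording()] object.
#' @return the recording with normalized channels.
#' @export
normalize_channels <- function(recording) {
  x <- recording$data
  if (ncol(x) < 2) stopf("each channel needs more than one sample")
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2))
  bad <- which(s == 0)
  if (length(bad)) {
    stopf("constant channel(s) cannot be normalized: %s",
          paste(recording$channel_labels[bad], collapse = ", "))
  }
  recording$data <- xc / s
  recording
}

#' Split an EEG recording into contiguous scan-locked epochs
#'
#' Epochs are non-overlapping, start at sample 0, and have length
#' `round(epoch_duration * fs)` samples; a trailing remainder shorter than
#' one epoch is discarded. With `epoch_duration` equal to the fMRI TR the
#' epoch grid locks one-to-one to the scan grid.
#'
#' @param recording an [eeg_recording()] object.
#' @param epoch_duration epoch length in seconds (typically the TR).
#' @return numeric array `(n_t, n_c, n_samples_per_epoch)` with attributes
#'   `fs` and `epoch_duration`.
#' @export
epoch_signal <- function(recording, epoch_duration) {
  n_spe <- round(epoch_duration * recording$fs)
  if (n_spe < 2) stopf("epoch_duration x fs must round to an integer >= 2")
  n_c <- nrow(recording$data)
  total <- ncol(recording$data)
  n_t <- floor(total / n_spe)
  if (n_t < 1) stopf("recording (%d samples) shorter than one epoch (%d)",
                     total, n_spe)
  x <- recording$data[, seq_len(n_t * n_spe), drop = FALSE]
  # (n_c, n_spe, n_t) -> (n_t, n_c, n_spe)
  ep <- aperm(array(x, dim = c(n_c, n_spe, n_t)), c(3, 1, 2))
  dimnames(ep) <- list(NULL, recording$channel_labels, NULL)
  attr(ep, "fs") <- recording$fs
  attr(ep, "epoch_duration") <- epoch_duration
  ep
}

#' Epoch power spectra as a spatiospectral matrix
#'
#' Each epoch and channel is transformed with a rectangular-window FFT
#' (coefficients scaled by `1/sqrt(N)` so that the summed squared moduli
#' over all bins equal the summed squared time samples). Absolute power is
#' the squared modulus; relative power divides each bin by the total power
#' of that epoch-channel over all FFT bins, so relative spectra sum to 1
#' before band truncation. Bins `k` with `k * fs / N <= band_max` are
#' retained, DC included (1.66 s epochs at 250 Hz and a 40 Hz band give 67
#' bins).
#'
#' @param epochs epoch array from [epoch_signal()].
#' @param fs sampling rate in Hz (defaults to the array attribute).
#' @param band_max upper band edge in Hz; must be below fs/2.
#' @param power_mode `"absolute"` or `"relative"`.
#' @param TR epoch duration in seconds carried as metadata.
#' @param subject_id,session_id identifiers carried as metadata.
#' @return an object of class `ss_matrix`: list with the power array
#'   `E(n_t, n_c, n_omega)`, bin frequencies `freqs`, `power_mode`, `TR`
#'   and ids.
#' @export
compute_power <- function(epochs, fs = attr(epochs, "fs"), band_max = 40,
                          power_mode = c("absolute", "relative"),
                          TR = attr(epochs, "epoch_duration"),
                          subject_id = NA, session_id = NA) {
  power_mode <- match.arg(power_mode)
  epoch_powers(epochs, fs = fs, band_max = band_max,
               modes = power_mode, TR = TR, subject_id = subject_id,
               session_id = session_id)[[power_mode]]
}

# compute absolute and/or relative power matrices with a single FFT pass
epoch_powers <- function(epochs, fs = attr(epochs, "fs"), band_max = 40,
                         modes = c("absolute", "relative"),
                         TR = attr(epochs, "epoch_duration"),
                         subject_id = NA, session_id = NA) {
  if (band_max >= fs / 2) stopf("band_max must be below the Nyquist rate")
  n_t <- dim(epochs)[1]
  n_c <- dim(epochs)[2]
  N <- dim(epochs)[3]
  # columns = one epoch-channel each; rows = time samples
  x <- matrix(aperm(epochs, c(3, 1, 2)), nrow = N)
  pw <- Mod(stats::mvfft(x))^2 / N # N x (n_t * n_c), all bins
  n_omega <- min(floor(band_max * N / fs) + 1, N)
  as_ss <- function(pw_band, mode) {
    E <- aperm(array(pw_band, dim = c(n_omega, n_t, n_c)), c(2, 3, 1))
    dimnames(E) <- list(NULL, dimnames(epochs)[[2]], NULL)
    structure(list(E = E,
                   freqs = (seq_len(n_omega) - 1) * fs / N,
                   power_mode = mode, TR = TR, fs = fs, n_fft = N,
                   subject_id = subject_id, session_id = session_id),
              class = "ss_matrix")
  }
  band <- pw[seq_len(n_omega), , drop = FALSE]
  out <- list()
  if ("absolute" %in% modes) out$absolute <- as_ss(band, "absolute")
  if ("relative" %in% modes) {
    tot <- colSums(pw)
    if (any(tot == 0)) {
      stopf("all-zero epoch: relative power undefined (zero total power)")
    }
    out$relative <- as_ss(sweep(band, 2, tot, "/"), "relative")
  }
  out
}

#' @export
print.ss_matrix <- function(x, ...) {
  d <- dim(x$E)
  cat(sprintf(
    "<ss_matrix> %s power: %d epochs x %d channels x %d bins (0-%.1f Hz)\n",
    x$power_mode, d[1], d[2], d[3], max(x$freqs)))
  invisible(x)
}

# flatten E to (n_t) x (n_c * n_omega) with channel-major layout: feature
# index = (channel - 1) * n_omega + bin; shared by the ICA stage
flatten_ss <- function(ss) {
  d <- dim(ss$E)
  matrix(aperm(ss$E, c(1, 3, 2)), nrow = d[1], ncol = d[2] * d[3])
}

# inverse of the flatten_ss feature layout for a single pattern row
unflatten_pattern <- function(row, n_c, n_omega) {
  t(matrix(row, nrow = n_omega, ncol = n_c))
}
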