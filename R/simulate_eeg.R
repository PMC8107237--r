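#' Specify a ground-truth EEG spatiospectral pattern
#'
#' A pattern is a band-limited rhythm projected to the scalp through a
#' fixed channel topography. Per epoch the source is a random-phase
#' multisine whose magnitude spectrum follows a 4th-order Butterworth
#' band-pass power profile, scaled by an amplitude envelope: a constant
#' baseline plus, for each stimulus, a boxcar of one epoch length
#' aligned to the epoch grid and scaled by the type-specific modulation
#' amplitude, times a slow log-normal amplitude modulation. The
#' optional BOLD side of the pattern (an active voxel mask and
#' per-voxel response coefficient ranges) drives the fMRI forward
#' model.
#'
#' @param name pattern label.
#' @param band numeric `(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param topography optional per-channel weight vector; when `NULL` a
#'   random topography with unit root-mean-square amplitude is drawn at
#'   synthesis time.
#' @param baseline envelope baseline amplitude.
#' @param modulation named amplitudes added to the envelope during the
#'   epoch containing each stimulus type's onset (may be negative).
#' @param mask_lo,mask_hi opposite voxel corners (1-based, inclusive) of
#'   the pattern's active BOLD block, or `NULL` for an EEG-only pattern.
#' @param coef_ranges list of length-2 ranges for the per-voxel response
#'   coefficients `b1`, `b2`, `b3` drawn uniformly inside the mask.
#' @param amp_sd standard deviation of the slow multiplicative
#'   (log-normal) amplitude modulation of the rhythm. Real EEG rhythms
#'   wax and wane over seconds; this coherent band-wide power
#'   fluctuation is what distinguishes a rhythm from stationary filtered
#'   noise, whose epoch band power varies only bin-by-bin. Set 0 for a
#'   stationary source.
#' @param amp_tau correlation time of the amplitude modulation in
#'   seconds.
#' @param bin_cv coefficient of variation of the per-bin, per-epoch
#'   spectral magnitude jitter around the band profile. 0 gives epochs
#'   whose band spectrum follows the profile exactly; stationary
#'   filtered Gaussian noise would correspond to fully exponential bin
#'   power (far above the default 0.3).
#' @return a `pattern_spec` list.
#' @export
pattern_spec <- function(name, band, topography = NULL, baseline = 1,
                         modulation = c(frequent = 0, target = 0,
                                        distractor = 0),
                         mask_lo = NULL, mask_hi = NULL,
                         coef_ranges = list(b1 = c(0.6, 1.4),
                                            b2 = c(-0.5, 0.5),
                                            b3 = c(-0.3, 0.3)),
                         amp_sd = 0.5, amp_tau = 8, bin_cv = 0) {
  stopifnot(length(band) == 2, band[1] < band[2])
  structure(list(name = name, band = band, topography = topography,
                 baseline = baseline, modulation = modulation,
                 mask_lo = mask_lo, mask_hi = mask_hi,
                 coef_ranges = coef_ranges,
                 amp_sd = amp_sd, amp_tau = amp_tau, bin_cv = bin_cv),
            class = "pattern_spec")
}

# one-sided band power profile of a 4th-order Butterworth band-pass
# applied forward and backward (|H|^4), on the epoch FFT bin grid,
# normalized so a unit-envelope source has unit variance
band_profile <- function(band, fs, n_spe) {
  filt <- signal::butter(4, band / (fs / 2), type = "pass")
  kmax <- floor((n_spe - 1) / 2)
  f <- (1:kmax) * fs / n_spe # positive-frequency bins, DC excluded
  H <- signal::freqz(filt$b, filt$a, n = 2 * pi * f / fs)$h
  prof <- Mod(H)^4
  prof / (2 * sum(prof))
}

# synthesize one band-limited rhythm source: per epoch, a random-phase
# multisine whose one-sided magnitude spectrum is the band profile
# scaled by the epoch envelope, with log-normal per-bin magnitude
# jitter of coefficient of variation bin_cv. Returns the time samples
# (n_spe x n_epochs, column per epoch).
synth_rhythm_epochs <- function(prof, env_ep, bin_cv, n_spe) {
  n_t <- length(env_ep)
  # restrict to bins carrying non-negligible band power; the inverse
  # DFT is then a small dense product instead of a full FFT
  keep <- which(prof >= max(prof) * 1e-8)
  nb <- length(keep)
  mag <- sqrt(prof[keep]) %o% env_ep
  if (bin_cv > 0) {
    sl <- sqrt(log(1 + bin_cv^2))
    jit <- exp(matrix(stats::rnorm(nb * n_t, -sl^2 / 2, sl), nb, n_t))
    mag <- mag * jit
  }
  ph <- matrix(stats::runif(nb * n_t, 0, 2 * pi), nb, n_t)
  # real part of the one-sided inverse DFT, doubled for the conjugate
  # bins: sample variance equals the squared envelope when the profile
  # sums (two-sided) to 1
  B <- exp(outer(0:(n_spe - 1), keep) * (2i * pi / n_spe))
  2 * Re(B %*% (mag * exp(1i * ph)))
}

# expected absolute-power signature of a pattern in E-space after channel
# z-scoring: squared topography (over channel variance) times the
# band power profile on the retained FFT bins (DC carries none).
truth_e_pattern <- function(topo, prof, all_topo, all_m2, noise_sd,
                            n_omega, m2) {
  prof0 <- c(0, prof)[seq_len(n_omega)]
  var_c <- as.vector(all_topo^2 %*% all_m2) + noise_sd^2
  p <- outer(topo^2 * m2 / var_c, prof0)
  p / sqrt(sum(p^2))
}

#' Synthesize stimulus-modulated EEG recordings for one subject
#'
#' Each channel is the topography-weighted sum of the patterns'
#' envelope-modulated band-limited rhythm sources (see [pattern_spec()]
#' for the source model) plus white sensor noise. The
#' recorded ground-truth fluctuation of a pattern is the realized epoch
#' mean-square amplitude of its modulated source (the quantity the epoch
#' power spectra measure in the pattern's band), at TR resolution.
#'
#' @param schedules list of the subject's session schedules
#'   ([generate_stimulus_schedule()]).
#' @param patterns list of [pattern_spec()] objects.
#' @param fs EEG sampling rate in Hz.
#' @param n_channels channel count.
#' @param TR epoch length in seconds (fMRI repetition time).
#' @param n_scans epochs (= scans) per session.
#' @param noise_sd sensor noise standard deviation relative to the
#'   unit-variance sources.
#' @param seed integer seed; sessions use derived child seeds.
#' @param subject_id subject index used for seeding and metadata.
#' @param band_max spectral band upper edge used for the recorded
#'   ground-truth pattern signatures.
#' @return list with `recordings` (one [eeg_recording()] per session),
#'   `fluctuations` (per session `n_t x n_patterns` matrices of realized
#'   epoch power), `envelopes` (per session epoch envelope amplitudes),
#'   `topographies` (channels x patterns), and `truth_patterns`
#'   (unit-norm expected `n_c x n_omega` signatures, absolute power).
#' @export
synthesize_eeg <- function(schedules, patterns, fs = 250, n_channels = 30,
                           TR = 1.66, n_scans = 256, noise_sd = 0.5,
                           seed = 1L, subject_id = 1L, band_max = 40) {
  n_spe <- round(TR * fs)
  n_samples <- n_scans * n_spe
  P <- length(patterns)
  for (p in patterns) {
    if (p$band[1] <= 0 || p$band[2] >= fs / 2) {
      stopf("pattern '%s': band must lie inside (0, fs/2)", p$name)
    }
  }
  # fixed per-subject topographies (shared across sessions)
  set.seed(child_seed(seed, subject_id, 0))
  topo <- sapply(patterns, function(p) {
    if (!is.null(p$topography)) {
      stopifnot(length(p$topography) == n_channels)
      p$topography
    } else {
      v <- stats::rnorm(n_channels)
      v / sqrt(mean(v^2)) # unit RMS amplitude
    }
  })
  topo <- matrix(topo, nrow = n_channels, ncol = P)
  profiles <- lapply(patterns, function(p) {
    band_profile(p$band, fs, n_spe)
  })
  recordings <- vector("list", length(schedules))
  fluctuations <- vector("list", length(schedules))
  envelopes <- vector("list", length(schedules))
  m2 <- numeric(P) # mean squared envelope, for truth signatures
  for (j in seq_along(schedules)) {
    sched <- schedules[[j]]
    set.seed(child_seed(seed, subject_id, j))
    env_ep <- matrix(0, n_scans, P)
    src <- matrix(0, n_samples, P)
    for (k in seq_len(P)) {
      p <- patterns[[k]]
      e <- rep(p$baseline, n_scans)
      for (i in seq_len(nrow(sched))) {
        ep <- floor(sched$onset[i] / TR) + 1
        amp <- p$modulation[[sched$trial_type[i]]] %||% 0
        if (ep <= n_scans) e[ep] <- e[ep] + amp
      }
      if (any(e < 0)) {
        stopf("pattern '%s': modulation drives the envelope negative",
              p$name)
      }
      amp_sd <- p$amp_sd %||% 0
      if (amp_sd > 0) {
        # slow log-normal amplitude modulation (AR(1) at epoch rate)
        phi <- exp(-TR / (p$amp_tau %||% 8))
        z <- numeric(n_scans)
        z[1] <- stats::rnorm(1, sd = amp_sd)
        innov <- stats::rnorm(n_scans - 1, sd = amp_sd * sqrt(1 - phi^2))
        for (tt in seq_len(n_scans - 1)) z[tt + 1] <- phi * z[tt] + innov[tt]
        e <- e * exp(z)
      }
      env_ep[, k] <- e
      src[, k] <- as.vector(synth_rhythm_epochs(profiles[[k]], e,
                                                p$bin_cv %||% 0, n_spe))
    }
    data <- topo %*% t(src) +
      noise_sd * matrix(stats::rnorm(n_channels * n_samples),
                        n_channels, n_samples)
    recordings[[j]] <- eeg_recording(data, fs, subject_id = subject_id,
                                     session_id = j)
    # realized epoch mean-square amplitude of each modulated source
    fluctuations[[j]] <- apply(src, 2, function(v) {
      colMeans(matrix(v^2, n_spe, n_scans))
    })
    colnames(fluctuations[[j]]) <- vapply(patterns, `[[`, "", "name")
    envelopes[[j]] <- env_ep
    m2 <- m2 + colMeans(env_ep^2) / length(schedules)
  }
  n_omega <- floor(band_max * n_spe / fs) + 1
  truth <- lapply(seq_len(P), function(k) {
    truth_e_pattern(topo[, k], profiles[[k]], topo, m2, noise_sd,
                    n_omega, m2[k])
  })
  names(truth) <- vapply(patterns, `[[`, "", "name")
  list(recordings = recordings, fluctuations = fluctuations,
       envelopes = envelopes, topographies = topo, truth_patterns = truth)
}
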