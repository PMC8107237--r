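#' Default ground-truth patterns of the synthetic oddball study
#'
#' Two patterns span the contrast the pipeline is built to detect: a
#' delta-band (1-4 Hz) pattern whose power drops during frequent stimuli
#' (the event-related spectral fingerprint of interest) coupled to one
#' active BOLD block, and an unmodulated alpha-band (8-12 Hz) background
#' rhythm coupled to a disjoint block, serving as the specificity
#' control.
#'
#' @return list of [pattern_spec()] objects.
#' @export
default_patterns <- function() {
  list(
    pattern_spec("delta_task", band = c(1, 4),
                 modulation = c(frequent = -0.3, target = 0,
                                distractor = 0),
                 mask_lo = c(4, 4, 3), mask_hi = c(9, 9, 6)),
    pattern_spec("alpha_background", band = c(8, 12),
                 modulation = c(frequent = 0, target = 0, distractor = 0),
                 mask_lo = c(12, 12, 6), mask_hi = c(17, 17, 9)))
}

# focal channel topography: Gaussian bump over the channel index axis,
# unit RMS amplitude. Scalp rhythms are spatially focal; spacing the
# bumps keeps distinct generators on largely distinct leads.
bump_topography <- function(n_channels, center_frac, width_frac = 0.12) {
  c0 <- center_frac * n_channels
  v <- exp(-0.5 * ((seq_len(n_channels) - c0) / (width_frac *
                                                   n_channels))^2)
  v / sqrt(mean(v^2))
}

#' Study configuration with the printed acquisition constants as defaults
#'
#' Collects every tunable of the synthetic study and the analysis
#' pipeline. Defaults reproduce the reference acquisition (TR 1.66 s,
#' 250 Hz EEG, 0-40 Hz band, four sessions of 256 scans and 84 stimuli at
#' 70/15/15% and 4-6 s ISIs, 30 leads, 50/20 PCA, 20 components, 10
#' stability runs, |t| > 3.25 selection, F > 5.7 at cluster extent 100)
#' on a desk-scale 20 x 20 x 10 voxel grid at 3 mm.
#'
#' @param ... named overrides of any default field.
#' @return an object of class `study_config` (a validated list).
#' @export
study_config <- function(...) {
  cfg <- list(
    subjects = 8L, sessions = 4L, n_scans = 256L,
    events_per_session = 84L,
    proportions = c(frequent = 0.70, target = 0.15, distractor = 0.15),
    isi_choices = c(4, 5, 6), stim_duration = 0.5,
    TR = 1.66, fs = 250, n_channels = 30L, band_max = 40,
    eeg_noise_sd = 0.5,
    patterns = default_patterns(),
    grid_shape = c(20L, 20L, 10L), voxel_size = c(3, 3, 3),
    bold_noise = list(cnr = 1, ar1 = 0.3, drift = 0.5),
    n_pcs_unit = 50L, n_pcs_group = 20L, m = 20L, n_runs = 10L,
    r_min = 0.7, stability_min = 0.8, var_share_min = 1,
    t_crit = 3.25, mean_crit = 2.0, std_crit = 0.5,
    f_crit = 5.7, f_visual = 8.1, f_fwe = 12.1,
    min_extent = 100L, connectivity = 18L,
    hrf_duration = 32, hrf_dt = NULL, # NULL -> TR / 20
    estimator = "ols",
    models = c("ASM", "RSM", "ASSM", "RSSM"),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (is.null(cfg$hrf_dt)) cfg$hrf_dt <- cfg$TR / 20
  thr <- c(cfg$t_crit, cfg$mean_crit, cfg$std_crit, cfg$f_crit,
           cfg$min_extent)
  if (any(thr <= 0)) stopf("all thresholds must be positive")
  if (cfg$TR <= 0 || cfg$fs <= 0) stopf("TR and fs must be positive")
  structure(cfg, class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %d subjects x %d sessions x %d scans, TR %g s, %d ch @ %g Hz, grid %s\n",
    x$subjects, x$sessions, x$n_scans, x$TR, x$n_channels, x$fs,
    paste(x$grid_shape, collapse = "x")))
  invisible(x)
}

# compute absolute- and relative-power spatiospectral matrices of one
# session with a single FFT pass
session_spectra <- function(recording, TR, band_max) {
  # fast path equivalent to epoch_signal() + epoch_powers(): z-score
  # channels, reshape epoch samples contiguously, one FFT pass
  rec <- normalize_channels(recording)
  fs <- rec$fs
  N <- round(TR * fs)
  n_c <- nrow(rec$data)
  n_t <- floor(ncol(rec$data) / N)
  x <- t(rec$data[, seq_len(n_t * N), drop = FALSE]) # samples x channels
  dim(x) <- c(N, n_t * n_c) # column = one epoch of one channel
  pw <- Mod(stats::mvfft(x))^2 / N
  n_omega <- min(floor(band_max * N / fs) + 1, N)
  as_ss <- function(pw_band, mode) {
    E <- aperm(array(pw_band, dim = c(n_omega, n_t, n_c)), c(2, 3, 1))
    dimnames(E) <- list(NULL, rec$channel_labels, NULL)
    structure(list(E = E, freqs = (seq_len(n_omega) - 1) * fs / N,
                   power_mode = mode, TR = TR, fs = fs, n_fft = N,
                   subject_id = rec$subject_id,
                   session_id = rec$session_id),
              class = "ss_matrix")
  }
  band <- pw[seq_len(n_omega), , drop = FALSE]
  tot <- colSums(pw)
  list(absolute = as_ss(band, "absolute"),
       relative = as_ss(sweep(band, 2, tot, "/"), "relative"))
}

# simulate one subject's schedules, EEG and epoch spectra
simulate_subject <- function(config, patterns, subject, seed,
                             keep_recordings = FALSE,
                             compute_spectra = TRUE) {
  schedules <- generate_stimulus_schedule(
    config$sessions, config$events_per_session, config$proportions,
    config$isi_choices, seed = child_seed(seed, 101L, subject),
    stim_duration = config$stim_duration,
    session_duration = config$n_scans * config$TR)
  eeg <- synthesize_eeg(schedules, patterns, fs = config$fs,
                        n_channels = config$n_channels, TR = config$TR,
                        n_scans = config$n_scans,
                        noise_sd = config$eeg_noise_sd,
                        seed = child_seed(seed, 102L),
                        subject_id = subject, band_max = config$band_max)
  E_abs <- E_rel <- list()
  if (compute_spectra) {
    for (j in seq_along(eeg$recordings)) {
      sp <- session_spectra(eeg$recordings[[j]], config$TR,
                            config$band_max)
      id <- unit_id(subject, j)
      E_abs[[id]] <- sp$absolute
      E_rel[[id]] <- sp$relative
    }
  }
  list(schedules = schedules,
       recordings = if (keep_recordings) eeg$recordings,
       E_abs = E_abs, E_rel = E_rel,
       fluctuations = eeg$fluctuations,
       envelopes = eeg$envelopes,
       topographies = eeg$topographies,
       truth_patterns = eeg$truth_patterns)
}

# fix study-level topographies so group patterns are shared across
# subjects: focal bumps spaced over the channel axis by default, or
# seeded random vectors when topography = "random"
fix_topographies <- function(config, seed) {
  set.seed(child_seed(seed, 99L))
  P <- length(config$patterns)
  lapply(seq_len(P), function(k) {
    p <- config$patterns[[k]]
    if (is.null(p$topography)) {
      p$topography <- bump_topography(config$n_channels, (k - 0.5) / P)
    } else if (identical(p$topography, "random")) {
      v <- stats::rnorm(config$n_channels)
      p$topography <- v / sqrt(mean(v^2))
    }
    p
  })
}

#' Simulate a complete synthetic oddball EEG-fMRI study in memory
#'
#' Generates stimulus schedules, EEG recordings (transiently; their epoch
#' power spectra are retained), BOLD volume series and the ground-truth
#' record for `config$subjects` subjects. Channel topographies are drawn
#' once per study so the embedded patterns are group-level, as the group
#' decomposition assumes.
#'
#' @param config a [study_config()] object.
#' @param seed master seed (defaults to `config$seed`); all subjects,
#'   sessions and stages derive child seeds from it.
#' @param with_fmri also synthesize BOLD volumes (default TRUE).
#' @return a `study` list: `config`, per-subject `schedules`, named unit
#'   lists `E_abs` and `E_rel`, `volumes[[subject]][[session]]`, and
#'   `ground_truth` (pattern specs, topographies, expected pattern
#'   signatures, realized fluctuations, BOLD masks/coefficients, noise
#'   parameters, master seed).
#' @export
simulate_study <- function(config = study_config(), seed = config$seed,
                           with_fmri = TRUE) {
  patterns <- fix_topographies(config, seed)
  subs <- lapply(seq_len(config$subjects), function(s) {
    simulate_subject(config, patterns, s, seed)
  })
  ground_truth <- list(
    patterns = patterns,
    topographies = subs[[1]]$topographies,
    truth_patterns = subs[[1]]$truth_patterns,
    fluctuations = lapply(subs, `[[`, "fluctuations"),
    envelopes = lapply(subs, `[[`, "envelopes"),
    bold = sample_bold_ground_truth(patterns, config$grid_shape,
                                    seed = child_seed(seed, 103L)),
    noise = list(eeg_sd = config$eeg_noise_sd,
                 bold = config$bold_noise),
    seed = seed)
  volumes <- NULL
  if (with_fmri) {
    basis <- canonical_basis(dt = config$hrf_dt,
                             duration = config$hrf_duration)
    volumes <- synthesize_fmri(ground_truth, config$grid_shape,
                               config$voxel_size, config$TR, basis,
                               noise = config$bold_noise,
                               seed = child_seed(seed, 104L))
  }
  structure(list(config = config,
                 schedules = lapply(subs, `[[`, "schedules"),
                 E_abs = do.call(c, lapply(subs, `[[`, "E_abs")),
                 E_rel = do.call(c, lapply(subs, `[[`, "E_rel")),
                 volumes = volumes,
                 ground_truth = ground_truth),
            class = "study")
}

#' Write a complete synthetic study to disk
#'
#' Produces, per subject and session, a BIDS-style events TSV, a flat
#' binary EEG container with JSON sidecar, and a 4-D NIfTI BOLD series,
#' plus one study-level ground-truth JSON sidecar and a config echo.
#' Fully reproducible: the same `(config, seed)` yields byte-identical
#' output.
#'
#' @param config a [study_config()] object.
#' @param out_dir output directory (created if needed).
#' @param seed master seed (defaults to `config$seed`).
#' @return invisibly, a character vector of the written file paths.
#' @export
generate_dataset <- function(config = study_config(), out_dir,
                             seed = config$seed) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output path '%s'", out_dir)
  study <- simulate_study(config, seed)
  patterns <- study$ground_truth$patterns
  files <- character(0)
  for (s in seq_len(config$subjects)) {
    sdir <- file.path(out_dir, sprintf("sub-%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    # regenerate this subject's raw EEG (deterministic) for writing
    raw <- simulate_subject(config, patterns, s, seed,
                            keep_recordings = TRUE,
                            compute_spectra = FALSE)
    for (j in seq_len(config$sessions)) {
      ev <- file.path(sdir, sprintf("ses-%d_events.tsv", j))
      write_events_tsv(study$schedules[[s]][[j]], ev)
      pre <- file.path(sdir, sprintf("ses-%d_eeg", j))
      write_eeg_bin(raw$recordings[[j]], pre)
      ni <- file.path(sdir, sprintf("ses-%d_bold.nii.gz", j))
      write_fmri_nifti(study$volumes[[s]][[j]], ni)
      files <- c(files, ev, paste0(pre, ".dat"), paste0(pre, ".json"), ni)
    }
  }
  gt <- study$ground_truth
  side <- list(
    seed = seed,
    patterns = lapply(gt$patterns, function(p) {
      p[c("name", "band", "baseline", "modulation", "topography")]
    }),
    bold = lapply(gt$bold, function(b) {
      if (is.null(b)) NULL else b[c("idx", "b1", "b2", "b3")]
    }),
    noise = gt$noise,
    fluctuations = lapply(gt$fluctuations, function(subj) {
      lapply(subj, function(m) unname(as.data.frame(m)))
    }))
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(side, gt_path, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  cfg <- unclass(config)
  cfg$patterns <- lapply(cfg$patterns, unclass)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(files, gt_path, cfg_path))
}

#' Load a study from a dataset directory written by [generate_dataset()]
#'
#' Reads events, EEG containers and BOLD series, recomputes the epoch
#' power spectra, and attaches the ground-truth sidecar when present.
#'
#' @param dir dataset directory.
#' @param config a [study_config()] describing the acquisition.
#' @return a `study` list as from [simulate_study()].
#' @export
load_study <- function(dir, config = study_config()) {
  schedules <- vector("list", config$subjects)
  volumes <- vector("list", config$subjects)
  E_abs <- E_rel <- list()
  for (s in seq_len(config$subjects)) {
    sdir <- file.path(dir, sprintf("sub-%02d", s))
    schedules[[s]] <- vector("list", config$sessions)
    volumes[[s]] <- vector("list", config$sessions)
    for (j in seq_len(config$sessions)) {
      schedules[[s]][[j]] <- read_events_tsv(
        file.path(sdir, sprintf("ses-%d_events.tsv", j)),
        session_id = j,
        session_duration = config$n_scans * config$TR)
      rec <- read_eeg_bin(file.path(sdir, sprintf("ses-%d_eeg", j)))
      sp <- session_spectra(rec, config$TR, config$band_max)
      id <- unit_id(s, j)
      E_abs[[id]] <- sp$absolute
      E_rel[[id]] <- sp$relative
      volumes[[s]][[j]] <- read_fmri_nifti(
        file.path(sdir, sprintf("ses-%d_bold.nii.gz", j)),
        subject_id = s, session_id = j)
    }
  }
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  }
  structure(list(config = config, schedules = schedules, E_abs = E_abs,
                 E_rel = E_rel, volumes = volumes,
                 ground_truth = ground_truth),
            class = "study")
}
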