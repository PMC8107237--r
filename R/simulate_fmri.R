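#' Construct an fMRI volume series container
#'
#' @param data 4-D numeric array `(x, y, z, scan)`.
#' @param voxel_size voxel edge lengths in mm (length 3, positive).
#' @param TR repetition time in seconds (positive).
#' @param affine optional 4x4 voxel-to-world transform; defaults to a
#'   scaling by `voxel_size` about the origin.
#' @param subject_id,session_id identifiers.
#' @return an object of class `fmri_series`.
#' @export
fmri_series <- function(data, voxel_size, TR, affine = NULL,
                        subject_id = NA, session_id = NA) {
  stopifnot(length(dim(data)) == 4)
  if (TR <= 0) stopf("TR must be positive")
  if (any(voxel_size <= 0)) stopf("voxel_size must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(list(data = data, voxel_size = voxel_size, TR = TR,
                 affine = affine, subject_id = subject_id,
                 session_id = session_id),
            class = "fmri_series")
}

#' @export
print.fmri_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_series> %dx%dx%d voxels x %d scans, TR %g s\n",
              d[1], d[2], d[3], d[4], x$TR))
  invisible(x)
}

# build a logical block mask from two inclusive voxel corners
block_mask <- function(grid_shape, lo, hi) {
  m <- array(FALSE, grid_shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Draw per-voxel BOLD ground-truth coefficients for each pattern
#'
#' Inside each pattern's active mask, the response coefficients
#' `(b1, b2, b3)` on the canonical-plus-derivatives basis are drawn
#' uniformly from the pattern's configured ranges, so active voxels span a
#' range of response shapes (including trough-dominant ones); all voxels
#' outside every mask have zero coefficients.
#'
#' @param patterns list of [pattern_spec()] objects.
#' @param grid_shape voxel grid dimensions (length 3).
#' @param seed integer seed.
#' @return list per pattern: `mask` (logical array), `idx` (voxel linear
#'   indices) and coefficient vectors `b1`, `b2`, `b3` (NULL for EEG-only
#'   patterns).
#' @export
sample_bold_ground_truth <- function(patterns, grid_shape, seed = 1L) {
  set.seed(child_seed(seed, 7L))
  out <- lapply(patterns, function(p) {
    if (is.null(p$mask_lo)) return(NULL)
    if (any(p$mask_hi > grid_shape) || any(p$mask_lo < 1)) {
      stopf("pattern '%s': active mask exceeds the image grid", p$name)
    }
    mask <- block_mask(grid_shape, p$mask_lo, p$mask_hi)
    idx <- which(mask)
    n <- length(idx)
    list(mask = mask, idx = idx,
         b1 = stats::runif(n, p$coef_ranges$b1[1], p$coef_ranges$b1[2]),
         b2 = stats::runif(n, p$coef_ranges$b2[1], p$coef_ranges$b2[2]),
         b3 = stats::runif(n, p$coef_ranges$b3[1], p$coef_ranges$b3[2]))
  })
  names(out) <- vapply(patterns, `[[`, "", "name")
  out
}

#' Synthesize BOLD volume series from ground-truth pattern fluctuations
#'
#' Each active voxel's series is the sum over patterns of
#' `b1 (p * r) + b2 (p * r') + b3 (p * r'')`, where `p` is the pattern's
#' session-standardized ground-truth fluctuation and `r` the canonical
#' response; `*` denotes causal convolution on a fine time grid sampled at
#' scan times. A linear drift and stationary AR(1) Gaussian noise are
#' added. The noise standard deviation is either given directly
#' (`noise$sd`) or derived from the configured contrast-to-noise ratio
#' (`noise$cnr`) as the session's median active-voxel signal SD divided by
#' the CNR.
#'
#' @param ground_truth study ground truth (see [simulate_study()]),
#'   carrying per-subject/session `fluctuations` and per-pattern `bold`
#'   masks and coefficients.
#' @param grid_shape voxel grid dimensions.
#' @param voxel_size voxel edges in mm.
#' @param TR repetition time in seconds.
#' @param hrf_basis an [canonical_basis()] object whose `dt` divides `TR`.
#' @param noise list with elements `cnr` (default 1), `ar1` (lag-one
#'   autocorrelation, default 0.3), `drift` (slope amplitude in noise-SD
#'   units, default 0.5) and optionally `sd` (overrides `cnr`).
#' @param seed integer seed; each subject-session uses a child seed.
#' @return nested list `[[subject]][[session]]` of [fmri_series()] objects.
#' @export
synthesize_fmri <- function(ground_truth, grid_shape,
                            voxel_size = c(3, 3, 3), TR = 1.66,
                            hrf_basis = NULL,
                            noise = list(cnr = 1, ar1 = 0.3, drift = 0.5),
                            seed = 1L) {
  if (is.null(hrf_basis)) hrf_basis <- canonical_basis(dt = TR / 20)
  bold <- ground_truth$bold
  if (is.null(bold)) stopf("ground truth carries no BOLD coefficients")
  for (b in bold) {
    if (!is.null(b) && !all(dim(b$mask) == grid_shape)) {
      stopf("active mask shape does not match the image grid")
    }
  }
  ar1 <- noise$ar1 %||% 0.3
  drift <- noise$drift %||% 0.5
  n_vox <- prod(grid_shape)
  out <- vector("list", length(ground_truth$fluctuations))
  for (s in seq_along(ground_truth$fluctuations)) {
    sess <- ground_truth$fluctuations[[s]]
    out[[s]] <- vector("list", length(sess))
    for (j in seq_along(sess)) {
      fl <- sess[[j]]
      n_scans <- nrow(fl)
      sig <- matrix(0, n_scans, n_vox)
      active <- integer(0)
      for (k in seq_len(ncol(fl))) {
        b <- bold[[colnames(fl)[k]]]
        if (is.null(b)) next
        X <- convolve_with_basis(zscore_n(fl[, k]), hrf_basis, TR, n_scans)
        sig[, b$idx] <- sig[, b$idx] + X %*% rbind(b$b1, b$b2, b$b3)
        active <- union(active, b$idx)
      }
      sd_noise <- noise$sd %||% {
        if (!length(active)) {
          stopf("no active voxels: noise$sd must be given explicitly")
        }
        stats::median(apply(sig[, active, drop = FALSE], 2, stats::sd)) /
          (noise$cnr %||% 1)
      }
      set.seed(child_seed(seed, 11L, s, j))
      if (sd_noise > 0) {
        eps <- matrix(stats::rnorm(n_scans * n_vox,
                                   sd = sd_noise * sqrt(1 - ar1^2)),
                      n_scans, n_vox)
        eps[1, ] <- stats::rnorm(n_vox, sd = sd_noise) # stationary start
        nz <- stats::filter(eps, ar1, method = "recursive")
        ramp <- seq(-0.5, 0.5, length.out = n_scans)
        slopes <- stats::runif(n_vox, -drift, drift) * sd_noise
        sig <- sig + as.matrix(nz) + outer(ramp, slopes)
      }
      out[[s]][[j]] <- fmri_series(array(t(sig),
                                         dim = c(grid_shape, n_scans)),
                                   voxel_size = voxel_size, TR = TR,
                                   subject_id = s, session_id = j)
    }
  }
  out
}
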