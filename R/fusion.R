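# Causal convolution of a TR-resolution fluctuation with the three basis
# functions on the fine dt grid, sampled back at scan onsets. Each epoch
# value is placed as an impulse at its epoch onset, so a unit impulse at
# epoch 0 reproduces the basis function exactly at scan times.
convolve_with_basis <- function(values, basis, TR, n_scans) {
  ratio <- TR / basis$dt
  if (abs(ratio - round(ratio)) > 1e-9) {
    stopf("TR (%g s) must be an integer multiple of the basis dt (%g s)",
          TR, basis$dt)
  }
  ratio <- round(ratio)
  if (length(values) < n_scans) {
    stopf("fluctuation (%d epochs) shorter than n_scans (%d)",
          length(values), n_scans)
  }
  values <- values[seq_len(n_scans)]
  n_fine <- n_scans * ratio
  u <- numeric(n_fine)
  u[(seq_len(n_scans) - 1) * ratio + 1] <- values
  scan_at <- (seq_len(n_scans) - 1) * ratio + 1
  vapply(list(basis$r, basis$dr, basis$ddr), function(k) {
    x <- stats::convolve(u, rev(k), type = "open")[seq_len(n_fine)]
    x[scan_at]
  }, numeric(n_scans))
}

#' Build fusion regressors from a pattern fluctuation
#'
#' The fluctuation is convolved (causally, on the fine `dt` grid of the
#' basis) with the canonical response and its two temporal derivatives and
#' sampled at scan onsets, producing the three regressors of the variable
#' response model. Sessions are processed independently; regressors are
#' mean-centered per session so that the session DC columns carry the
#' intercepts. No orthogonalization is applied among the regressors.
#'
#' @param fluct a [pattern_fluctuation()] object (or numeric vector for a
#'   single session).
#' @param basis an [canonical_basis()] object; `basis$dt` must divide the
#'   TR.
#' @param TR repetition time in seconds.
#' @param n_scans scans per session (fluctuations are truncated to this
#'   length per session).
#' @param center mean-center regressors per session (default TRUE; the
#'   forward simulator uses FALSE).
#' @return an object of class `fusion_regressors`: list with `X`
#'   (`total_scans x 3`, columns x1..x3), session DC indicator matrix
#'   `dc`, per-row `session`, `TR`.
#' @export
build_regressors <- function(fluct, basis, TR, n_scans, center = TRUE) {
  if (is.numeric(fluct)) {
    fluct <- list(values = fluct, session = rep(1L, length(fluct)))
  }
  sessions <- unique(fluct$session)
  Xs <- lapply(sessions, function(j) {
    X <- convolve_with_basis(fluct$values[fluct$session == j], basis, TR,
                             n_scans)
    if (center) X <- sweep(X, 2, colMeans(X))
    X
  })
  X <- do.call(rbind, Xs)
  colnames(X) <- c("x1", "x2", "x3")
  session <- rep(seq_along(sessions), each = n_scans)
  dc <- outer(session, seq_along(sessions), `==`) + 0
  colnames(dc) <- sprintf("dc_s%d", seq_along(sessions))
  structure(list(X = X, dc = dc, session = session, TR = TR,
                 n_scans = n_scans),
            class = "fusion_regressors")
}

#' Fit the voxelwise fusion GLM for one subject
#'
#' Regresses every voxel's concatenated-session BOLD time course on the
#' three basis regressors plus session DC columns. The default estimator
#' is ordinary least squares; `method = "ar1"` applies two-pass AR(1)
#' prewhitening with a pooled lag-one autocorrelation estimated from the
#' OLS residuals.
#'
#' @param volumes list of the subject's session [fmri_series()] objects,
#'   in acquisition order.
#' @param regressors a [build_regressors()] object covering the same
#'   sessions.
#' @param method `"ols"` or `"ar1"`.
#' @param mask optional logical array of in-brain voxels (default: all).
#' @return an object of class `voxel_betas`: list with 3-D coefficient
#'   maps `b1`, `b2`, `b3`, residual variance `sigma2`, `mask`, grid
#'   geometry, the pooled `rho` (AR1 only) and `subject_id`.
#' @export
fit_voxel_glm <- function(volumes, regressors,
                          method = c("ols", "ar1"), mask = NULL) {
  method <- match.arg(method)
  grid_shape <- dim(volumes[[1]]$data)[1:3]
  n_scans <- vapply(volumes, function(v) dim(v$data)[4], 0L)
  if (sum(n_scans) != nrow(regressors$X)) {
    stopf("scan count (%d) does not match regressor rows (%d)",
          sum(n_scans), nrow(regressors$X))
  }
  if (is.null(mask)) mask <- array(TRUE, grid_shape)
  idx <- which(mask)
  Y <- do.call(rbind, lapply(volumes, function(v) {
    t(matrix(v$data, ncol = dim(v$data)[4])[idx, , drop = FALSE])
  }))
  fit <- voxel_glm_fit(Y, regressors, method)
  beta <- fit$beta
  sig2 <- fit$sig2
  rho <- fit$rho
  to_map <- function(v) {
    m <- array(0, grid_shape)
    m[idx] <- v
    m
  }
  structure(list(b1 = to_map(beta[1, ]), b2 = to_map(beta[2, ]),
                 b3 = to_map(beta[3, ]), sigma2 = to_map(sig2),
                 mask = mask, grid_shape = grid_shape,
                 voxel_size = volumes[[1]]$voxel_size,
                 affine = volumes[[1]]$affine, rho = rho,
                 method = method,
                 subject_id = volumes[[1]]$subject_id),
            class = "voxel_betas")
}

# least-squares core on a prebuilt scans x voxels matrix; shared by
# fit_voxel_glm and the pipeline (which caches Y across models)
voxel_glm_fit <- function(Y, regressors, method = "ols") {
  X <- cbind(regressors$X, regressors$dc)
  dec <- qr(X)
  if (dec$rank < ncol(X)) stopf("fusion design matrix is rank deficient")
  beta <- qr.coef(dec, Y)
  res <- Y - X %*% beta
  rho <- NA_real_
  if (method == "ar1") {
    # pooled lag-one autocorrelation within sessions
    ses <- regressors$session
    num <- den <- 0
    for (j in unique(ses)) {
      r <- res[ses == j, , drop = FALSE]
      n <- nrow(r)
      num <- num + sum(r[-1, ] * r[-n, ])
      den <- den + sum(r^2)
    }
    rho <- num / den
    wY <- Y
    wX <- X
    for (j in unique(ses)) {
      rows <- which(ses == j)
      first <- rows[1]
      rest <- rows[-1]
      wY[rest, ] <- Y[rest, ] - rho * Y[rest - 1, ]
      wX[rest, ] <- X[rest, ] - rho * X[rest - 1, ]
      wY[first, ] <- sqrt(1 - rho^2) * Y[first, ]
      wX[first, ] <- sqrt(1 - rho^2) * X[first, ]
    }
    dec <- qr(wX)
    beta <- qr.coef(dec, wY)
    res <- wY - wX %*% beta
  }
  list(beta = beta, sig2 = colSums(res^2) / (nrow(Y) - ncol(X)),
       rho = rho)
}

#' Group F-map over subjects' coefficient maps
#'
#' Per voxel, the `3 s` observations (s subjects x 3 basis regressors)
#' are modeled with three group-indicator columns and F tests the three
#' group means jointly against zero:
#' `F = (model SS / 3) / (residual SS / (3 s - 3))` with degrees of
#' freedom `(3, 3 s - 3)`. Group-mean coefficients are retained for
#' response-shape reconstruction and sign assignment.
#'
#' @param beta_maps list of per-subject [fit_voxel_glm()] results on
#'   aligned grids.
#' @return an object of class `group_fmap`: list with the 3-D `F` map,
#'   `signed_F` (NULL until [sign_f_map()]), `dof`, group-mean coefficient
#'   maps `mean_b1..mean_b3`, grid geometry and subject count `s`.
#' @export
group_f_test <- function(beta_maps) {
  s <- length(beta_maps)
  if (s < 2) stopf("group statistics need at least 2 subjects")
  ref <- beta_maps[[1]]
  for (b in beta_maps) {
    if (!identical(b$grid_shape, ref$grid_shape)) {
      stopf("subject coefficient maps are on misaligned grids")
    }
  }
  n_vox <- prod(ref$grid_shape)
  get <- function(name) {
    vapply(beta_maps, function(b) as.vector(b[[name]]), numeric(n_vox))
  }
  B <- lapply(c("b1", "b2", "b3"), get) # each n_vox x s
  means <- lapply(B, rowMeans)
  rss <- Reduce(`+`, lapply(seq_len(3), function(k) {
    rowSums((B[[k]] - means[[k]])^2)
  }))
  mss <- s * Reduce(`+`, lapply(means, function(m) m^2))
  dof <- c(3, 3 * s - 3)
  F <- (mss / dof[1]) / (rss / dof[2])
  shape <- ref$grid_shape
  structure(list(F = array(F, shape), signed_F = NULL, dof = dof,
                 mean_b1 = array(means[[1]], shape),
                 mean_b2 = array(means[[2]], shape),
                 mean_b3 = array(means[[3]], shape),
                 grid_shape = shape, voxel_size = ref$voxel_size,
                 affine = ref$affine, s = s),
            class = "group_fmap")
}

#' @export
print.group_fmap <- function(x, ...) {
  cat(sprintf("<group_fmap> %s grid, F(%d, %d), max F %.2f%s\n",
              paste(x$grid_shape, collapse = "x"), x$dof[1], x$dof[2],
              max(x$F), if (is.null(x$signed_F)) "" else ", signed"))
  invisible(x)
}

#' Assign response-shape signs to a group F-map
#'
#' Per voxel the group-mean response `h = b1 r + b2 r' + b3 r''` is
#' reconstructed; voxels whose trough amplitude exceeds their peak
#' amplitude (reduced peak, amplified trough) receive a negative sign,
#' all others a positive sign, and `signed_F = sign * F`.
#'
#' @param fmap a [group_f_test()] object.
#' @param basis an [canonical_basis()] object.
#' @return the F-map with `signed_F` and `sign` filled in.
#' @export
sign_f_map <- function(fmap, basis) {
  if (is.null(fmap$mean_b1)) stopf("group-mean coefficients are missing")
  sgn <- hrf_shape_sign(as.vector(fmap$mean_b1),
                        as.vector(fmap$mean_b2),
                        as.vector(fmap$mean_b3), basis)
  fmap$sign <- array(sgn, fmap$grid_shape)
  fmap$signed_F <- fmap$sign * fmap$F
  fmap
}
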