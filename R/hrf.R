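#' Canonical hemodynamic response basis with temporal derivatives
#'
#' The canonical response is the standard double-gamma shape (peak delay
#' 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot ratio 6),
#' sampled on a regular grid and normalized to a unit peak. The first and
#' second temporal derivatives are finite differences on the same grid
#' (central in the interior, one-sided at the ends), giving the
#' three-function basis used to model variable response shapes and
#' latencies voxel by voxel.
#'
#' @param dt grid step in seconds (0 < dt <= 0.5).
#' @param duration support of the response in seconds (>= 24 s; the
#'   undershoot has decayed by 32 s, the default).
#' @return an object of class `hrf_basis`: list with grid `t`, canonical
#'   response `r`, derivatives `dr` and `ddr`, `dt` and `duration`.
#' @export
canonical_basis <- function(dt = 0.1, duration = 32) {
  if (dt <= 0 || dt > 0.5) stopf("dt must lie in (0, 0.5] s")
  if (duration < 24) stopf("duration must be >= 24 s")
  t <- seq(0, duration, by = dt)
  r <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  r <- r / max(r)
  structure(list(t = t, r = r, dr = fd_gradient(r, dt),
                 ddr = fd_gradient(fd_gradient(r, dt), dt),
                 dt = dt, duration = duration),
            class = "hrf_basis")
}

# finite-difference derivative: central interior, one-sided endpoints
fd_gradient <- function(y, dt) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / dt
  d[n] <- (y[n] - y[n - 1]) / dt
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d
}

#' Reconstruct a voxel response shape from basis coefficients
#'
#' The fitted response is the exact linear combination
#' `h = b1 * r + b2 * dr + b3 * ddr` of the canonical response and its two
#' temporal derivatives; peak/trough values and latencies summarize its
#' shape.
#'
#' @param betas numeric length-3 coefficient vector (b1, b2, b3).
#' @param basis an [canonical_basis()] object.
#' @return an object of class `reconstructed_hrf`: list with the sampled
#'   response `h`, `peak`, `trough` and their latencies in seconds.
#' @export
reconstruct_hrf <- function(betas, basis) {
  stopifnot(length(betas) == 3, all(is.finite(betas)))
  h <- betas[1] * basis$r + betas[2] * basis$dr + betas[3] * basis$ddr
  i_max <- which.max(h)
  i_min <- which.min(h)
  structure(list(h = h, t = basis$t,
                 peak = h[i_max], trough = h[i_min],
                 peak_latency = basis$t[i_max],
                 trough_latency = basis$t[i_min],
                 betas = betas),
            class = "reconstructed_hrf")
}

#' @export
print.reconstructed_hrf <- function(x, ...) {
  cat(sprintf(
    "<reconstructed_hrf> peak %.3f @ %.1f s, trough %.3f @ %.1f s\n",
    x$peak, x$peak_latency, x$trough, x$trough_latency))
  invisible(x)
}

# sign convention for F-maps: negative when the response trough dominates
# the peak (reduced peak, amplified trough); vectorized over voxels
hrf_shape_sign <- function(b1, b2, b3, basis) {
  nb <- length(basis$r)
  # H: voxels x time samples of the reconstructed responses
  H <- outer(b1, basis$r) + outer(b2, basis$dr) + outer(b3, basis$ddr)
  hi <- apply(H, 1, max)
  lo <- apply(H, 1, min)
  ifelse(abs(lo) > abs(hi), -1, 1)
}
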