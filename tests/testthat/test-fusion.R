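test_that("the canonical basis has the documented double-gamma shape", {
  b <- canonical_basis(dt = 0.1, duration = 32)
  expect_equal(b$r[1], 0)
  expect_equal(max(b$r), 1)
  expect_lt(abs(b$t[which.max(b$r)] - 5.0), 0.2)
  # single positive peak followed by an undershoot
  expect_lt(min(b$r), 0)
  expect_gt(b$t[which.min(b$r)], b$t[which.max(b$r)])
  # discrete fundamental theorem: dr integrates back to r
  trapz <- sum((b$dr[-1] + b$dr[-length(b$dr)]) / 2) * b$dt
  expect_lt(abs(trapz - (b$r[length(b$r)] - b$r[1])), 1e-3)
  # grid refinement stability at shared points
  fine <- canonical_basis(dt = 0.05, duration = 32)
  expect_lt(max(abs(fine$r[seq(1, length(fine$t), by = 2)] - b$r)), 1e-3)
  expect_error(canonical_basis(dt = 0.6), "dt")
  expect_error(canonical_basis(duration = 10), "duration")
})

test_that("an impulse fluctuation reproduces the basis at scan times", {
  TR <- 1.66
  b <- canonical_basis(dt = TR / 20, duration = 32)
  n <- 15 # all scan times inside the 32 s basis support
  reg <- build_regressors(c(1, rep(0, n - 1)), b, TR, n, center = FALSE)
  scan_grid <- seq(1, by = 20, length.out = n) # t = 0, TR, 2 TR, ...
  expect_equal(unname(reg$X[, "x1"]), b$r[scan_grid], tolerance = 1e-10)
  expect_equal(unname(reg$X[, "x2"]), b$dr[scan_grid], tolerance = 1e-10)
  expect_equal(unname(reg$X[, "x3"]), b$ddr[scan_grid], tolerance = 1e-10)
  # time invariance: shifting the impulse shifts the regressors
  reg3 <- build_regressors(c(0, 0, 0, 1, rep(0, n - 4)), b, TR, n,
                           center = FALSE)
  expect_equal(reg3$X[4:n, "x1"], reg$X[1:(n - 3), "x1"],
               tolerance = 1e-12)
})

test_that("regressors absorb constants and are linear", {
  TR <- 1.66
  b <- canonical_basis(dt = TR / 20, duration = 32)
  # a constant fluctuation gives constant regressors once the causal
  # convolution has ramped past the basis support, so the steady-state
  # segment is absorbed entirely by the session DC after centering
  const <- build_regressors(rep(3, 40), b, TR, 40, center = FALSE)
  steady <- 21:40 # beyond the 32 s basis support
  expect_lt(max(apply(const$X[steady, ], 2, stats::sd)), 1e-10)
  centered <- build_regressors(rep(3, 40), b, TR, 40)
  expect_lt(max(abs(sweep(centered$X[steady, ], 2,
                          colMeans(centered$X[steady, ])))), 1e-10)
  set.seed(5)
  u <- rexp(16)
  v <- rexp(16)
  ru <- build_regressors(u, b, TR, 16)$X
  rv <- build_regressors(v, b, TR, 16)$X
  ruv <- build_regressors(2 * u + 3 * v, b, TR, 16)$X
  expect_lt(max(abs(ruv - 2 * ru - 3 * rv)), 1e-10)
  bad <- canonical_basis(dt = 0.1, duration = 32)
  expect_error(build_regressors(u, bad, TR, 16), "multiple")
})

test_that("the voxel GLM recovers noiseless coefficients", {
  TR <- 1.66
  b <- canonical_basis(dt = TR / 20, duration = 32)
  set.seed(6)
  reg <- build_regressors(rexp(40), b, TR, 40)
  y <- 2 * reg$X[, 1] - 1 * reg$X[, 2] + 5
  vol <- fmri_series(array(rep(y, each = 8), c(2, 2, 2, 40)),
                     c(3, 3, 3), TR)
  fit <- fit_voxel_glm(list(vol), reg)
  expect_lt(max(abs(fit$b1 - 2)), 1e-8)
  expect_lt(max(abs(fit$b2 + 1)), 1e-8)
  expect_lt(max(abs(fit$b3)), 1e-8)
  expect_true(all(fit$sigma2 >= 0))
})

test_that("the voxel GLM matches a hand least-squares solution", {
  # 4 scans, 3 columns (x1..x3 constructed directly)
  reg <- structure(list(X = cbind(x1 = c(0.5, 2, -1, 1),
                                  x2 = c(0, 1, 1, -2),
                                  x3 = c(1, 0, 1, 0.5)),
                        dc = matrix(1, 4, 1,
                                    dimnames = list(NULL, "dc_s1")),
                        session = rep(1L, 4), TR = 1, n_scans = 4L),
                   class = "fusion_regressors")
  y <- c(0.3, 1.4, -0.2, 0.9)
  vol <- fmri_series(array(y, c(1, 1, 1, 4)), c(1, 1, 1), 1)
  fit <- fit_voxel_glm(list(vol), reg)
  oracle <- solve(crossprod(cbind(reg$X, 1)),
                  crossprod(cbind(reg$X, 1), y))
  expect_equal(c(fit$b1, fit$b2, fit$b3), oracle[1:3],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("OLS and AR(1) prewhitening agree on white noise", {
  TR <- 1.66
  b <- canonical_basis(dt = TR / 20, duration = 32)
  set.seed(7)
  reg <- build_regressors(rexp(120), b, TR, 120)
  vol <- fmri_series(array(rnorm(8 * 120), c(2, 2, 2, 120)),
                     c(3, 3, 3), TR)
  ols <- fit_voxel_glm(list(vol), reg, method = "ols")
  ar1 <- fit_voxel_glm(list(vol), reg, method = "ar1")
  se <- sqrt(max(ols$sigma2)) /
    stats::sd(reg$X[, 1]) / sqrt(120)
  expect_lt(max(abs(ols$b1 - ar1$b1)), 2 * se)
  expect_lt(abs(ar1$rho), 0.2)
})

test_that("the group F-map follows the stated one-way ANOVA form", {
  set.seed(8)
  grid <- c(2, 2, 1)
  mk <- function(b) {
    structure(list(b1 = array(b[1], grid), b2 = array(b[2], grid),
                   b3 = array(b[3], grid), sigma2 = array(1, grid),
                   mask = NULL, grid_shape = as.integer(grid),
                   voxel_size = c(3, 3, 3), affine = diag(4),
                   rho = NA, method = "ols", subject_id = 1),
              class = "voxel_betas")
  }
  maps <- list(mk(c(1, 0, -1)), mk(c(2, 1, 0)))
  fm <- group_f_test(maps)
  expect_identical(fm$dof, c(3, 3))
  # closed-form recomputation
  B <- rbind(c(1, 0, -1), c(2, 1, 0))
  mss <- 2 * sum(colMeans(B)^2) / 3
  rss <- sum(sweep(B, 2, colMeans(B))^2) / 3
  expect_equal(fm$F[1, 1, 1], mss / rss, tolerance = 1e-12)
  # scaling one subject changes F exactly as the formula says
  maps2 <- list(mk(c(1, 0, -1) * 3), mk(c(2, 1, 0)))
  B2 <- rbind(3 * c(1, 0, -1), c(2, 1, 0))
  f2 <- (2 * sum(colMeans(B2)^2) / 3) /
    (sum(sweep(B2, 2, colMeans(B2))^2) / 3)
  expect_equal(group_f_test(maps2)$F[1, 1, 1], f2, tolerance = 1e-12)
  expect_error(group_f_test(maps[1]), "2 subjects")
  # s = 21 subjects give denominator dof 60
  maps21 <- lapply(1:21, function(i) mk(rnorm(3)))
  expect_identical(group_f_test(maps21)$dof, c(3, 60))
})

test_that("response reconstruction is an exact basis combination", {
  b <- canonical_basis(dt = 0.1, duration = 32)
  h <- reconstruct_hrf(c(1, 0, 0), b)
  expect_equal(h$h, b$r)
  expect_equal(h$peak, 1)
  neg <- reconstruct_hrf(c(-1, 0, 0), b)
  expect_equal(neg$trough, -1)
  expect_equal(neg$trough_latency, h$peak_latency)
  # first-derivative response crosses zero at the canonical peak
  d <- reconstruct_hrf(c(0, 1, 0), b)
  cross <- b$t[which(diff(sign(d$h[b$t > 1])) < 0)[1] + sum(b$t <= 1)]
  expect_lt(abs(cross - h$peak_latency), 0.1 + 1e-9)
  # refitting h onto the basis leaves zero residual
  fit <- stats::lm.fit(cbind(b$r, b$dr, b$ddr), d$h)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("F-map signs follow the peak/trough dominance rule", {
  b <- canonical_basis(dt = 0.1, duration = 32)
  grid <- c(4, 4, 4)
  triples <- as.matrix(expand.grid(b1 = c(-1, -0.5, 0.5, 1),
                                   b2 = c(-1, 0, 0.5, 1),
                                   b3 = c(-0.5, 0, 0.3, 1)))
  triples <- triples[1:prod(grid), ]
  fm <- structure(list(F = array(1, grid), signed_F = NULL,
                       dof = c(3, 21),
                       mean_b1 = array(triples[, 1], grid),
                       mean_b2 = array(triples[, 2], grid),
                       mean_b3 = array(triples[, 3], grid),
                       grid_shape = as.integer(grid),
                       voxel_size = c(3, 3, 3), affine = diag(4), s = 8),
                  class = "group_fmap")
  signed <- sign_f_map(fm, b)
  for (i in seq_len(nrow(triples))) {
    h <- reconstruct_hrf(triples[i, ], b)
    want <- if (abs(h$trough) > abs(h$peak)) -1 else 1
    expect_identical(as.vector(signed$sign)[i], want)
  }
  expect_equal(abs(signed$signed_F), signed$F)
})
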