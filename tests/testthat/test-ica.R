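# construct a reduction object directly from group-reduced data, for
# tests that exercise the ICA core without a full study
fake_reduction <- function(G, pattern_dim = c(1, ncol(G))) {
  structure(list(G = G, V = diag(nrow(G)),
                 units = list(list(id = "u1", U = diag(nrow(G)),
                                   mu = rep(0, ncol(G)),
                                   n_t = nrow(G))),
                 unit_ids = "u1", d1 = nrow(G), d2 = nrow(G),
                 group_eigvals = rep(1, nrow(G)),
                 pattern_dim = pattern_dim,
                 freqs = seq_len(pattern_dim[2]) - 1,
                 power_mode = "absolute", TR = 1.66),
            class = "ss_reduction")
}

# sparse non-negative source rows (super-Gaussian over features)
sparse_sources <- function(m, p, seed) {
  set.seed(seed)
  S <- matrix(0, m, p)
  for (k in seq_len(m)) {
    on <- sample(p, 25)
    S[k, on] <- rexp(25) + 0.5
  }
  S
}

test_that("two-stage reduction has the configured shape and bases", {
  st <- tiny_study()
  red <- stack_and_reduce(st$E_abs, 20, 6)
  expect_identical(dim(red$G), c(6L, as.integer(10 * 67)))
  expect_identical(nrow(red$V), 20L * length(st$E_abs))
  expect_error(stack_and_reduce(st$E_abs, 20, 1000), "exceeds")
  expect_error(stack_and_reduce(c(st$E_abs[1], st$E_rel[1]), 10, 2),
               "power mode")
})

test_that("explained variance is non-increasing across components", {
  st <- tiny_study()
  red <- stack_and_reduce(st$E_abs, 20, 6)
  expect_true(all(diff(red$group_eigvals) <= 1e-8))
  for (u in red$units) expect_true(all(diff(u$eigvals) <= 1e-8))
})

test_that("a complete basis reconstructs unit data exactly", {
  st <- tiny_study()
  one <- st$E_abs[1]
  n_t <- dim(one[[1]]$E)[1]
  red <- suppressWarnings(stack_and_reduce(one, n_t, 4))
  dec <- infomax_ica(red, m = 4, n_runs = 2, seed = 3)
  X <- specfuse:::flatten_ss(one[[1]])
  # rank-4 model of a full-rank unit: reconstruction matches the
  # centered data's best rank-4 approximation plus the mean
  W <- back_reconstruct(dec, names(one))
  expect_identical(dim(W), c(n_t, 4L))
  # with m = d2 the ICA factorization is exact within the retained space
  Xc <- sweep(X, 2, colMeans(X))
  G <- red$G
  expect_lt(max(abs(dec$A %*% dec$S - G)), 1e-8)
})

test_that("a low-rank mixture concentrates group variance in its rank", {
  set.seed(7)
  S <- sparse_sources(3, 400, 7)
  units <- lapply(1:2, function(i) {
    W <- matrix(rexp(40 * 3), 40, 3)
    make_ss(array(W %*% S, dim = c(40, 1, 400)))
  })
  names(units) <- c("u1", "u2")
  red <- stack_and_reduce(units, 10, 3)
  ev <- red$group_eigvals
  expect_gte(sum(ev[1:3]) / sum(pmax(ev, 0)), 0.99)
})

test_that("Infomax recovers known super-Gaussian sources", {
  S <- sparse_sources(5, 1500, 21)
  set.seed(22)
  A <- matrix(rnorm(25), 5, 5)
  dec <- infomax_ica(fake_reduction(A %*% S, c(1, 1500)), m = 5,
                     n_runs = 5, seed = 2)
  C <- abs(stats::cor(t(dec$S), t(S)))
  best <- apply(C, 2, which.max)
  expect_gt(min(apply(C, 2, max)), 0.95)
  expect_identical(length(unique(best)), 5L)
  # unit-norm rows with positive dominant element
  expect_equal(unname(rowSums(dec$S^2)), rep(1, 5), tolerance = 1e-10)
  for (k in 1:5) {
    v <- dec$S[k, ]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("recovered sources are invariant to source rescaling", {
  S <- sparse_sources(4, 1200, 31)
  set.seed(32)
  A <- matrix(rnorm(16), 4, 4)
  d1 <- infomax_ica(fake_reduction(A %*% S, c(1, 1200)), m = 4,
                    n_runs = 3, seed = 5)
  d2 <- infomax_ica(fake_reduction((A %*% diag(c(3, 0.2, 1, 10))) %*% S,
                                   c(1, 1200)),
                    m = 4, n_runs = 3, seed = 5)
  C <- abs(stats::cor(t(d1$S), t(d2$S)))
  expect_gt(min(apply(C, 1, max)), 0.999)
})

test_that("stability runs behave and the same seed reproduces", {
  S <- sparse_sources(3, 800, 41)
  set.seed(42)
  G <- matrix(rnorm(9), 3, 3) %*% S
  one <- infomax_ica(fake_reduction(G, c(1, 800)), m = 3, n_runs = 1,
                     seed = 9)
  expect_equal(one$stability_index, rep(1, 3))
  a <- infomax_ica(fake_reduction(G, c(1, 800)), m = 3, n_runs = 4,
                   seed = 9)
  b <- infomax_ica(fake_reduction(G, c(1, 800)), m = 3, n_runs = 4,
                   seed = 9)
  expect_equal(a$S, b$S, tolerance = 1e-8)
  expect_true(all(a$stability_index >= 0 & a$stability_index <= 1))
})

test_that("Infomax agrees with an exhaustive rotation search", {
  set.seed(55)
  p <- 100
  S <- rbind(rexp(p) * sign(rnorm(p)), rexp(p) * sign(rnorm(p)))
  X <- matrix(rnorm(4), 2, 2) %*% S
  # whiten
  eg <- eigen(tcrossprod(X) / p, symmetric = TRUE)
  Xw <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% X
  fit <- specfuse:::infomax_core(Xw, diag(2))
  ang_im <- atan2(fit$W[1, 2], fit$W[1, 1]) %% (pi / 2)
  # oracle: rotation maximizing summed absolute excess kurtosis
  kurt <- function(v) mean((v - mean(v))^4) / stats::var(v)^2 - 3
  angs <- seq(0, pi / 2, by = pi / 720)
  obj <- vapply(angs, function(a) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    sum(abs(apply(R %*% Xw, 1, kurt)))
  }, 0)
  ang_or <- angs[which.max(obj)]
  d <- abs(ang_im - ang_or) %% (pi / 2)
  d <- min(d, pi / 2 - d) * 180 / pi
  expect_lt(d, 5)
})

test_that("back-reconstruction is unit-independent and validated", {
  st <- tiny_study()
  red <- stack_and_reduce(st$E_abs, 30, 6)
  dec <- infomax_ica(red, m = 6, n_runs = 2, seed = 7)
  expect_error(back_reconstruct(dec, "nope"), "unknown")
  # permuting unit order leaves each unit's dynamics unchanged
  red2 <- stack_and_reduce(rev(st$E_abs), 30, 6)
  dec2 <- infomax_ica(red2, m = 6, n_runs = 2, seed = 7)
  W1 <- back_reconstruct(dec, "sub01_ses1")
  W2 <- back_reconstruct(dec2, "sub01_ses1")
  # decompositions may differ in component order/sign; match columns
  C <- stats::cor(W1, W2)
  expect_gt(min(apply(abs(C), 1, max)), 0.999)
})

test_that("back-reconstructed dynamics track the ground truth", {
  st <- tiny_study()
  red <- stack_and_reduce(st$E_abs, 30, 6)
  dec <- infomax_ica(red, m = 6, n_runs = 3, seed = 8)
  fl <- st$ground_truth$fluctuations[[1]][[1]]
  W <- back_reconstruct(dec, "sub01_ses1")
  C <- abs(stats::cor(W, fl))
  expect_gt(max(C[, "delta_task"]), 0.9)
  expect_gt(max(C[, "alpha_bg"]), 0.9)
})

test_that("cross-mode matching flags identity and rejects noise", {
  st <- tiny_study()
  red <- stack_and_reduce(st$E_abs, 30, 6)
  dec <- infomax_ica(red, m = 6, n_runs = 2, seed = 12)
  self <- match_across_power_modes(dec, dec, r_min = 0.7,
                                   stability_min = 0, var_share_min = 0)
  expect_true(all(abs(self$match_r) > 0.999999))
  expect_true(all(self$stable))
  # random unit-norm patterns: no cross-mode matches at r_min = 0.7
  set.seed(13)
  mk <- function() {
    d <- dec
    S <- matrix(rnorm(6 * ncol(dec$S)), 6)
    d$S <- S / sqrt(rowSums(S^2))
    d
  }
  null <- match_across_power_modes(mk(), mk(), r_min = 0.7,
                                   stability_min = 0, var_share_min = 0)
  expect_identical(sum(null$stable), 0L)
})

test_that("lead averaging collapses patterns to spectral filters", {
  m <- matrix(2.5, nrow = 4, ncol = 6)
  expect_equal(average_over_leads(m), rep(2.5, 6))
  one <- matrix(seq(0.1, 0.6, by = 0.1), nrow = 1)
  expect_equal(average_over_leads(one), as.vector(one))
  pm <- rbind(c(1, -2, 3), c(-1, 2, -3))
  expect_equal(average_over_leads(pm), c(0, 0, 0))
})
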