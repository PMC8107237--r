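two_session_schedules <- function() {
  generate_stimulus_schedule(2, 20, seed = 17, session_duration = 100)
}

test_that("a four-session three-type design has 16 labelled columns", {
  sch <- generate_stimulus_schedule(4, 84, seed = 1,
                                    session_duration = 256 * 1.66)
  des <- build_task_design(sch, TR = 1.66, n_epochs = 256)
  expect_identical(des$q, 16L)
  expect_identical(ncol(des$X), 16L)
  expect_identical(nrow(des$X), 4L * 256L)
  # stimulus columns binary, DC columns partition the rows
  expect_true(all(des$X[, 1:12] %in% c(0, 1)))
  expect_equal(rowSums(des$X[, 13:16]), rep(1, 1024))
  expect_identical(sum(des$X[, 1:12]), 336)
})

test_that("onsets use the half-open epoch convention", {
  sch <- list(structure(data.frame(onset = c(0, 3.32), duration = 0.5,
                                   trial_type = c("frequent", "target"),
                                   stringsAsFactors = FALSE),
                        session_id = 1, session_duration = 16.6,
                        class = c("stim_schedule", "data.frame")))
  des <- build_task_design(sch, TR = 1.66)
  expect_equal(unname(des$X[1, "frequent_s1"]), 1) # onset 0 -> epoch 1
  expect_equal(unname(des$X[3, "target_s1"]), 1)   # onset 2 TR -> epoch 3
  bad <- sch
  bad[[1]]$onset[2] <- 50
  expect_error(build_task_design(bad, TR = 1.66), "beyond")
})

test_that("empty schedules yield zero stimulus columns, intact DC", {
  empty <- list(structure(data.frame(onset = numeric(0),
                                     duration = numeric(0),
                                     trial_type = character(0),
                                     stringsAsFactors = FALSE),
                          session_id = 1, session_duration = 33.2,
                          class = c("stim_schedule", "data.frame")))
  des <- build_task_design(empty, TR = 1.66,
                           types = c("frequent", "target"))
  expect_identical(sum(des$X[, 1:2]), 0)
  expect_equal(des$X[, "dc_s1"], rep(1, 20))
})

test_that("the pattern GLM matches the normal-equation oracle", {
  sch <- two_session_schedules()
  des <- build_task_design(sch, TR = 1.66, n_epochs = 64)
  set.seed(3)
  truth <- matrix(rnorm(des$q * 2), des$q, 2)
  U <- des$X %*% truth
  expect_equal(fit_pattern_glm(U, des), truth, tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthogonal-residual input maps to zero coefficients
  resid <- stats::residuals(stats::lm(rnorm(nrow(des$X)) ~ des$X - 1))
  expect_lt(max(abs(fit_pattern_glm(cbind(resid), des))), 1e-8)
  # small system against explicit normal equations
  set.seed(4)
  Xs <- cbind(1, rnorm(6))
  Us <- cbind(rnorm(6), rnorm(6))
  oracle <- solve(t(Xs) %*% Xs) %*% t(Xs) %*% Us
  expect_equal(unname(fit_pattern_glm(Us, Xs)), oracle,
               tolerance = 1e-10)
  expect_error(fit_pattern_glm(Us, cbind(Xs, Xs[, 1] + Xs[, 2])),
               "rank deficient")
})

test_that("the group t-statistic is sqrt(s) mean over sample sd", {
  betas <- lapply(c(2, 4, 6), function(v) matrix(v, 1, 1))
  out <- group_ttest(betas, 1)
  expect_equal(out$t, sqrt(3) * 4 / 2, tolerance = 1e-12)
  sym <- group_ttest(lapply(c(1, -1), function(v) matrix(v, 1, 1)), 1)
  expect_equal(sym$t, 0)
  near <- group_ttest(lapply(c(1, 1, 1 + 1e-9),
                             function(v) matrix(v, 1, 1)), 1)
  expect_true(is.finite(near$t) && abs(near$t) > 1e6)
  expect_error(group_ttest(lapply(c(1, 1), function(v) matrix(v, 1, 1)),
                           1), "variance")
  expect_error(group_ttest(list(matrix(1, 1, 1)), 1), "2 subjects")
})

test_that("t is invariant to a common positive rescaling of betas", {
  set.seed(9)
  vals <- rnorm(6, mean = 1)
  t1 <- group_ttest(lapply(vals, function(v) matrix(v, 1, 1)), 1)$t
  t2 <- group_ttest(lapply(7.3 * vals, function(v) matrix(v, 1, 1)), 1)$t
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("the Bonferroni t threshold reproduces the printed 3.25", {
  expect_equal(round(critical_t(0.05, 10, 16), 2), 3.25)
  expect_equal(round(critical_t(0.05, 1, 16), 2), 2.12)
  expect_equal(critical_t(0.05, 1, 1e7), stats::qnorm(0.975),
               tolerance = 1e-3)
  expect_error(critical_t(1.2, 10, 16), "alpha")
})

test_that("selection reproduces the published example rows", {
  mk <- function(...) {
    v <- c(...)
    lapply(seq_along(v), function(i) matrix(v[i], 1, 1,
                                            dimnames = list("p", "freq")))
  }
  tabs <- function(v) {
    out <- lapply(v, function(x) matrix(x, 1, 1,
                                        dimnames = list("p", "frequent")))
    names(out) <- c("ASM", "RSM", "ASSM", "RSSM")
    out
  }
  # high-delta frequent row: mean -3.64, flagged by the primary rule
  hi <- select_task_related(tabs(c(-3.44, -4.70, -2.09, -4.32)))
  expect_equal(hi$mean_t, -3.64, tolerance = 0.005)
  expect_true(hi$selected_fwe)
  expect_identical(hi$direction, -1)
  # narrow-theta target row: mean 2.05, SD 0.33, secondary rule only
  th <- select_task_related(tabs(c(2.18, 1.49, 2.37, 2.17)))
  expect_equal(th$mean_t, 2.05, tolerance = 0.005)
  expect_equal(th$sd_t, 0.33, tolerance = 0.02)
  expect_false(th$selected_fwe)
  expect_true(th$candidate && th$selected)
  # all-zero row is never selected
  z <- select_task_related(tabs(c(0, 0, 0, 0)))
  expect_false(z$selected)
})

test_that("the family-wise rule is monotone in |t|", {
  set.seed(21)
  for (i in 1:50) {
    v <- rnorm(4, sd = 2)
    tabs <- lapply(v, function(x) matrix(x, 1, 1))
    names(tabs) <- c("a", "b", "c", "d")
    base <- select_task_related(tabs)
    j <- sample(4, 1)
    tabs[[j]][1, 1] <- tabs[[j]][1, 1] * 2
    raised <- select_task_related(tabs)
    if (base$selected_fwe) expect_true(raised$selected_fwe)
  }
})

test_that("misaligned t tables are rejected", {
  a <- matrix(0, 2, 3, dimnames = list(c("p1", "p2"), c("f", "t", "d")))
  b <- matrix(0, 3, 3)
  expect_error(select_task_related(list(A = a, B = b)), "misaligned")
})

test_that("spectral filtering applies g, z-scores, and averages", {
  set.seed(31)
  E <- array(rexp(20 * 3 * 5), dim = c(20, 3, 5))
  ss <- make_ss(E)
  g <- c(0, 0, 1, 0, 0)
  # delta filter picks out bin 3; oracle by explicit loops
  P <- sapply(1:3, function(c) E[, c, 3])
  Z <- apply(P, 2, function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  expect_equal(spectral_filter(ss, g), rowMeans(Z), tolerance = 1e-12)
  expect_error(spectral_filter(ss, c(1, 2)), "match")
  flat <- make_ss(array(1, dim = c(4, 2, 3)))
  expect_error(spectral_filter(flat, c(1, 0, 0)), "constant")
})

test_that("fluctuation assembly respects model/power-mode contracts", {
  st <- tiny_study()
  red <- stack_and_reduce(st$E_abs, 30, 6)
  dec <- infomax_ica(red, m = 6, n_runs = 2, seed = 5)
  g <- average_over_leads(pattern_matrix(dec, 1))
  units <- c("sub01_ses1", "sub01_ses2")
  fl <- pattern_fluctuation("ASM", E_list = st$E_abs[units], g = g)
  expect_length(fl$values, 2 * 128)
  expect_true(all(is.finite(fl$values)))
  expect_identical(fl$session, rep(1:2, each = 128))
  # relative spectra are refused under an absolute-power model
  expect_error(pattern_fluctuation("ASM", E_list = st$E_rel[units],
                                   g = g), "absolute")
  expect_error(pattern_fluctuation("RSSM", decomposition = dec,
                                   pattern_index = 1, unit_ids = units),
               "relative")
  # session order permutes blockwise
  fl2 <- pattern_fluctuation("ASM", E_list = st$E_abs[rev(units)], g = g)
  expect_equal(fl2$values, c(fl$values[129:256], fl$values[1:128]),
               tolerance = 1e-12)
  # spatiospectral dynamics concatenate back-reconstructed columns
  fs <- pattern_fluctuation("ASSM", decomposition = dec,
                            pattern_index = 2, unit_ids = units)
  W <- back_reconstruct(dec, "sub01_ses1")
  expect_equal(fs$values[1:128], unname(W[, 2]), tolerance = 1e-12)
})
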