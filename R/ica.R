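#' Two-stage PCA reduction of stacked spatiospectral matrices
#'
#' Each subject-session unit's epochs-by-features matrix (features =
#' flattened channel x frequency bins) is reduced along time to
#' `n_pcs_unit` components by an uncentered temporal PCA; the reduced
#' matrices are concatenated across units and reduced again to
#' `n_pcs_group` components. Both orthonormal bases are retained so that
#' per-unit pattern dynamics can be back-reconstructed after ICA. When a
#' unit has fewer epochs than `n_pcs_unit` the unit reduction is truncated
#' with a warning.
#'
#' @param matrices named list of [compute_power()] matrices, one per
#'   subject-session unit, all sharing channel/bin geometry and power
#'   mode. Names are used as unit ids (conventionally `subNN_sesJ`).
#' @param n_pcs_unit temporal components kept per unit (default 50).
#' @param n_pcs_group group components kept after concatenation
#'   (default 20).
#' @return an object of class `ss_reduction` carrying the group-reduced
#'   data `G` (`n_pcs_group x n_features`), the group basis `V`, per-unit
#'   bases, eigenvalue spectra and geometry metadata.
#' @export
stack_and_reduce <- function(matrices, n_pcs_unit = 50, n_pcs_group = 20) {
  stopifnot(length(matrices) >= 1)
  ref <- matrices[[1]]
  for (ssm in matrices) {
    if (!identical(dim(ssm$E)[2:3], dim(ref$E)[2:3]) ||
        !identical(ssm$power_mode, ref$power_mode)) {
      stopf("all spatiospectral matrices must share shape and power mode")
    }
  }
  ids <- names(matrices) %||% sprintf("unit%02d", seq_along(matrices))
  d1 <- min(n_pcs_unit, min(vapply(matrices, function(m) dim(m$E)[1], 0L)))
  if (d1 < n_pcs_unit) {
    warning(sprintf(
      "n_pcs_unit truncated from %d to %d (fewest epochs in a unit)",
      n_pcs_unit, d1))
  }
  units <- vector("list", length(matrices))
  Fs <- vector("list", length(matrices))
  for (i in seq_along(matrices)) {
    X <- flatten_ss(matrices[[i]])
    mu <- colMeans(X) # feature means over time, kept for reconstruction
    X <- sweep(X, 2, mu)
    eg <- eigen(tcrossprod(X), symmetric = TRUE)
    U <- eg$vectors[, seq_len(d1), drop = FALSE]
    units[[i]] <- list(id = ids[i], U = U, mu = mu, n_t = nrow(X),
                       eigvals = eg$values)
    Fs[[i]] <- crossprod(U, X)
  }
  Fmat <- do.call(rbind, Fs)
  if (n_pcs_group > nrow(Fmat)) {
    stopf("n_pcs_group (%d) exceeds stacked unit components (%d)",
          n_pcs_group, nrow(Fmat))
  }
  eg <- eigen(tcrossprod(Fmat), symmetric = TRUE)
  V <- eg$vectors[, seq_len(n_pcs_group), drop = FALSE]
  structure(list(G = crossprod(V, Fmat), V = V, units = units,
                 unit_ids = ids, d1 = d1, d2 = n_pcs_group,
                 group_eigvals = eg$values,
                 pattern_dim = dim(ref$E)[2:3], freqs = ref$freqs,
                 power_mode = ref$power_mode, TR = ref$TR),
            class = "ss_reduction")
}

# full-batch natural-gradient Infomax with logistic nonlinearity;
# X is whitened (m x samples), W0 the initial square unmixing matrix.
# The learning rate anneals only when successive updates oscillate
# (direction change beyond 60 degrees); convergence requires both a tiny
# relative weight change and a small natural-gradient norm, so a
# shrinking step cannot masquerade as a fixed point. On numerical
# blow-up the run restarts from W0 with a halved rate.
infomax_core <- function(X, W0, lrate = 0.2, max_iter = 5000,
                         tol = 1e-6, grad_tol = 1e-3,
                         max_restarts = 12) {
  m <- nrow(X)
  p <- ncol(X)
  I <- diag(m)
  for (restart in seq_len(max_restarts)) {
    W <- W0
    lr <- lrate / 2^(restart - 1)
    dW_old <- NULL
    ok <- TRUE
    delta <- Inf
    for (it in seq_len(max_iter)) {
      U <- W %*% X
      Y2 <- 2 / (1 + exp(-U)) # 2 * logistic(u)
      Gd <- I + tcrossprod(1 - Y2, U) / p
      dW <- Gd %*% W
      if (!is.null(dW_old)) {
        cosang <- sum(dW * dW_old) /
          sqrt(sum(dW^2) * sum(dW_old^2))
        if (is.finite(cosang) && cosang < 0.5) lr <- lr * 0.9
      }
      W <- W + lr * dW
      dW_old <- dW
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        ok <- FALSE
        break
      }
      delta <- lr * sqrt(sum(dW^2) / sum(W^2))
      if (delta < tol && sqrt(sum(Gd^2)) / m < grad_tol) {
        return(list(W = W, converged = TRUE, iterations = it,
                    delta = delta))
      }
    }
    if (ok) {
      return(list(W = W, converged = FALSE, iterations = max_iter,
                  delta = delta))
    }
  }
  list(W = W0, converged = FALSE, iterations = 0, delta = Inf)
}

# greedy one-to-one assignment maximizing |correlation| between the rows
# of two source matrices; returns an index vector into rows of S2
greedy_match <- function(S1, S2) {
  C <- abs(stats::cor(t(S1), t(S2)))
  C[!is.finite(C)] <- 0
  n <- nrow(C)
  assign <- integer(n)
  free_r <- rep(TRUE, n)
  free_c <- rep(TRUE, ncol(C))
  for (step in seq_len(min(n, ncol(C)))) {
    M <- C
    M[!free_r, ] <- -1
    M[, !free_c] <- -1
    ij <- arrayInd(which.max(M), dim(M))
    assign[ij[1]] <- ij[2]
    free_r[ij[1]] <- FALSE
    free_c[ij[2]] <- FALSE
  }
  assign
}

#' Infomax group ICA with stability runs
#'
#' The group-reduced data are whitened and unmixed by full-batch
#' natural-gradient Infomax (logistic nonlinearity, annealed learning
#' rate) from `n_runs` seeded random orthonormal initializations.
#' Components are matched across runs greedily by absolute correlation of
#' their source rows; each cluster is represented by its centrotype (the
#' member with the highest mean similarity to the rest), and the cluster's
#' mean pairwise absolute correlation is reported as its stability index.
#' Source rows are normalized to unit Euclidean norm with the
#' maximum-absolute element positive; the mixing matrix absorbs the
#' rescaling, so `G ~ A S` is preserved.
#'
#' @param reduction an [stack_and_reduce()] object.
#' @param m number of components; must equal the group PCA dimension.
#' @param n_runs number of stability runs (default 10).
#' @param seed integer seed controlling every run's initialization.
#' @param max_iter,tol,lrate Infomax iteration controls.
#' @return an object of class `ss_decomposition` with the source matrix
#'   `S` (`m x n_features`), mixing `A` (`G ~ A S`), per-component
#'   `stability_index`, the retained reduction bases, and geometry
#'   metadata.
#' @export
infomax_ica <- function(reduction, m = reduction$d2, n_runs = 10,
                        seed = 1L, max_iter = 5000, tol = 1e-6,
                        lrate = 0.2) {
  if (m != reduction$d2) {
    stopf("m (%d) must equal the group PCA dimension (%d)", m,
          reduction$d2)
  }
  if (n_runs < 1) stopf("n_runs must be >= 1")
  G <- reduction$G
  p <- ncol(G)
  eg <- eigen(tcrossprod(G) / p, symmetric = TRUE)
  if (min(eg$values) <= 0) {
    stopf("group-reduced data are rank deficient; reduce n_pcs_group")
  }
  K <- diag(1 / sqrt(eg$values), m) %*% t(eg$vectors)
  Xw <- K %*% G
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(child_seed(seed, 23L, r))
    W0 <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
    fit <- infomax_core(Xw, W0, lrate = lrate, max_iter = max_iter,
                        tol = tol)
    runs[[r]] <- c(fit, list(S = fit$W %*% Xw))
  }
  conv <- vapply(runs, `[[`, TRUE, "converged")
  if (!any(conv)) {
    stopf("Infomax failed to converge in all %d runs (final deltas: %s)",
          n_runs, paste(sprintf("%.2e", vapply(runs, `[[`, 0, "delta")),
                        collapse = ", "))
  }
  # cluster components across runs against the first run
  S_ref <- runs[[1]]$S
  members <- lapply(seq_len(m), function(k) S_ref[k, , drop = FALSE])
  for (r in seq_len(n_runs)[-1]) {
    idx <- greedy_match(S_ref, runs[[r]]$S)
    for (k in seq_len(m)) {
      members[[k]] <- rbind(members[[k]], runs[[r]]$S[idx[k], ])
    }
  }
  S <- matrix(0, m, p)
  stability <- numeric(m)
  for (k in seq_len(m)) {
    M <- members[[k]]
    if (nrow(M) == 1) {
      S[k, ] <- M[1, ]
      stability[k] <- 1
      next
    }
    C <- abs(stats::cor(t(M)))
    S[k, ] <- M[which.max(rowMeans(C)), ]
    stability[k] <- mean(C[upper.tri(C)])
  }
  # mixing in group-reduced space, then unit-norm + sign convention
  A <- tcrossprod(G, S) %*% solve(tcrossprod(S))
  nrm <- sqrt(rowSums(S^2))
  sgn <- vapply(seq_len(m), function(k) {
    v <- S[k, ]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  S <- S * (sgn / nrm)
  A <- A %*% diag(nrm * sgn, m)
  # share of the retained (group-reduced) variance carried per component
  var_share <- colSums(A^2) / sum(colSums(A^2))
  structure(list(S = S, A = A, var_share = var_share,
                 V = reduction$V, units = reduction$units,
                 unit_ids = reduction$unit_ids, d1 = reduction$d1,
                 m = m, stability_index = stability,
                 pattern_dim = reduction$pattern_dim,
                 freqs = reduction$freqs,
                 power_mode = reduction$power_mode, TR = reduction$TR,
                 n_runs = n_runs, converged_runs = sum(conv),
                 seed = seed),
            class = "ss_decomposition")
}

#' @export
print.ss_decomposition <- function(x, ...) {
  cat(sprintf(
    "<ss_decomposition> %d %s-power patterns over %d channels x %d bins; %d/%d runs converged; median stability %.2f\n",
    x$m, x$power_mode, x$pattern_dim[1], x$pattern_dim[2],
    x$converged_runs, x$n_runs, stats::median(x$stability_index)))
  invisible(x)
}

#' Back-reconstruct a unit's pattern dynamics
#'
#' Multiplies the unit's partition of the temporal PCA basis by its
#' partition of the aggregate (group) reduction basis and the group
#' mixing, yielding the per-epoch mixing weights of every group pattern
#' for that subject-session.
#'
#' @param decomposition an [infomax_ica()] object.
#' @param unit_id one of the unit ids used in [stack_and_reduce()].
#' @return numeric matrix `n_t x m` of pattern dynamics.
#' @export
back_reconstruct <- function(decomposition, unit_id) {
  i <- match(unit_id, decomposition$unit_ids)
  if (is.na(i)) stopf("unknown unit '%s'", unit_id)
  d1 <- decomposition$d1
  rows <- ((i - 1) * d1 + 1):(i * d1)
  W <- decomposition$units[[i]]$U %*%
    decomposition$V[rows, , drop = FALSE] %*% decomposition$A
  colnames(W) <- sprintf("ic%02d", seq_len(decomposition$m))
  W
}

#' Reconstruct a unit's spatiospectral data from the decomposition
#'
#' Returns `W S` plus the unit's feature means (the temporal PCA is
#' centered over time), i.e. the decomposition's model of the unit's
#' epochs-by-features matrix. With a complete unit basis and `m` equal
#' to the true rank the reconstruction is exact.
#'
#' @param decomposition an [infomax_ica()] object.
#' @param unit_id unit id.
#' @return numeric matrix `n_t x (n_c * n_omega)`.
#' @export
reconstruct_unit <- function(decomposition, unit_id) {
  i <- match(unit_id, decomposition$unit_ids)
  if (is.na(i)) stopf("unknown unit '%s'", unit_id)
  W <- back_reconstruct(decomposition, unit_id)
  sweep(W %*% decomposition$S, 2, decomposition$units[[i]]$mu, "+")
}

#' Extract one pattern as a channels x frequency matrix
#'
#' @param decomposition an [infomax_ica()] object.
#' @param index component index.
#' @return numeric `n_c x n_omega` matrix.
#' @export
pattern_matrix <- function(decomposition, index) {
  unflatten_pattern(decomposition$S[index, ],
                    decomposition$pattern_dim[1],
                    decomposition$pattern_dim[2])
}

#' Match patterns across absolute and relative power decompositions
#'
#' Patterns observed in both the absolute- and the relative-power
#' decompositions are the candidates for stable, physiologically
#' meaningful spatiospectral patterns. Rows of the two source matrices are
#' matched one-to-one greedily by absolute Pearson correlation; a pair is
#' marked stable when its correlation reaches `r_min`, both components'
#' ICASSO-style stability indices reach `stability_min`, and both carry
#' an above-average share of the retained variance (a Kaiser-style
#' floor: run-to-run stability alone cannot reject over-factoring
#' residue, whose deterministic optima replicate across runs but carry
#' little variance). Unmatched or sub-threshold components are retained
#' but flagged unstable.
#'
#' @param abs_decomp,rel_decomp decompositions from [infomax_ica()] of the
#'   absolute- and relative-power spatiospectral matrices.
#' @param r_min minimum absolute cross-mode correlation (default 0.7).
#' @param stability_min minimum within-mode stability index (default 0.8;
#'   0 disables the gate).
#' @param var_share_min variance-share floor as a multiple of the uniform
#'   share `1/m` (default 1, i.e. above-average; 0 disables the gate).
#' @return an object of class `pattern_set`: data frame with one row per
#'   matched pair (label, component indices, correlation, stabilities,
#'   `stable` flag) plus the two decompositions as attributes.
#' @export
match_across_power_modes <- function(abs_decomp, rel_decomp, r_min = 0.7,
                                     stability_min = 0.8,
                                     var_share_min = 1) {
  if (!identical(abs_decomp$pattern_dim, rel_decomp$pattern_dim)) {
    stopf("decompositions must share channel/bin geometry")
  }
  idx <- greedy_match(abs_decomp$S, rel_decomp$S)
  r <- vapply(seq_along(idx), function(k) {
    stats::cor(abs_decomp$S[k, ], rel_decomp$S[idx[k], ])
  }, 0)
  tab <- data.frame(
    label = sprintf("pat%02d", seq_along(idx)),
    abs_index = seq_along(idx),
    rel_index = idx,
    match_r = r,
    stability_abs = abs_decomp$stability_index,
    stability_rel = rel_decomp$stability_index[idx],
    var_share_abs = abs_decomp$var_share,
    var_share_rel = rel_decomp$var_share[idx],
    stringsAsFactors = FALSE)
  tab$stable <- abs(tab$match_r) >= r_min &
    tab$stability_abs >= stability_min &
    tab$stability_rel >= stability_min &
    tab$var_share_abs >= var_share_min / abs_decomp$m &
    tab$var_share_rel >= var_share_min / rel_decomp$m
  # stable patterns first, relabelled in decreasing match quality
  tab <- tab[order(-tab$stable, -abs(tab$match_r)), ]
  tab$label <- sprintf("pat%02d", seq_len(nrow(tab)))
  rownames(tab) <- NULL
  structure(tab, class = c("pattern_set", "data.frame"),
            abs_decomp = abs_decomp, rel_decomp = rel_decomp)
}

#' Average a spatiospectral pattern over leads into a spectral filter
#'
#' @param pattern `n_c x n_omega` pattern matrix (see [pattern_matrix()]).
#' @return numeric spectral filter `g(omega)` of length `n_omega`.
#' @export
average_over_leads <- function(pattern) {
  stopifnot(is.matrix(pattern), nrow(pattern) >= 1)
  colMeans(pattern)
}
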