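#' Build the binary task design matrix at epoch resolution
#'
#' Epoch `t` of session `j` receives a 1 in the column of stimulus type
#' `k` and session `j` iff an onset of that type falls inside the
#' half-open interval `[t * TR, (t + 1) * TR)` of that session. One
#' constant (DC) column per session completes the model, so a four-session
#' three-type design has 16 columns.
#'
#' @param schedules list of session schedules, ordered by session.
#' @param TR epoch duration in seconds.
#' @param n_epochs epochs per session; defaults to
#'   `round(session_duration / TR)` of each schedule.
#' @param types stimulus type order; defaults to
#'   frequent, target, distractor restricted to the types present.
#' @return an object of class `task_design`: list with the design matrix
#'   `X`, column `labels`, `q`, `types`, `n_sessions` and per-row session
#'   index `session`.
#' @export
build_task_design <- function(schedules, TR,
                              n_epochs = NULL, types = NULL) {
  if (TR <= 0) stopf("TR must be positive")
  n_sessions <- length(schedules)
  if (is.null(types)) {
    seen <- unique(unlist(lapply(schedules, function(s) s$trial_type)))
    types <- intersect(c("frequent", "target", "distractor"), seen)
    types <- c(types, setdiff(seen, types))
  }
  n_t <- vapply(seq_len(n_sessions), function(j) {
    as.integer(if (!is.null(n_epochs)) n_epochs
               else round(attr(schedules[[j]], "session_duration") / TR))
  }, 0L)
  blocks <- vector("list", n_sessions)
  for (j in seq_len(n_sessions)) {
    sched <- schedules[[j]]
    B <- matrix(0, n_t[j], length(types),
                dimnames = list(NULL, types))
    for (i in seq_len(nrow(sched))) {
      ep <- floor(sched$onset[i] / TR) + 1
      if (ep > n_t[j]) {
        stopf("session %d: onset %.2f s beyond session duration", j,
              sched$onset[i])
      }
      B[ep, sched$trial_type[i]] <- 1
    }
    blocks[[j]] <- B
  }
  total <- sum(n_t)
  q <- length(types) * n_sessions + n_sessions
  X <- matrix(0, total, q)
  labels <- character(q)
  row0 <- 0
  for (j in seq_len(n_sessions)) {
    for (k in seq_along(types)) {
      col <- (k - 1) * n_sessions + j
      X[row0 + seq_len(n_t[j]), col] <- blocks[[j]][, k]
      labels[col] <- sprintf("%s_s%d", types[k], j)
    }
    dc <- length(types) * n_sessions + j
    X[row0 + seq_len(n_t[j]), dc] <- 1
    labels[dc] <- sprintf("dc_s%d", j)
    row0 <- row0 + n_t[j]
  }
  colnames(X) <- labels
  structure(list(X = X, labels = labels, q = q, types = types,
                 n_sessions = n_sessions,
                 session = rep(seq_len(n_sessions), n_t)),
            class = "task_design")
}

#' Contrast vector selecting one stimulus type across sessions
#'
#' @param design a [build_task_design()] object.
#' @param type stimulus type name.
#' @return binary contrast vector of length `q`.
#' @export
contrast_for_type <- function(design, type) {
  k <- match(type, design$types)
  if (is.na(k)) stopf("unknown stimulus type '%s'", type)
  c0 <- numeric(design$q)
  c0[(k - 1) * design$n_sessions + seq_len(design$n_sessions)] <- 1
  c0
}

#' Least-squares fit of pattern fluctuations on the task design
#'
#' Solves `U = X beta + eps` by QR-based least squares (no explicit
#' normal-equation inversion).
#'
#' @param U `n x n_patterns` matrix of fluctuation time courses.
#' @param X a [build_task_design()] object or design matrix.
#' @return `q x n_patterns` coefficient matrix.
#' @export
fit_pattern_glm <- function(U, X) {
  if (inherits(X, "task_design")) X <- X$X
  U <- as.matrix(U)
  if (nrow(U) != nrow(X)) stopf("U and X must have matching rows")
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    dep <- colnames(X)[dec$pivot[(dec$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient (dependent columns: %s)",
          paste(dep, collapse = ", "))
  }
  beta <- qr.coef(dec, U)
  rownames(beta) <- colnames(X)
  beta
}

#' Group one-sample t-statistic of a contrast over subjects
#'
#' For each pattern, `t = sqrt(s) * mean(c' beta) / sd(c' beta)` over the
#' `s` subjects (sample standard deviation, denominator `s - 1`).
#'
#' @param betas list of per-subject coefficient matrices
#'   ([fit_pattern_glm()]).
#' @param contrast contrast vector of length `q`.
#' @return list with `t` (per pattern), `mean`, `sd`, the per-subject
#'   contrast `values`, and `s`.
#' @export
group_ttest <- function(betas, contrast) {
  s <- length(betas)
  if (s < 2) stopf("group statistics need at least 2 subjects")
  P <- ncol(betas[[1]])
  raw <- vapply(betas, function(b) as.numeric(crossprod(contrast, b)),
                numeric(P))
  vals <- if (P == 1) matrix(raw, ncol = 1) else t(raw)
  mu <- colMeans(vals)
  sdev <- apply(vals, 2, stats::sd)
  if (any(sdev == 0)) {
    stopf("zero between-subject variance: t statistic undefined")
  }
  list(t = sqrt(s) * mu / sdev, mean = mu, sd = sdev, values = vals,
       s = s)
}

#' Bonferroni-corrected two-tailed Student-t critical value
#'
#' @param alpha family-wise significance level.
#' @param n_comparisons number of comparisons corrected for.
#' @param dof degrees of freedom.
#' @return the critical |t| threshold.
#' @export
critical_t <- function(alpha = 0.05, n_comparisons = 10, dof = 16) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  if (dof < 1) stopf("dof must be >= 1")
  stats::qt(1 - alpha / (2 * n_comparisons), df = dof)
}

#' Select task-related patterns from the four models' t-tables
#'
#' A (pattern, stimulus type) pair is task-related at the family-wise
#' level when any model's |t| exceeds `t_crit` (the paper-style
#' Bonferroni threshold, default 3.25). A pair is additionally flagged a
#' candidate when the mean t over models exceeds `mean_crit` in absolute
#' value while the between-model standard deviation (population,
#' denominator = number of models) stays below `std_crit`. `selected` is
#' the union of the two rules; `direction` is the sign of the mean t.
#'
#' @param t_tables named list of `n_patterns x n_types` t-value matrices,
#'   one per model, aligned on rows and columns.
#' @param t_crit critical |t| for the family-wise rule.
#' @param mean_crit threshold on |mean t| for the secondary rule.
#' @param std_crit cap on the between-model SD for the secondary rule.
#' @return data frame with one row per (pattern, type): per-model t
#'   values, `mean_t`, `sd_t`, `selected_fwe`, `candidate`, `selected`,
#'   `direction`.
#' @export
select_task_related <- function(t_tables, t_crit = 3.25, mean_crit = 2.0,
                                std_crit = 0.5) {
  ref <- t_tables[[1]]
  for (tt in t_tables) {
    if (!identical(dim(tt), dim(ref)) ||
        !identical(dimnames(tt), dimnames(ref))) {
      stopf("t tables are misaligned across models")
    }
  }
  A <- array(unlist(t_tables),
             dim = c(nrow(ref), ncol(ref), length(t_tables)))
  mean_t <- apply(A, c(1, 2), mean)
  sd_t <- apply(A, c(1, 2), sd_n)
  any_hit <- apply(abs(A) > t_crit, c(1, 2), any)
  candidate <- abs(mean_t) > mean_crit & sd_t < std_crit
  grid <- expand.grid(pattern = rownames(ref) %||%
                        sprintf("pat%02d", seq_len(nrow(ref))),
                      type = colnames(ref) %||%
                        sprintf("type%d", seq_len(ncol(ref))),
                      stringsAsFactors = FALSE)
  out <- cbind(grid,
               as.data.frame(matrix(aperm(A, c(3, 1, 2)),
                                    ncol = length(t_tables),
                                    byrow = TRUE,
                                    dimnames = list(NULL,
                                                    names(t_tables)))))
  out$mean_t <- as.vector(mean_t)
  out$sd_t <- as.vector(sd_t)
  out$selected_fwe <- as.vector(any_hit)
  out$candidate <- as.vector(candidate)
  out$selected <- out$selected_fwe | out$candidate
  out$direction <- sign(out$mean_t)
  out
}

#' Filter epoch power spectra with a spectral pattern
#'
#' Applies `p(t, c) = sum_omega g(omega) E(t, c, omega)`, z-scores each
#' channel's time course (denominator n) and averages over channels,
#' yielding the session's pattern power fluctuation at epoch (TR)
#' resolution. Constant channel time courses raise an error rather than
#' silently contributing zeros.
#'
#' @param ss an [compute_power()] spatiospectral matrix.
#' @param g spectral filter of length `n_omega`.
#' @return numeric fluctuation of length `n_t`.
#' @export
spectral_filter <- function(ss, g) {
  d <- dim(ss$E)
  if (length(g) != d[3]) {
    stopf("filter length %d does not match %d frequency bins",
          length(g), d[3])
  }
  P <- matrix(matrix(ss$E, d[1] * d[2], d[3]) %*% g, d[1], d[2])
  Z <- apply(P, 2, zscore_n)
  rowMeans(Z)
}

#' Assemble a pattern fluctuation time course under one fusion model
#'
#' Spectral models (`ASM`, `RSM`) filter the epoch power spectra with the
#' lead-averaged spectral pattern and average z-scored channel courses;
#' spatiospectral models (`ASSM`, `RSSM`) use the pattern's
#' back-reconstructed mixing column. Sessions are concatenated in
#' acquisition order.
#'
#' @param model one of `"ASM"`, `"RSM"`, `"ASSM"`, `"RSSM"`.
#' @param E_list for spectral models: list of the subject's session
#'   [compute_power()] matrices (absolute power for ASM, relative for
#'   RSM).
#' @param g for spectral models: spectral filter (see
#'   [average_over_leads()]).
#' @param decomposition for spatiospectral models: the matching-mode
#'   [infomax_ica()] object.
#' @param pattern_index for spatiospectral models: component index.
#' @param unit_ids for spatiospectral models: the subject's session unit
#'   ids in acquisition order.
#' @param subject_id,label metadata carried on the result.
#' @return an object of class `pattern_fluctuation`: list with `values`,
#'   per-element `session` index, `model`, `label`, `subject_id`.
#' @export
pattern_fluctuation <- function(model = c("ASM", "RSM", "ASSM", "RSSM"),
                                E_list = NULL, g = NULL,
                                decomposition = NULL, pattern_index = NULL,
                                unit_ids = NULL, subject_id = NA,
                                label = NA) {
  model <- match.arg(model)
  if (model %in% c("ASM", "RSM")) {
    mode_needed <- if (model == "ASM") "absolute" else "relative"
    if (is.null(E_list) || is.null(g)) {
      stopf("%s needs E_list and a spectral filter g", model)
    }
    for (ss in E_list) {
      if (ss$power_mode != mode_needed) {
        stopf("%s requires %s-power spectra (got %s)", model, mode_needed,
              ss$power_mode)
      }
    }
    values <- unlist(lapply(E_list, spectral_filter, g = g))
    session <- rep(seq_along(E_list),
                   vapply(E_list, function(ss) dim(ss$E)[1], 0L))
  } else {
    mode_needed <- if (model == "ASSM") "absolute" else "relative"
    if (is.null(decomposition) || is.null(pattern_index) ||
        is.null(unit_ids)) {
      stopf("%s needs a decomposition, pattern_index and unit_ids", model)
    }
    if (decomposition$power_mode != mode_needed) {
      stopf("%s requires the %s-power decomposition (got %s)", model,
            mode_needed, decomposition$power_mode)
    }
    cols <- lapply(unit_ids, function(u) {
      back_reconstruct(decomposition, u)[, pattern_index]
    })
    values <- unlist(cols)
    session <- rep(seq_along(unit_ids), vapply(cols, length, 0L))
  }
  structure(list(values = as.numeric(values), session = session,
                 model = model, label = label, subject_id = subject_id),
            class = "pattern_fluctuation")
}
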