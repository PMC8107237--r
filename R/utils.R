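# Internal helpers shared across modules.

#' Derive a child RNG seed from a master seed and integer indices
#'
#' One master seed spawns per-subject/per-session/per-stage seeds by fixed
#' integer arithmetic (multiplicative congruential mixing modulo 2^31 - 1),
#' so that simulated units are mutually independent yet each is individually
#' reproducible. All products stay below 2^53 and are therefore exact in
#' double arithmetic.
#'
#' @param master integer master seed.
#' @param ... non-negative integer indices (subject, session, stage, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# z-score with population (denominator n) variance
zscore_n <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    stop("cannot z-score a constant time course (zero variance)")
  }
  (x - mu) / s
}

# population standard deviation (denominator n)
sd_n <- function(x) sqrt(mean((x - mean(x))^2))

# stop() with sprintf formatting, no call in message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# unit id used to key subject-session data throughout the pipeline
unit_id <- function(subject, session) sprintf("sub%02d_ses%d", subject, session)
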