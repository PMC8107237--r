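# Shared fixtures, built in code. The tiny study keeps every stage fast
# enough for routine runs; it is cached per test session.

tiny_patterns <- function() {
  list(
    pattern_spec("delta_task", c(1, 4),
                 modulation = c(frequent = -0.4, target = 0,
                                distractor = 0),
                 mask_lo = c(2, 2, 2), mask_hi = c(5, 5, 4)),
    pattern_spec("alpha_bg", c(8, 12),
                 mask_lo = c(7, 7, 4), mask_hi = c(10, 10, 6)))
}

tiny_config <- function(...) {
  study_config(subjects = 3L, sessions = 2L, n_scans = 128L,
               n_channels = 10L, events_per_session = 40L,
               grid_shape = c(12L, 12L, 8L),
               patterns = tiny_patterns(),
               n_pcs_unit = 40L, n_pcs_group = 6L, m = 6L,
               n_runs = 3L, min_extent = 20L, ...)
}

.fixture_env <- new.env(parent = emptyenv())

# tiny study (with BOLD volumes), simulated once per test session
tiny_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_study(tiny_config(), seed = 11)
  }
  .fixture_env$study
}

# flatten a channels x bins pattern matrix in the package's feature
# order (frequency fastest within channel)
flatten_pattern <- function(m) as.vector(t(m))

# build an ss_matrix directly from a power array (for constructed
# decomposition fixtures)
make_ss <- function(E, power_mode = "absolute", TR = 1.66, fs = 250) {
  structure(list(E = E, freqs = seq_len(dim(E)[3]) - 1,
                 power_mode = power_mode, TR = TR, fs = fs,
                 n_fft = dim(E)[3], subject_id = NA, session_id = NA),
            class = "ss_matrix")
}
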