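# Shared fixtures. Built once per test run and cached; all synthetic, all
# seeded. Desk-scale configuration: 8 markers, 500 Hz radar rate, coarse
# training stride — small enough for property checks in seconds.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(...) {
  defaults <- list(n_markers = 8, rate = 500, marker_rate = 250,
                   dt_tr = 0.10, n_test = 10, d = 4, snr_db = 10, seed = 42)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

# cached small training database (compressed at d = 4) with its subject
fixture_db <- function() {
  if (is.null(.fixture_env$db)) {
    cfg <- small_config()
    db <- build_synthetic_db(cfg, seed = 42)
    db <- precompute_test_banks(db)
    .fixture_env$db <- db
    .fixture_env$cfg <- cfg
  }
  .fixture_env$db
}

fixture_cfg <- function() {
  fixture_db()
  .fixture_env$cfg
}

# random complex vector with reproducible draw
rand_complex <- function(n, seed) {
  withr::with_seed(seed, complex(real = rnorm(n), imaginary = rnorm(n)))
}

# brute-force circular cross-correlation maximum (independent oracle)
brute_xcorr_max <- function(s, b) {
  n <- length(s)
  best <- 0
  for (tau in 0:(n - 1)) {
    idx <- ((seq_len(n) - 1 - tau) %% n) + 1
    v <- Mod(sum(s * Conj(b[idx]))) / n
    if (v > best) best <- v
  }
  best
}

# circular shift helper matching the correlation convention
circ_shift <- function(x, tau) {
  n <- length(x)
  x[((seq_len(n) - 1 - tau) %% n) + 1]
}
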