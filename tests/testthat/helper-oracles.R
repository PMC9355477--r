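# Independent brute-force oracles and small fixture builders shared across
# test files. The oracles re-derive the preprocessing definitions sample by
# sample, without any of the package's vectorised machinery.

# Per-sample blink threshold oracle: centered window of `window` samples
# around i (1-based [i - w/2, i + w/2 - 1], clipped), statistics over the
# valid samples, flag iff x < mean - k*sd - tol with the same numerical
# guard the implementation documents.
brute_force_blink_flags <- function(diameter, valid, window = 1200, k = 3) {
  n <- length(diameter)
  half_lo <- window %/% 2L
  half_hi <- window - half_lo
  flags <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi - 1L)
    w <- (lo:hi)[valid[lo:hi]]
    if (length(w) < 2 || !valid[i]) next
    m <- mean(diameter[w])
    s <- sd(diameter[w])
    tol <- 1e-9 * max(abs(m), 1)
    flags[i] <- diameter[i] < m - k * s - tol
  }
  flags
}

# Margin-mask oracle: a sample is invalidated iff it is flagged or lies
# within `pre` samples before or `post` samples after any flagged sample.
brute_force_margin_mask <- function(flags, pre = 77, post = 181) {
  n <- length(flags)
  out <- logical(n)
  for (i in which(flags)) {
    lo <- max(1L, i - pre)
    hi <- min(n, i + post)
    out[lo:hi] <- TRUE
  }
  out
}

# Noise-free generator configuration used by identity fixtures: constant
# level per block (no memory ramp, no block trend steps inside epochs), no
# measurement noise, no block-level residual.
clean_generator_config <- function(n_participants = 2, n_blocks = 3,
                                   blink_rate_per_min = 0, ...) {
  generator_config(
    n_participants = n_participants,
    trace_noise_sd = 0, sigma_eps = 0, memory_ramp_mm = 0,
    blink_rate_per_min = blink_rate_per_min,
    timeline = pipeline_config(n_blocks = n_blocks),
    ...
  )
}

# Centered block-level model data from a simulated study.
centered_model_data <- function(sim) {
  d <- merge(sim$blocks, sim$participants[, c("id", "rs_score", "snr_db")],
             by.x = "participant", by.y = "id")
  center_predictors(d)
}

# Cache for expensive shared fixtures within one test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Noise-free two-block single-participant session used by several
# preprocessing/baseline identity tests.
clean_session_fixture <- function() {
  cached("clean_session", {
    cfg <- clean_generator_config(n_participants = 1, n_blocks = 2)
    set.seed(42)
    parts <- gen_participants(cfg)
    sch <- build_timeline(cfg)
    mu <- gen_block_means(parts, cfg, n_blocks = 2)
    tr <- gen_trace(mu, sch, cfg)
    list(cfg = cfg, sch = sch, mu = mu, tr = tr)
  })
}
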