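# Synthetic SWIR sessions with known ground truth: participant covariates,
# block-level pupil baselines from the generating mixed model, raw 1,200 Hz
# traces with injected blinks, binomial recall, and a psychometric listener
# for staircase simulation.

#' Generator configuration
#'
#' Defaults encode the study conditions the analysis was designed around:
#' fixed effects (on the centered-predictor scale) equal to the reference
#' pupil-baseline model estimates, Reading Span scores ~ Normal(41.72, 11.99)
#' clipped to \[0, 100\], individual SNR ~ Normal(6.65, 3.08) dB, a
#' by-participant random intercept and random Block slope, and binomial
#' recall driven by the centered Reading Span score.
#'
#' @param n_participants number of participants to generate.
#' @param betas named list of generating fixed effects on the
#'   centered-predictor scale: `b0` (mm), `b_block` (mm per block), `b_rs`
#'   (mm per RS percentage point), `b_snr` (mm per dB), `b_rs_snr`
#'   (mm per RS-unit x dB).
#' @param tau0 SD of the by-participant random intercept (mm).
#' @param tau_block SD of the by-participant random Block slope (mm/block).
#' @param sigma_eps block-level residual SD (mm).
#' @param rs_mean,rs_sd Reading Span score distribution (percent).
#' @param snr_mean,snr_sd individual SNR distribution (dB).
#' @param age_mean,age_sd,pta_mean,pta_sd demographic covariates (not used by
#'   the generating model; carried for realism).
#' @param memory_ramp_mm linear increase of the pre-sentence pupil level per
#'   within-block sentence index (mm/sentence); emulates the storage load
#'   that builds up as items accumulate for later recall.
#' @param trace_noise_sd sample-level Gaussian measurement noise SD (mm).
#' @param blink_rate_per_min expected blink count per minute.
#' @param blink_duration_s range (min, max) of blink plateau durations (s).
#' @param recall list of recall-generator parameters on the logit scale:
#'   `g0` (grand log-odds of recalling a word), `g_rs` (per centered RS
#'   unit), `g0_sd` (between-participant SD of the log-odds), `g_block_sd`
#'   (SD of a by-participant linear Block trend, 0 disables it), `g_block`
#'   (mean Block trend, default 0: recall stable over the session).
#' @param psychometric list describing the simulated listener: `srt_db`
#'   (SNR of 50% sentence intelligibility) and `slope_per_db` (logistic slope
#'   on the logit scale per dB).
#' @param hint_trials number of staircase trials in [simulate_snr_setting()].
#' @param seed optional integer seed stored with the configuration.
#' @param timeline a [pipeline_config()] carrying the session timing
#'   constants.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 21,
                             betas = list(b0 = 3.48, b_block = -0.01,
                                          b_rs = 0.01, b_snr = -0.09,
                                          b_rs_snr = -0.01),
                             tau0 = 0.3,
                             tau_block = 0.003,
                             sigma_eps = 0.1,
                             rs_mean = 41.72, rs_sd = 11.99,
                             snr_mean = 6.65, snr_sd = 3.08,
                             age_mean = 58, age_sd = 11.3,
                             pta_mean = 49.30, pta_sd = 11.44,
                             memory_ramp_mm = 0.02,
                             trace_noise_sd = 0.05,
                             blink_rate_per_min = 15,
                             blink_duration_s = c(0.1, 0.3),
                             recall = list(g0 = qlogis(0.581), g_rs = 0.02,
                                           g0_sd = 0.5, g_block_sd = 0.02,
                                           g_block = 0),
                             psychometric = list(srt_db = 3.9,
                                                 slope_per_db = 0.5),
                             hint_trials = 20,
                             seed = NULL,
                             timeline = pipeline_config()) {
  cfg <- as.list(environment())
  sds <- c(cfg$tau0, cfg$tau_block, cfg$sigma_eps, cfg$rs_sd, cfg$snr_sd,
           cfg$trace_noise_sd, cfg$recall$g0_sd, cfg$recall$g_block_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (cfg$blink_rate_per_min < 0)
    stop("blink_rate_per_min must be >= 0", call. = FALSE)
  need_b <- c("b0", "b_block", "b_rs", "b_snr", "b_rs_snr")
  miss <- setdiff(need_b, names(cfg$betas))
  if (length(miss))
    stop("betas is missing: ", paste(miss, collapse = ", "), call. = FALSE)
  structure(cfg, class = "generator_config")
}

#' Generate participant records
#'
#' Draws covariates and by-participant random effects: RS score from a
#' clipped normal, SNR from a normal, `u0` (random intercept) and `u1`
#' (random Block slope) from centered normals.
#'
#' @param cfg a [generator_config()].
#' @param n number of participants (defaults to `cfg$n_participants`).
#' @return data frame with columns `id`, `rs_score`, `snr_db`, `age`,
#'   `pta_db_hl`, `included`, `u0`, `u1`.
#' @export
gen_participants <- function(cfg = generator_config(),
                             n = cfg$n_participants) {
  stopifnot(n >= 1)
  data.frame(
    id = seq_len(n),
    rs_score = pmin(100, pmax(0, rnorm(n, cfg$rs_mean, cfg$rs_sd))),
    snr_db = rnorm(n, cfg$snr_mean, cfg$snr_sd),
    age = round(rnorm(n, cfg$age_mean, cfg$age_sd)),
    pta_db_hl = rnorm(n, cfg$pta_mean, cfg$pta_sd),
    included = TRUE,
    u0 = rnorm(n, 0, cfg$tau0),
    u1 = rnorm(n, 0, cfg$tau_block)
  )
}

#' Build the session timeline
#'
#' Constructs the block/sentence schedule of a full session: background noise
#' starting 3 s before the first sentence of each block and 1 s before the
#' remaining six, stopping 1 s after each sentence; 4 s silent response
#' intervals between sentences (2 s after the seventh), a 4 s retention
#' interval, the recall phase, and a short between-block break.
#'
#' @param cfg a [pipeline_config()] (or a [generator_config()], whose
#'   `timeline` element is then used).
#' @return a `session_schedule` with `sentences` and `blocks` tables.
#' @export
build_timeline <- function(cfg = pipeline_config()) {
  if (inherits(cfg, "generator_config")) cfg <- cfg$timeline
  if (cfg$sentence_duration_s <= cfg$baseline_window_s)
    stop("sentence duration must exceed the baseline window", call. = FALSE)
  sent_rows <- vector("list", cfg$n_blocks)
  block_rows <- vector("list", cfg$n_blocks)
  t <- 0
  for (b in seq_len(cfg$n_blocks)) {
    start_b <- t
    s <- data.frame(block = b, sentence_index = seq_len(cfg$n_sentences),
                    noise_onset_s = NA_real_, sentence_onset_s = NA_real_,
                    sentence_offset_s = NA_real_, noise_offset_s = NA_real_)
    for (k in seq_len(cfg$n_sentences)) {
      lead <- if (k == 1) cfg$noise_lead_first_s else cfg$noise_lead_other_s
      s$noise_onset_s[k] <- t
      s$sentence_onset_s[k] <- t + lead
      s$sentence_offset_s[k] <- s$sentence_onset_s[k] + cfg$sentence_duration_s
      s$noise_offset_s[k] <- s$sentence_offset_s[k] + cfg$noise_tail_s
      t <- s$noise_offset_s[k] +
        if (k < cfg$n_sentences) cfg$response_s else cfg$last_response_s
    }
    retention_onset <- t
    beep <- retention_onset + cfg$retention_s
    recall_off <- beep + cfg$recall_s
    t <- recall_off + cfg$break_s
    sent_rows[[b]] <- s
    block_rows[[b]] <- data.frame(block = b, start_s = start_b,
                                  retention_onset_s = retention_onset,
                                  beep_s = beep, recall_onset_s = beep,
                                  recall_offset_s = recall_off, end_s = t)
  }
  session_schedule(sentences = do.call(rbind, sent_rows),
                   blocks = do.call(rbind, block_rows))
}

# Centered covariates over a generated sample: the same sample-mean centering
# the fitting stage applies (see center_predictors).
centered_covariates <- function(participants, n_blocks) {
  list(rs_c = participants$rs_score - mean(participants$rs_score),
       snr_c = participants$snr_db - mean(participants$snr_db),
       block_c = seq_len(n_blocks) - mean(seq_len(n_blocks)))
}

#' True block-level pupil means
#'
#' Evaluates the generating linear mixed model for every participant x block
#' cell: `mu = b0 + (b_block + u1) * Block_c + b_rs * RS_c + b_snr * SNR_c +
#' b_rs_snr * RS_c * SNR_c + u0`, with all predictors centered at their
#' sample means. Block-level residual noise is *not* included here; it is
#' added by the block-table or trace generators.
#'
#' @param participants output of [gen_participants()].
#' @param cfg a [generator_config()].
#' @param n_blocks number of blocks.
#' @return data frame `id`, `block`, `mu` (mm).
#' @export
gen_block_means <- function(participants, cfg = generator_config(),
                            n_blocks = cfg$timeline$n_blocks) {
  cc <- centered_covariates(participants, n_blocks)
  b <- cfg$betas
  g <- expand.grid(row = seq_len(nrow(participants)),
                   block = seq_len(n_blocks))
  mu <- b$b0 +
    (b$b_block + participants$u1[g$row]) * cc$block_c[g$block] +
    b$b_rs * cc$rs_c[g$row] +
    b$b_snr * cc$snr_c[g$row] +
    b$b_rs_snr * cc$rs_c[g$row] * cc$snr_c[g$row] +
    participants$u0[g$row]
  data.frame(id = participants$id[g$row], block = g$block, mu = mu)
}

#' Generate block-level recall performance
#'
#' Per participant and block, the number of correctly recalled words is
#' Binomial(7, p) with `logit(p) = g0 + g_rs * RS_c + u_g0 + (g_block +
#' u_block) * Block_c`. With the default `g_block = 0` recall is stable over
#' the session; `g_block_sd > 0` lets participants differ in their individual
#' trend (set both to zero for a pure RS-driven generator).
#'
#' @param participants output of [gen_participants()].
#' @param cfg a [generator_config()].
#' @param n_blocks number of blocks.
#' @return data frame `id`, `block`, `n_correct`, `recall_pct`, `p_true`.
#' @export
gen_recall <- function(participants, cfg = generator_config(),
                       n_blocks = cfg$timeline$n_blocks) {
  rc <- cfg$recall
  n <- nrow(participants)
  cc <- centered_covariates(participants, n_blocks)
  ug0 <- rnorm(n, 0, rc$g0_sd)
  ub <- rnorm(n, 0, rc$g_block_sd)
  g <- expand.grid(row = seq_len(n), block = seq_len(n_blocks))
  eta <- rc$g0 + rc$g_rs * cc$rs_c[g$row] + ug0[g$row] +
    (rc$g_block + ub[g$row]) * cc$block_c[g$block]
  p <- plogis(eta)
  k <- rbinom(length(p), cfg$timeline$n_sentences, p)
  data.frame(id = participants$id[g$row], block = g$block, n_correct = k,
             recall_pct = 100 * k / cfg$timeline$n_sentences, p_true = p)
}

#' Simulate a block-level outcome table
#'
#' The block-level twin of the full trace simulation: draws participants,
#' evaluates the generating mixed model, adds block-level residual noise and
#' binomial recall. This is the workhorse for parameter-recovery and
#' elimination studies, where sample-level traces are irrelevant.
#'
#' @param cfg a [generator_config()].
#' @param seed optional integer seed (applied with [set.seed()]).
#' @param n_participants,n_blocks overrides of the configured sizes.
#' @return list with `blocks` (participant, block, pupil_baseline_mm,
#'   n_sentences_used, recall_pct), `participants`, and `truth` (the
#'   generating random effects and true block means).
#' @export
simulate_block_data <- function(cfg = generator_config(), seed = NULL,
                                n_participants = cfg$n_participants,
                                n_blocks = cfg$timeline$n_blocks) {
  if (!is.null(seed)) set.seed(seed)
  parts <- gen_participants(cfg, n = n_participants)
  means <- gen_block_means(parts, cfg, n_blocks = n_blocks)
  means$y <- means$mu + rnorm(nrow(means), 0, cfg$sigma_eps)
  recall <- gen_recall(parts, cfg, n_blocks = n_blocks)
  stopifnot(all(means$id == recall$id), all(means$block == recall$block))
  blocks <- data.frame(participant = means$id, block = means$block,
                       pupil_baseline_mm = means$y,
                       n_sentences_used = cfg$timeline$n_sentences,
                       recall_pct = recall$recall_pct)
  list(blocks = blocks,
       participants = parts[, c("id", "rs_score", "snr_db", "age",
                                "pta_db_hl", "included")],
       truth = list(random_effects = parts[, c("id", "u0", "u1")],
                    block_means = means[, c("id", "block", "mu")],
                    recall_p = recall[, c("id", "block", "p_true")],
                    config = cfg))
}

# Piecewise-constant level for one participant's session: per block the true
# block mean, plus the memory ramp indexed by the upcoming sentence. The ramp
# level for sentence k holds from the end of sentence k-1's background noise
# (so the pre-sentence baseline window of sentence k sits on level k), and the
# level of sentence 7 holds through retention/recall/break.
trace_level <- function(n, trace0_s, fs, schedule, block_mu, ramp) {
  level <- numeric(n)
  sen <- schedule$sentences
  blocks <- unique(sen$block)
  blk_tab <- schedule$blocks
  for (b in blocks) {
    s <- sen[sen$block == b, , drop = FALSE]
    b_start <- if (!is.null(blk_tab)) blk_tab$start_s[blk_tab$block == b]
               else s$noise_onset_s[1]
    b_end <- if (!is.null(blk_tab)) blk_tab$end_s[blk_tab$block == b]
             else max(s$noise_offset_s) + 10
    mu_b <- block_mu$mu[block_mu$block == b]
    # segment boundaries: sentence k's level runs until its noise offset
    seg_start <- c(b_start, s$noise_offset_s[-nrow(s)])
    seg_end <- c(s$noise_offset_s[-nrow(s)], b_end)
    for (k in seq_len(nrow(s))) {
      i0 <- max(1L, as.integer(ceiling((seg_start[k] - trace0_s) * fs - 1e-9)) + 1L)
      i1 <- min(n, as.integer(ceiling((seg_end[k] - trace0_s) * fs - 1e-9)))
      if (i1 >= i0) level[i0:i1] <- mu_b + ramp * (k - 1)
    }
  }
  level
}

#' Generate a raw pupil trace for one participant
#'
#' Sample-level diameter = true block mean + within-block memory ramp (held
#' over each sentence's segment) + Gaussian measurement noise, on the
#' configured sample clock. All samples are marked valid; blinks are injected
#' separately by [inject_blinks()].
#'
#' @param block_mu data frame `block`, `mu` for this participant (one row per
#'   block; see [gen_block_means()]).
#' @param schedule a `session_schedule` from [build_timeline()].
#' @param cfg a [generator_config()].
#' @param eye which eye the trace represents.
#' @return a [pupil_trace].
#' @export
gen_trace <- function(block_mu, schedule, cfg = generator_config(),
                      eye = "right") {
  fs <- cfg$timeline$sample_rate_hz
  end_s <- if (!is.null(schedule$blocks)) max(schedule$blocks$end_s)
           else max(schedule$sentences$noise_offset_s) + 10
  n <- as.integer(ceiling(end_s * fs))
  level <- trace_level(n, 0, fs, schedule, block_mu, cfg$memory_ramp_mm)
  noise <- if (cfg$trace_noise_sd > 0) rnorm(n, 0, cfg$trace_noise_sd) else 0
  pupil_trace(level + noise, sample_rate = fs, t0 = 0, eye = eye)
}

#' Inject blinks into a trace
#'
#' Overwrites randomly placed intervals with a blink artifact: a 20 ms linear
#' dip to 10% of the local diameter, a plateau of drawn duration, and a 20 ms
#' linear recovery. Placement is a Poisson process at the configured rate; in
#' `"response_only"` mode blinks are confined to the silent response
#' intervals so that no sentence epoch is touched.
#'
#' @param trace a [pupil_trace].
#' @param cfg a [generator_config()].
#' @param schedule required for `where = "response_only"`.
#' @param where `"anywhere"` or `"response_only"`.
#' @return list with `trace` (modified copy) and `intervals`, a data frame of
#'   true blink extents (`start`, `end`, 1-based half-open sample indices).
#' @export
inject_blinks <- function(trace, cfg = generator_config(), schedule = NULL,
                          where = c("anywhere", "response_only")) {
  where <- match.arg(where)
  n <- length(trace)
  fs <- trace$sample_rate
  minutes <- n / fs / 60
  n_blinks <- rpois(1, cfg$blink_rate_per_min * minutes)
  intervals <- data.frame(start = integer(0), end = integer(0))
  if (n_blinks == 0) return(list(trace = trace, intervals = intervals))
  edge <- max(1L, round(0.020 * fs))  # 20 ms ramps
  plateau <- round(runif(n_blinks, cfg$blink_duration_s[1],
                         cfg$blink_duration_s[2]) * fs)
  total_len <- plateau + 2L * edge
  if (where == "response_only") {
    if (is.null(schedule))
      stop("`schedule` is required for response_only placement",
           call. = FALSE)
    sen <- schedule$sentences
    resp <- data.frame(from = sen$noise_offset_s,
                       to = c(sen$noise_onset_s[-1],
                              sen$noise_offset_s[nrow(sen)] + 2))
    same_block <- c(sen$block[-nrow(sen)] == sen$block[-1], FALSE)
    resp$to[!same_block] <- resp$from[!same_block] +
      cfg$timeline$last_response_s
    # buffer so that the removal margins applied downstream cannot reach
    # into the neighbouring sentence epochs
    pre_buf <- cfg$timeline$pre_margin_samples + 1L
    post_buf <- cfg$timeline$post_margin_samples + 1L
    starts <- integer(n_blinks)
    for (i in seq_len(n_blinks)) {
      w <- resp[sample.int(nrow(resp), 1), ]
      lo <- time_to_index(trace, w$from) + pre_buf
      hi <- time_to_index(trace, w$to) - total_len[i] - post_buf
      starts[i] <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1) - 1L
    }
  } else {
    starts <- sample.int(max(1L, n - max(total_len)), n_blinks, replace = TRUE)
  }
  d <- trace$diameter
  keep <- rep(TRUE, n_blinks)
  for (i in seq_len(n_blinks)) {
    s0 <- starts[i]; e0 <- min(n, s0 + total_len[i] - 1L)
    if (s0 > n) { keep[i] <- FALSE; next }
    local <- d[s0]
    floor_mm <- 0.1 * local
    idx <- s0:e0
    len <- length(idx)
    down <- min(edge, len)
    up <- min(edge, max(0L, len - down))
    prof <- c(seq(local, floor_mm, length.out = down + 1)[-1],
              rep(floor_mm, max(0L, len - down - up)),
              if (up > 0) seq(floor_mm, d[min(n, e0 + 1L)],
                              length.out = up + 1)[-(up + 1)] else numeric(0))
    d[idx] <- prof[seq_len(len)]
    intervals <- rbind(intervals, data.frame(start = s0, end = e0 + 1L))
  }
  trace$diameter <- d
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  list(trace = trace, intervals = intervals)
}

#' Psychometric listener
#'
#' Returns a simulated listener: a function of SNR that draws a correct /
#' incorrect sentence repetition with `P(correct) = plogis((snr - srt_db) *
#' slope_per_db)`.
#'
#' @param srt_db SNR of 50% sentence intelligibility (dB).
#' @param slope_per_db logistic slope (logit units per dB).
#' @return function `(snr_db) -> logical`.
#' @export
psychometric_listener <- function(srt_db, slope_per_db) {
  force(srt_db); force(slope_per_db)
  function(snr_db) {
    runif(1) < plogis((snr_db - srt_db) * slope_per_db)
  }
}

#' Simulate a complete session dataset
#'
#' Full trace-level simulation for a set of participants: timeline, true
#' block means, raw traces with injected blinks, and recall outcomes.
#' Optionally writes `samples_<id>.tsv`, `events.tsv`, `participants.csv` and
#' `truth.json` to a directory.
#'
#' @param cfg a [generator_config()].
#' @param seed optional integer seed.
#' @param out_dir optional output directory.
#' @param blink_where blink placement mode passed to [inject_blinks()];
#'   `"response_only"` yields the clean-baselines fixture in which every
#'   sentence keeps 100% validity.
#' @return list with `participants`, `schedule`, `sessions` (per participant:
#'   `left`, `right` traces and true `blink_intervals`), `recall`, `truth`.
#' @export
simulate_session <- function(cfg = generator_config(), seed = NULL,
                             out_dir = NULL,
                             blink_where = "anywhere") {
  if (!is.null(seed)) set.seed(seed)
  parts <- gen_participants(cfg)
  schedule <- build_timeline(cfg)
  n_blocks <- cfg$timeline$n_blocks
  means <- gen_block_means(parts, cfg, n_blocks = n_blocks)
  recall <- gen_recall(parts, cfg, n_blocks = n_blocks)
  sessions <- vector("list", nrow(parts))
  for (i in seq_len(nrow(parts))) {
    mu_i <- means[means$id == parts$id[i], c("block", "mu")]
    right <- gen_trace(mu_i, schedule, cfg, eye = "right")
    left <- gen_trace(mu_i, schedule, cfg, eye = "left")
    br <- inject_blinks(right, cfg, schedule, where = blink_where)
    bl <- inject_blinks(left, cfg, schedule, where = blink_where)
    sessions[[i]] <- list(id = parts$id[i], right = br$trace,
                          left = bl$trace,
                          blink_intervals = list(right = br$intervals,
                                                 left = bl$intervals))
  }
  truth <- list(random_effects = parts[, c("id", "u0", "u1")],
                block_means = means,
                recall_p = recall[, c("id", "block", "p_true")])
  out <- list(participants = parts[, c("id", "rs_score", "snr_db", "age",
                                       "pta_db_hl", "included")],
              schedule = schedule, sessions = sessions,
              recall = recall[, c("id", "block", "n_correct", "recall_pct")],
              truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session_events(schedule, file.path(out_dir, "events.tsv"))
    write_participants(out$participants,
                       file.path(out_dir, "participants.csv"))
    for (s in sessions)
      write_pupil_samples(s$left, s$right,
                          file.path(out_dir, sprintf("samples_%03d.tsv", s$id)))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
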