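# Blink detection, margins, interpolation and validity filters, pinned by
# brute-force per-sample oracles.

test_that("eye selection prefers the right eye unless the left has more data", {
  n <- 100
  mk <- function(pct, eye) pupil_trace(rep(3.2, n),
                                       valid = seq_len(n) <= pct, eye = eye)
  expect_equal(select_eye(mk(80, "left"), mk(90, "right"))$eye, "right")
  expect_equal(select_eye(mk(51, "left"), mk(50, "right"))$eye, "left")
  expect_equal(select_eye(mk(70, "left"), mk(70, "right"))$eye, "right")
  expect_error(select_eye(mk(0, "left"), mk(0, "right")), "unusable")
})

test_that("a constant trace yields zero blinks (strict threshold)", {
  tr <- pupil_trace(rep(3.5, 5000))
  runs <- detect_blinks(tr, 1200, 3)
  expect_equal(nrow(runs), 0)
})

test_that("detection matches the brute-force per-sample oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 3000
    x <- 3.4 + rnorm(n, 0, 0.05)
    # inject a couple of rectangular dips of varying width/depth
    for (j in 1:2) {
      s <- sample(200:(n - 400), 1)
      w <- sample(20:80, 1)
      x[s:(s + w)] <- x[s:(s + w)] - runif(1, 0.8, 2.5)
    }
    valid <- runif(n) > 0.02
    tr <- pupil_trace(x, valid = valid)
    for (win in c(301, 1200)) {
      runs <- detect_blinks(tr, win, 3)
      expect_identical(attr(runs, "flagged"),
                       brute_force_blink_flags(x, valid, win, 3),
                       info = paste("seed", seed, "window", win))
    }
  }
})

test_that("a single injected dip is detected as one run covering its core", {
  n <- 20000
  x <- rep(3.5, n)
  x[8001:8060] <- 0.4          # 60-sample dip, 5% of the 1200 window
  tr <- pupil_trace(x)
  runs <- detect_blinks(tr, 1200, 3)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start[1], 8001L)
  expect_equal(runs$end[1], 8061L)
  expect_equal(sum(attr(runs, "flagged")), 60)
})

test_that("margins extend, clip, and merge exactly as the arithmetic says", {
  # 120-sample run gains 77 + 181 margin samples
  out <- apply_blink_margins(data.frame(start = 1001L, end = 1121L),
                             pre = 77, post = 181, n = 100000)
  expect_equal(out, data.frame(start = 924L, end = 1302L))
  expect_equal(out$end - out$start, 120 + 77 + 181)

  # left edge clips at the first sample
  out2 <- apply_blink_margins(data.frame(start = 11L, end = 20L),
                              pre = 77, post = 181, n = 1000)
  expect_equal(out2$start, 1L)

  # nearby runs merge into one interval (checked against the mask oracle)
  runs <- data.frame(start = c(101L, 251L), end = c(201L, 301L))
  out3 <- apply_blink_margins(runs, 77, 181, n = 1000)
  expect_equal(nrow(out3), 1)
  flags <- logical(1000)
  flags[c(101:200, 251:300)] <- TRUE
  oracle <- brute_force_margin_mask(flags, 77, 181)
  got <- logical(1000)
  got[out3$start:(out3$end - 1)] <- TRUE
  expect_identical(got, oracle)
})

test_that("margin mask equals the brute-force union on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed + 20)
    n <- 4000
    flags <- runif(n) < 0.005
    runs <- pupilhab:::runs_from_mask(flags)
    out <- apply_blink_margins(runs, 77, 181, n = n)
    got <- logical(n)
    for (i in seq_len(nrow(out))) got[out$start[i]:(out$end[i] - 1)] <- TRUE
    expect_identical(got, brute_force_margin_mask(flags, 77, 181),
                     info = paste("seed", seed))
  }
})

test_that("interpolation is linear, edge-filled, and leaves valid samples alone", {
  # gap of 4 between 3.0 and 3.2
  tr <- pupil_trace(c(3.0, 0, 0, 0, 0, 3.2),
                    valid = c(TRUE, rep(FALSE, 4), TRUE))
  out <- interpolate_gaps(tr)
  expect_equal(out$diameter, c(3.0, 3.04, 3.08, 3.12, 3.16, 3.2),
               tolerance = 1e-12)
  expect_equal(out$valid, tr$valid)  # mask keeps pre-interpolation state

  # no intervals, fully valid: identity
  tr2 <- pupil_trace(c(3.1, 3.2, 3.3))
  expect_identical(interpolate_gaps(tr2)$diameter, tr2$diameter)

  # leading gap takes the first valid value
  tr3 <- pupil_trace(c(0, 0, 3.3, 3.4), valid = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(interpolate_gaps(tr3)$diameter, c(3.3, 3.3, 3.3, 3.4))

  # valid samples are never altered; no gaps remain
  set.seed(31)
  x <- rnorm(500, 3.3, 0.2)
  v <- runif(500) > 0.3
  v[c(1, 500)] <- TRUE
  tr4 <- pupil_trace(x, valid = v)
  out4 <- interpolate_gaps(tr4)
  expect_identical(out4$diameter[v], x[v])
  expect_false(anyNA(out4$diameter))

  expect_error(interpolate_gaps(pupil_trace(c(1, 2),
                                            valid = c(FALSE, FALSE))),
               "unusable")
})

test_that("the sentence filter keeps 60% and discards anything below", {
  fs <- 1200
  # one sentence: onset 2 s, offset 3 s -> epoch [1, 4) = 3600 samples
  sen <- data.frame(block = 1, sentence_index = 1, noise_onset_s = 1,
                    sentence_onset_s = 2, sentence_offset_s = 3,
                    noise_offset_s = 4)
  sch <- session_schedule(sen)
  cfg <- pipeline_config()
  mk <- function(pct_valid) {
    n <- 6 * fs
    valid <- rep(TRUE, n)
    epoch <- 1201:4800  # samples covering times [1 s, 4 s)
    n_invalid <- round(length(epoch) * (1 - pct_valid / 100))
    if (n_invalid > 0) valid[epoch[seq_len(n_invalid)]] <- FALSE
    pupil_trace(rep(3.3, n), valid = valid)
  }
  exact60 <- sentence_validity(mk(60), sch, cfg)
  expect_equal(exact60$pct_valid, 60)
  expect_false(exact60$discarded)
  at59 <- sentence_validity(mk(59), sch, cfg)
  expect_true(at59$discarded)
  full <- sentence_validity(mk(100), sch, cfg)
  expect_equal(full$pct_valid, 100)
  expect_false(full$discarded)
})

test_that("the participant filter excludes above 15% missing, retains at it", {
  cfg <- pipeline_config()
  mk <- function(n_discarded, total = 196)
    data.frame(block = 1, sentence_index = seq_len(total),
               pct_valid = 100, discarded = seq_len(total) <= n_discarded)
  expect_true(participant_filter(mk(30), cfg)$excluded)    # 15.3%
  expect_false(participant_filter(mk(29), cfg)$excluded)   # 14.8%
  expect_false(participant_filter(mk(0), cfg)$excluded)
})

test_that("filters are monotone in epoch validity", {
  fs <- 1200
  sen <- data.frame(block = 1, sentence_index = 1, noise_onset_s = 1,
                    sentence_onset_s = 2, sentence_offset_s = 3,
                    noise_offset_s = 4)
  sch <- session_schedule(sen)
  cfg <- pipeline_config()
  set.seed(41)
  valid <- rep(TRUE, 6 * fs)
  prev_pct <- 100
  for (step in 1:6) {
    valid[sample(1200:4799, 400)] <- FALSE
    led <- sentence_validity(pupil_trace(rep(3.3, 6 * fs), valid = valid),
                             sch, cfg)
    expect_lte(led$pct_valid, prev_pct)
    if (led$pct_valid < 60) expect_true(led$discarded)
    prev_pct <- led$pct_valid
  }
})

test_that("the full chain is clean on a blink-free noiseless session", {
  fix <- clean_session_fixture()
  pp <- run_preprocess(fix$tr, fix$tr, fix$sch, fix$cfg$timeline)
  expect_true(pp$usable)
  expect_equal(sum(pp$sentence_ledger$discarded), 0)
  expect_false(pp$excluded)
  expect_equal(pp$eye, "right")
})

test_that("blinks confined to response intervals leave baselines untouched", {
  fix <- clean_session_fixture()
  cfgb <- fix$cfg
  cfgb$blink_rate_per_min <- 8
  set.seed(43)
  ib <- inject_blinks(fix$tr, cfgb, fix$sch, where = "response_only")
  expect_gt(nrow(ib$intervals), 0)
  pp_blink <- run_preprocess(ib$trace, ib$trace, fix$sch, fix$cfg$timeline)
  pp_clean <- run_preprocess(fix$tr, fix$tr, fix$sch, fix$cfg$timeline)
  # clean-baselines contract: every sentence keeps 100% validity
  expect_true(all(pp_blink$sentence_ledger$pct_valid == 100))
  rb <- extract_block_records(pp_blink, fix$sch, cfg = fix$cfg$timeline)
  rc <- extract_block_records(pp_clean, fix$sch, cfg = fix$cfg$timeline)
  expect_lt(max(abs(rb$pupil_baseline_mm - rc$pupil_baseline_mm)), 1e-9)
})

test_that("obliterating half a sentence discards exactly that sentence", {
  fix <- clean_session_fixture()
  tr <- fix$tr
  sen <- fix$sch$sentences
  k <- 3  # block 1, sentence 3
  on <- sen$sentence_onset_s[k]; off <- sen$sentence_offset_s[k]
  i0 <- floor((on - 1) * 1200) + 1
  i1 <- floor((off + 1) * 1200)
  kill <- i0:round(i0 + 0.5 * (i1 - i0))
  tr$valid[kill] <- FALSE
  pp <- run_preprocess(tr, tr, fix$sch, fix$cfg$timeline)
  led <- pp$sentence_ledger
  expect_true(led$discarded[led$block == 1 & led$sentence_index == 3])
  expect_equal(sum(led$discarded), 1)
  # the block baseline now averages the remaining sentences
  rec <- extract_block_records(pp, fix$sch, cfg = fix$cfg$timeline)
  expect_equal(rec$n_sentences_used[rec$block == 1], 6)
})
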