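# Domain types, configuration and file formats shared by all stages.

#' Construct a pupil trace
#'
#' A `pupil_trace` holds one eye's pupil diameter samples over a session:
#' a regular sample clock, the diameter in millimetres, and a validity mask.
#' Invalid samples may hold any sentinel value; they are never used in
#' statistics.
#'
#' @param diameter numeric vector of pupil diameters (mm).
#' @param valid logical vector, same length as `diameter`. Default all `TRUE`.
#' @param sample_rate sampling frequency in Hz (default 1200, the native rate
#'   of the eye tracker the pipeline was designed around).
#' @param t0 time of the first sample in seconds (default 0).
#' @param eye `"right"` or `"left"`.
#' @return an object of class `pupil_trace`.
#' @seealso [read_pupil_samples()], [select_eye()], [detect_blinks()]
#' @export
pupil_trace <- function(diameter, valid = rep(TRUE, length(diameter)),
                        sample_rate = 1200, t0 = 0,
                        eye = c("right", "left")) {
  eye <- match.arg(eye)
  diameter <- as.numeric(diameter)
  valid <- as.logical(valid)
  if (length(valid) != length(diameter))
    stop("`diameter` and `valid` must have equal length", call. = FALSE)
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number", call. = FALSE)
  valid[is.na(valid)] <- FALSE
  structure(
    list(diameter = diameter, valid = valid,
         sample_rate = as.numeric(sample_rate), t0 = as.numeric(t0),
         eye = eye),
    class = "pupil_trace"
  )
}

#' @export
length.pupil_trace <- function(x) length(x$diameter)

#' @export
print.pupil_trace <- function(x, ...) {
  n <- length(x$diameter)
  cat(sprintf("<pupil_trace: %s eye, %d samples @ %g Hz (%.1f s), %.1f%% valid>\n",
              x$eye, n, x$sample_rate, n / x$sample_rate,
              100 * mean(x$valid)))
  invisible(x)
}

# First sample index (1-based) whose time is >= t_s. Sample i covers time
# t0 + (i-1)/fs; windows are half-open [start_s, end_s).
time_to_index <- function(trace, t_s) {
  as.integer(ceiling((t_s - trace$t0) * trace$sample_rate - 1e-9)) + 1L
}

# 1-based sample indices falling in [start_s, end_s); may be empty.
window_indices <- function(trace, start_s, end_s) {
  i0 <- time_to_index(trace, start_s)
  i1 <- time_to_index(trace, end_s) - 1L
  if (i1 < i0) integer(0) else seq.int(i0, i1)
}

#' Pipeline configuration
#'
#' All tunable constants of the preprocessing and extraction pipeline, with
#' defaults equal to the reference analysis rules: a 1 s (1,200-sample)
#' sliding window and a 3 SD threshold for blink detection, 77 samples of
#' pre-blink and 181 samples of post-blink margin, a 60% minimum of valid
#' samples per sentence, a 15% maximum of missing sentences per participant,
#' and a 1 s pre-sentence baseline window.
#'
#' @param sample_rate_hz eye-tracker sampling rate (Hz).
#' @param window_samples sliding-window length for blink detection (samples).
#' @param sd_k number of window SDs below the window mean that defines the
#'   blink threshold.
#' @param pre_margin_samples,post_margin_samples samples removed before/after
#'   each detected blink run (77 samples is 64 ms and 181 samples is 151 ms at
#'   1,200 Hz; the sample counts are authoritative).
#' @param sentence_valid_min_pct sentences with less than this percentage of
#'   valid samples are discarded.
#' @param participant_missing_max_pct participants with more than this
#'   percentage of discarded sentences are excluded.
#' @param baseline_window_s length of the pre-sentence baseline window (s).
#' @param sentence_epoch_pre_s,sentence_epoch_post_s bounds of the epoch over
#'   which the sentence validity percentage is computed:
#'   `[onset - pre, offset + post)`. The default epoch runs from the start of
#'   the baseline window to the end of the post-sentence background noise.
#' @param n_blocks,n_sentences session structure (28 lists of 7 sentences).
#' @param noise_lead_first_s,noise_lead_other_s background-noise lead time
#'   before the first / remaining sentences of a block (s).
#' @param noise_tail_s background noise continuing after sentence offset (s).
#' @param response_s,last_response_s silent response interval after sentences
#'   1..6 and after the final sentence of a block (s).
#' @param retention_s retention interval before the recall cue (s).
#' @param recall_s nominal free-recall duration used by the synthetic
#'   timeline (s); the live task is self-paced.
#' @param break_s between-block break (s); the reference protocol allowed
#'   5-10 s.
#' @param sentence_duration_s nominal sentence audio duration (s).
#' @param alpha_random,alpha_fixed backward-elimination significance levels
#'   for random and fixed effects.
#' @param step_correct_db,step_incorrect_db,double_step_trials staircase step
#'   sizes (dB) and the number of initial trials with doubled steps.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(sample_rate_hz = 1200,
                            window_samples = 1200,
                            sd_k = 3,
                            pre_margin_samples = 77,
                            post_margin_samples = 181,
                            sentence_valid_min_pct = 60,
                            participant_missing_max_pct = 15,
                            baseline_window_s = 1.0,
                            sentence_epoch_pre_s = 1.0,
                            sentence_epoch_post_s = 1.0,
                            n_blocks = 28,
                            n_sentences = 7,
                            noise_lead_first_s = 3,
                            noise_lead_other_s = 1,
                            noise_tail_s = 1,
                            response_s = 4,
                            last_response_s = 2,
                            retention_s = 4,
                            recall_s = 10,
                            break_s = 7.5,
                            sentence_duration_s = 1.8,
                            alpha_random = 0.1,
                            alpha_fixed = 0.05,
                            step_correct_db = 0.8,
                            step_incorrect_db = 3.2,
                            double_step_trials = 5) {
  cfg <- as.list(environment())
  durs <- c("baseline_window_s", "noise_lead_first_s", "noise_lead_other_s",
            "noise_tail_s", "response_s", "last_response_s", "retention_s",
            "recall_s", "break_s", "sentence_duration_s")
  for (d in durs)
    if (cfg[[d]] <= 0) stop("configured duration `", d, "` must be > 0",
                            call. = FALSE)
  if (cfg$sentence_duration_s <= 0)
    stop("sentence duration must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read an eye-tracker sample file
#'
#' Reads a tab-separated sample stream with columns `time_us`,
#' `pupil_left_mm`, `pupil_right_mm`, `valid_left`, `valid_right` into a pair
#' of aligned [pupil_trace] objects. Rows with unparseable fields are dropped
#' and counted.
#'
#' @param path file path.
#' @param sample_rate_hz sampling rate of the recording (Hz).
#' @return list with elements `left` and `right` ([pupil_trace]) and
#'   `n_malformed` (dropped row count).
#' @export
read_pupil_samples <- function(path, sample_rate_hz = 1200) {
  d <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("time_us", "pupil_left_mm", "pupil_right_mm",
            "valid_left", "valid_right")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("sample file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  bad <- is.na(d$time_us)
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    message(n_malformed, " malformed sample row(s) dropped")
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no usable sample rows in ", path, call. = FALSE)
  if (is.unsorted(d$time_us, strictly = TRUE))
    stop("sample timestamps are not strictly increasing", call. = FALSE)
  t0 <- d$time_us[1] / 1e6
  mk <- function(diam, val, eye) {
    val <- !is.na(val) & val != 0 & !is.na(diam)
    pupil_trace(ifelse(is.na(diam), 0, diam), val,
                sample_rate = sample_rate_hz, t0 = t0, eye = eye)
  }
  list(left = mk(d$pupil_left_mm, d$valid_left, "left"),
       right = mk(d$pupil_right_mm, d$valid_right, "right"),
       n_malformed = n_malformed)
}

#' Write an eye-tracker sample file
#'
#' Inverse of [read_pupil_samples()]; the two traces must be aligned.
#'
#' @param left,right [pupil_trace] objects on a common clock.
#' @param path output file path.
#' @export
write_pupil_samples <- function(left, right, path) {
  stopifnot(inherits(left, "pupil_trace"), inherits(right, "pupil_trace"),
            length(left) == length(right))
  n <- length(left)
  d <- data.frame(
    time_us = round(left$t0 * 1e6 + (seq_len(n) - 1) * 1e6 / left$sample_rate),
    pupil_left_mm = left$diameter,
    pupil_right_mm = right$diameter,
    valid_left = as.integer(left$valid),
    valid_right = as.integer(right$valid)
  )
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a session event table
#'
#' Reads the tab-separated event table describing block/sentence timing and
#' enforces the schedule invariants (strictly increasing times within a
#' block, sentence offset after onset).
#'
#' @param path file path to a table with columns `block`, `sentence_index`,
#'   `noise_onset_s`, `sentence_onset_s`, `sentence_offset_s` and optionally
#'   `noise_offset_s`.
#' @return a `session_schedule`: list with a `sentences` data frame and, when
#'   present in the file, a `blocks` data frame (`retention_onset_s`,
#'   `beep_s`, ...).
#' @export
read_session_events <- function(path) {
  d <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("block", "sentence_index", "noise_onset_s", "sentence_onset_s",
            "sentence_offset_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("event file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"noise_offset_s" %in% names(d))
    d$noise_offset_s <- d$sentence_offset_s + 1
  d <- d[order(d$block, d$sentence_index), , drop = FALSE]
  session_schedule(sentences = d)
}

#' Construct a session schedule
#'
#' @param sentences data frame with one row per sentence (`block`,
#'   `sentence_index`, `noise_onset_s`, `sentence_onset_s`,
#'   `sentence_offset_s`, `noise_offset_s`).
#' @param blocks optional per-block data frame (`block`, `retention_onset_s`,
#'   `beep_s`, `recall_onset_s`, `recall_offset_s`, `start_s`, `end_s`).
#' @return list of class `session_schedule`.
#' @export
session_schedule <- function(sentences, blocks = NULL) {
  req <- c("block", "sentence_index", "noise_onset_s", "sentence_onset_s",
           "sentence_offset_s", "noise_offset_s")
  stopifnot(all(req %in% names(sentences)))
  for (b in unique(sentences$block)) {
    s <- sentences[sentences$block == b, , drop = FALSE]
    tm <- as.vector(t(s[, c("noise_onset_s", "sentence_onset_s",
                            "sentence_offset_s", "noise_offset_s")]))
    if (any(diff(tm) <= 0))
      stop("times within block ", b, " are not strictly increasing",
           call. = FALSE)
  }
  structure(list(sentences = sentences, blocks = blocks),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule: %d blocks, %d sentences, %.1f s>\n",
              length(unique(x$sentences$block)), nrow(x$sentences),
              max(x$sentences$noise_offset_s)))
  invisible(x)
}

#' Write a session event table
#'
#' @param schedule a `session_schedule`.
#' @param path output file path.
#' @export
write_session_events <- function(schedule, path) {
  write.table(schedule$sentences, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read / write participant tables
#'
#' Participant covariates: Reading Span score (`rs_score`, percent), the
#' individual SNR at which the recall test was run (`snr_db`), `age` (years),
#' pure-tone average (`pta_db_hl`), and the `included` flag set by the
#' preprocessing filters.
#'
#' @param path file path (CSV).
#' @return `read_participants()`: a data frame.
#' @export
read_participants <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  need <- c("id", "rs_score", "snr_db")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("participant file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"included" %in% names(d)) d$included <- TRUE
  if (any(d$rs_score < 0 | d$rs_score > 100, na.rm = TRUE))
    stop("rs_score must lie in [0, 100]", call. = FALSE)
  d
}

#' @rdname read_participants
#' @param participants data frame of participant records.
#' @export
write_participants <- function(participants, path) {
  write.csv(participants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write block outcome tables
#'
#' One row per participant x block: the block pupil baseline (mm), the number
#' of sentence baselines it averages, and recall performance (percent of the
#' seven words recalled).
#'
#' @param path file path (CSV).
#' @return `read_block_table()`: a data frame.
#' @export
read_block_table <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  need <- c("participant", "block", "pupil_baseline_mm", "n_sentences_used",
            "recall_pct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("block table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' @rdname read_block_table
#' @param blocks data frame of block records.
#' @export
write_block_table <- function(blocks, path) {
  cols <- c("participant", "block", "pupil_baseline_mm", "n_sentences_used",
            "recall_pct")
  if (nrow(blocks) == 0)
    blocks <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                     cols))
  write.csv(blocks[, cols, drop = FALSE], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write a model report
#'
#' Serializes a fitted mixed-model workflow result to JSON: fixed-effect
#' estimates with 95% confidence intervals, variance components, the Type II
#' Wald chi-square table, marginal and conditional R-squared, variance
#' inflation factors, and the elimination trail when present.
#'
#' @param fit a `swir_lmm` object (see [fit_lmm()]).
#' @param path output file path.
#' @param trail optional elimination trail from [backward_eliminate()].
#' @return the report list, invisibly.
#' @export
write_model_report <- function(fit, path, trail = NULL) {
  stopifnot(inherits(fit, "swir_lmm"))
  co <- coef_table(fit)
  an <- anova_type2(fit)
  r2 <- r2_nakagawa(fit)
  vf <- tryCatch(vif_fixed(fit), error = function(e) NULL)
  report <- list(
    outcome = fit$spec$outcome,
    coefficients = co,
    variance_components = fit$varcorr,
    residual_sd = fit$sigma,
    anova_type2 = an,
    r2_marginal = r2[["marginal"]],
    r2_conditional = r2[["conditional"]],
    vif = vf,
    singular = fit$singular,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_participants = fit$n_groups,
    centering_offsets = fit$offsets
  )
  if (!is.null(trail)) report$elimination_trail <- trail
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(report)
}

#' Read back a model report
#'
#' @param path path to a JSON report written by [write_model_report()].
#' @return the report as a list.
#' @export
read_model_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
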