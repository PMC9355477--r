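# Pupil cleaning: eye selection, sliding-window blink detection, margin
# removal, linear interpolation, and the sentence/participant validity
# filters. Blink runs and intervals are 1-based half-open [start, end).

unusable_error <- function(msg) {
  stop(structure(class = c("pupilhab_unusable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Select the analysis eye
#'
#' The right eye is analysed by default; the left eye is used only when it
#' carries strictly more valid samples.
#'
#' @param left,right aligned [pupil_trace] objects.
#' @return the selected [pupil_trace].
#' @export
select_eye <- function(left, right) {
  stopifnot(inherits(left, "pupil_trace"), inherits(right, "pupil_trace"),
            length(left) == length(right))
  nl <- sum(left$valid); nr <- sum(right$valid)
  if (nl == 0 && nr == 0)
    unusable_error("both eyes fully invalid; participant unusable")
  if (nl > nr) left else right
}

# O(n) centered rolling mean/sd over the currently-valid samples.
# Window for sample i covers indices [i - w/2, i + w/2) (1-based, clipped).
# The series is centered at its global valid mean before the cumulative
# sums so that long traces do not lose precision to cancellation.
rolling_stats <- function(x, valid, window) {
  n <- length(x)
  half_lo <- window %/% 2L
  half_hi <- window - half_lo
  v <- as.numeric(valid)
  mu0 <- if (any(valid)) mean(x[valid]) else 0
  xc <- (x - mu0) * v
  cs1 <- cumsum(v)
  csx <- cumsum(xc)
  csx2 <- cumsum(xc * xc)
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi - 1L)
  at <- function(cs, j) ifelse(j >= 1, cs[pmax(j, 1L)], 0)
  cnt <- at(cs1, hi) - at(cs1, lo - 1L)
  sx <- at(csx, hi) - at(csx, lo - 1L)
  sx2 <- at(csx2, hi) - at(csx2, lo - 1L)
  m <- ifelse(cnt > 0, sx / cnt, NA_real_)
  # sample variance over window (n-1 denominator), guarded against roundoff
  varw <- ifelse(cnt > 1, pmax(0, (sx2 - cnt * m * m) / (cnt - 1)), NA_real_)
  list(mean = m + mu0, sd = sqrt(varw), count = cnt)
}

#' Detect blink samples
#'
#' A sample is flagged as part of a blink when its diameter falls strictly
#' below the window mean minus `k` window SDs, where mean and SD are computed
#' over the valid samples of the 1 s (1,200-sample) sliding window containing
#' the sample. The window is centered and clipped at the trace edges;
#' thresholds come from a single pass over the original validity mask.
#' Consecutive flagged samples merge into runs. The strict inequality is
#' guarded by a relative tolerance of `1e-9` so that floating-point noise on
#' a locally constant trace can never flag a sample.
#'
#' @param trace a [pupil_trace].
#' @param window_samples sliding-window length.
#' @param k threshold in window SDs below the window mean.
#' @return data frame of runs (`start`, `end`; 1-based half-open), with the
#'   per-sample logical flag vector as attribute `"flagged"`.
#' @export
detect_blinks <- function(trace, window_samples = 1200, k = 3) {
  n <- length(trace)
  if (n < 2) stop("trace must hold at least 2 samples", call. = FALSE)
  if (window_samples > n) {
    message("blink window (", window_samples,
            ") longer than trace; shrunk to ", n, " samples")
    window_samples <- n
  }
  st <- rolling_stats(trace$diameter, trace$valid, window_samples)
  # numerical guard: a sample must undercut the threshold by more than
  # floating-point noise; far below any physiological dip
  tol <- 1e-9 * pmax(abs(st$mean), 1)
  flagged <- trace$valid & st$count >= 2 & !is.na(st$sd) &
    trace$diameter < st$mean - k * st$sd - tol
  runs <- runs_from_mask(flagged)
  attr(runs, "flagged") <- flagged
  runs
}

runs_from_mask <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values] + 1L)
}

mask_from_runs <- function(runs, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(runs)))
    mask[runs$start[i]:(runs$end[i] - 1L)] <- TRUE
  mask
}

#' Extend blink runs by removal margins
#'
#' Each detected run `[s, e)` is extended to `[s - pre, e + post)`, clipped to
#' the trace bounds; overlapping extended runs are merged. The defaults
#' remove 77 samples (64 ms at 1,200 Hz) before and 181 samples (151 ms)
#' after each blink.
#'
#' @param runs data frame of runs from [detect_blinks()].
#' @param pre,post margin lengths in samples.
#' @param n trace length in samples.
#' @return data frame of merged intervals (`start`, `end`; 1-based
#'   half-open).
#' @export
apply_blink_margins <- function(runs, pre = 77, post = 181, n) {
  if (nrow(runs) == 0)
    return(data.frame(start = integer(0), end = integer(0)))
  stopifnot(all(runs$start >= 1), all(runs$end <= n + 1L))
  s <- pmax(1L, as.integer(runs$start) - as.integer(pre))
  e <- pmin(n + 1L, as.integer(runs$end) + as.integer(post))
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Interpolate invalidated samples
#'
#' Replaces samples that are invalid (tracker-invalid or inside the supplied
#' blink intervals) by linear interpolation between the nearest valid
#' neighbours; leading/trailing gaps take the nearest valid value. The
#' returned trace's validity mask keeps the *pre-interpolation* state, which
#' the sentence validity filter consumes.
#'
#' @param trace a [pupil_trace].
#' @param intervals data frame of intervals to invalidate (may be empty).
#' @return a [pupil_trace] with gap-free `diameter` and the pre-interpolation
#'   `valid` mask.
#' @export
interpolate_gaps <- function(trace, intervals = NULL) {
  n <- length(trace)
  invalid <- !trace$valid
  if (!is.null(intervals) && nrow(intervals) > 0)
    invalid <- invalid | mask_from_runs(intervals, n)
  ok <- which(!invalid)
  if (length(ok) == 0)
    unusable_error("no valid samples remain; trace unusable")
  out <- trace
  out$valid <- !invalid
  if (length(ok) < n) {
    if (length(ok) == 1) {
      out$diameter <- rep(trace$diameter[ok], n)
    } else {
      out$diameter <- approx(x = ok, y = trace$diameter[ok], xout = seq_len(n),
                             method = "linear", rule = 2)$y
    }
  }
  out
}

#' Sentence-level validity filter
#'
#' Computes, for each sentence, the percentage of valid samples over the
#' sentence epoch `[onset - pre, offset + post)` (by default the baseline
#' window through the end of the post-sentence background noise), using the
#' pre-interpolation validity mask. Sentences with less than
#' `sentence_valid_min_pct` (default 60%) valid data are discarded; an epoch
#' lying outside the trace is discarded outright.
#'
#' @param trace an interpolated [pupil_trace] (mask = pre-interpolation
#'   state).
#' @param schedule a `session_schedule`.
#' @param cfg a [pipeline_config()].
#' @return data frame `block`, `sentence_index`, `pct_valid`, `discarded`.
#' @export
sentence_validity <- function(trace, schedule, cfg = pipeline_config()) {
  sen <- schedule$sentences
  out <- sen[, c("block", "sentence_index")]
  out$pct_valid <- NA_real_
  out$discarded <- TRUE
  n <- length(trace)
  for (i in seq_len(nrow(sen))) {
    idx <- window_indices(trace,
                          sen$sentence_onset_s[i] - cfg$sentence_epoch_pre_s,
                          sen$sentence_offset_s[i] + cfg$sentence_epoch_post_s)
    if (length(idx) == 0 || min(idx) < 1 || max(idx) > n) next
    pct <- 100 * mean(trace$valid[idx])
    out$pct_valid[i] <- pct
    out$discarded[i] <- pct < cfg$sentence_valid_min_pct
  }
  out
}

#' Participant-level exclusion filter
#'
#' A participant is excluded when strictly more than
#' `participant_missing_max_pct` (default 15%) of their sentences were
#' discarded; exactly 15% is retained.
#'
#' @param sentence_ledger per-sentence ledger from [sentence_validity()].
#' @param cfg a [pipeline_config()].
#' @return list `pct_missing`, `excluded`.
#' @export
participant_filter <- function(sentence_ledger, cfg = pipeline_config()) {
  pct <- 100 * mean(sentence_ledger$discarded)
  list(pct_missing = pct,
       excluded = pct > cfg$participant_missing_max_pct)
}

#' Run the full preprocessing chain on one session
#'
#' Stage order: eye selection, blink detection, margin extension, invalid-
#' sample marking, linear interpolation, sentence validity, participant
#' filter.
#'
#' @param left,right aligned [pupil_trace] objects for the two eyes.
#' @param schedule the session's `session_schedule`.
#' @param cfg a [pipeline_config()].
#' @return list of class `swir_preprocessed`: `trace` (cleaned, interpolated
#'   selected-eye trace with the pre-interpolation validity mask),
#'   `blink_intervals`, `sentence_ledger`, `pct_missing`, `excluded`,
#'   `usable`, `eye`, `config`.
#' @export
run_preprocess <- function(left, right, schedule, cfg = pipeline_config()) {
  res <- tryCatch({
    eye <- select_eye(left, right)
    runs <- detect_blinks(eye, cfg$window_samples, cfg$sd_k)
    intervals <- apply_blink_margins(runs, cfg$pre_margin_samples,
                                     cfg$post_margin_samples, length(eye))
    cleaned <- interpolate_gaps(eye, intervals)
    ledger <- sentence_validity(cleaned, schedule, cfg)
    pf <- participant_filter(ledger, cfg)
    list(trace = cleaned, blink_intervals = intervals,
         sentence_ledger = ledger, pct_missing = pf$pct_missing,
         excluded = pf$excluded, usable = TRUE, eye = cleaned$eye,
         config = cfg)
  }, pupilhab_unusable = function(e) {
    list(trace = NULL, blink_intervals = NULL, sentence_ledger = NULL,
         pct_missing = 100, excluded = TRUE, usable = FALSE, eye = NA,
         config = cfg, reason = conditionMessage(e))
  })
  class(res) <- "swir_preprocessed"
  res
}
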