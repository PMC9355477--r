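# Sentence- and block-level baseline extraction, recall scoring, and epoch
# grand-averaging.

#' Sentence baseline pupil diameter
#'
#' The mean pupil diameter over the half-open window `[onset - window_s,
#' onset)`, i.e. the second of background noise immediately preceding the
#' sentence. The onset sample itself is excluded.
#'
#' @param trace an interpolated [pupil_trace].
#' @param sentence_onset_s sentence onset time (s).
#' @param window_s window length (s), default 1.
#' @return baseline in mm, or `NA` when the window lies outside the trace.
#' @export
sentence_baseline <- function(trace, sentence_onset_s, window_s = 1.0) {
  idx <- window_indices(trace, sentence_onset_s - window_s, sentence_onset_s)
  if (length(idx) == 0 || min(idx) < 1 || max(idx) > length(trace))
    return(NA_real_)
  mean(trace$diameter[idx])
}

#' Block pupil baseline
#'
#' The mean of the retained sentence baselines of one block. Averaging over
#' the seven sentences minimises the within-block memory-load ramp, leaving a
#' per-block index of tonic arousal.
#'
#' @param values sentence baselines (mm), one per sentence.
#' @param used logical: which sentences were retained by the validity filter.
#' @return list `value` (mm; `NA` when no sentence is usable) and `n_used`.
#' @export
block_pupil_baseline <- function(values, used = rep(TRUE, length(values))) {
  keep <- used & !is.na(values)
  if (!any(keep)) return(list(value = NA_real_, n_used = 0L))
  list(value = mean(values[keep]), n_used = sum(keep))
}

#' Score free recall for one block
#'
#' Percentage of the seven repeated words that were recalled, order-free and
#' case-insensitive, duplicates counted once. The reference is the word the
#' participant *repeated* after each sentence (not the stimulus word), so a
#' misperceived word that is later recalled still scores.
#'
#' @param recalled character vector of recalled words (any order).
#' @param target_words the words repeated during the block.
#' @return recall score in percent.
#' @export
recall_score <- function(recalled, target_words) {
  tw <- tolower(trimws(target_words))
  rc <- unique(tolower(trimws(recalled)))
  100 * sum(tw %in% rc) / length(tw)
}

#' Extract block records from a preprocessed session
#'
#' Computes the sentence baselines of every retained sentence and averages
#' them per block. Blocks with zero retained sentences yield no row (missing,
#' not zero, so they cannot bias the mixed model).
#'
#' @param prep a `swir_preprocessed` object from [run_preprocess()].
#' @param schedule the session's `session_schedule`.
#' @param participant participant identifier for the output rows.
#' @param recall optional data frame `block`, `recall_pct`.
#' @param cfg a [pipeline_config()].
#' @return data frame `participant`, `block`, `pupil_baseline_mm`,
#'   `n_sentences_used`, `recall_pct`.
#' @export
extract_block_records <- function(prep, schedule, participant = 1L,
                                  recall = NULL, cfg = pipeline_config()) {
  if (!isTRUE(prep$usable)) {
    return(data.frame(participant = integer(0), block = integer(0),
                      pupil_baseline_mm = numeric(0),
                      n_sentences_used = integer(0),
                      recall_pct = numeric(0)))
  }
  sen <- schedule$sentences
  led <- prep$sentence_ledger
  rows <- list()
  for (b in unique(sen$block)) {
    sb <- sen[sen$block == b, , drop = FALSE]
    lb <- led[led$block == b, , drop = FALSE]
    vals <- vapply(sb$sentence_onset_s, function(on)
      sentence_baseline(prep$trace, on, cfg$baseline_window_s), numeric(1))
    used <- !lb$discarded[match(sb$sentence_index, lb$sentence_index)]
    bb <- block_pupil_baseline(vals, used)
    if (bb$n_used == 0) next
    rp <- if (!is.null(recall)) recall$recall_pct[match(b, recall$block)]
          else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      participant = participant, block = b, pupil_baseline_mm = bb$value,
      n_sentences_used = bb$n_used, recall_pct = rp)
  }
  if (length(rows) == 0)
    return(data.frame(participant = integer(0), block = integer(0),
                      pupil_baseline_mm = numeric(0),
                      n_sentences_used = integer(0), recall_pct = numeric(0)))
  do.call(rbind, rows)
}

#' Grand-average pupil time course across sentence epochs
#'
#' Aligns every sentence epoch at its sentence onset, spanning from the start
#' of the baseline window (1 s before onset) to the onset of the next
#' sentence's background noise, and returns the per-timepoint mean with a
#' normal-approximation 95% confidence band. Ragged epochs are truncated to
#' the shortest.
#'
#' @param traces a single interpolated [pupil_trace] or a list of them (one
#'   per session sharing `schedule`).
#' @param schedule a `session_schedule`.
#' @param cfg a [pipeline_config()].
#' @return data frame `time_s` (0 = sentence onset), `mean`, `ci_lo`,
#'   `ci_hi`, `n_epochs`.
#' @export
epoch_grand_average <- function(traces, schedule, cfg = pipeline_config()) {
  if (inherits(traces, "pupil_trace")) traces <- list(traces)
  sen <- schedule$sentences
  pre <- cfg$baseline_window_s
  epochs <- list()
  for (tr in traces) {
    for (i in seq_len(nrow(sen))) {
      end_s <- if (i < nrow(sen) && sen$block[i + 1] == sen$block[i])
        sen$noise_onset_s[i + 1]
      else if (!is.null(schedule$blocks))
        schedule$blocks$retention_onset_s[match(sen$block[i],
                                                schedule$blocks$block)]
      else sen$noise_offset_s[i] + 1
      idx <- window_indices(tr, sen$sentence_onset_s[i] - pre, end_s)
      if (length(idx) == 0 || min(idx) < 1 || max(idx) > length(tr)) next
      epochs[[length(epochs) + 1L]] <- tr$diameter[idx]
    }
  }
  if (length(epochs) < 2)
    stop("need at least 2 sentence epochs to average", call. = FALSE)
  len <- min(lengths(epochs))
  m <- do.call(rbind, lapply(epochs, function(e) e[seq_len(len)]))
  mu <- colMeans(m)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  fs <- traces[[1]]$sample_rate
  data.frame(time_s = (seq_len(len) - 1) / fs - pre,
             mean = mu, ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
             n_epochs = nrow(m))
}
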