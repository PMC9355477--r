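# The two SNR-setting procedures: the weighted up-down HINT staircase
# targeting 80% sentence intelligibility, and the SWIR training-list
# adjustment that follows it. Step arithmetic is carried in integer tenths of
# a dB so accumulated SNRs are exact.

#' Weighted up-down HINT staircase
#'
#' Both target and background noise start at 70 dB SPL (SNR 0 dB); the noise
#' stays fixed while the target level tracks the responses. A correct
#' repetition lowers the SNR by 0.8 dB, an incorrect one raises it by 3.2 dB,
#' and for the first five sentences the step size is doubled. The asymmetric
#' 0.8/3.2 steps place the equilibrium at 80% intelligibility
#' (p = 3.2 / (3.2 + 0.8)). The update is applied after every response,
#' including the first.
#'
#' @param responses logical vector of correct/incorrect sentence repetitions.
#'   Alternatively supply a `listener`.
#' @param listener a function `(snr_db) -> logical`, e.g.
#'   [psychometric_listener()]; used when `responses` is `NULL`.
#' @param n_trials number of trials when simulating with a `listener`.
#' @param start_snr_db starting SNR (dB).
#' @param cfg a [pipeline_config()] carrying the step constants.
#' @param final `"last"` (SNR after the final update; default) or
#'   `"mean_last_k"` (mean of the last `k` presented SNRs).
#' @param k window for `final = "mean_last_k"`.
#' @return list `final_snr_db` and `history` (data frame `trial`, `snr_db`
#'   presented, `correct`, `step_db` applied).
#' @export
hint_staircase <- function(responses = NULL, listener = NULL,
                           n_trials = if (!is.null(responses))
                             length(responses) else 20,
                           start_snr_db = 0, cfg = pipeline_config(),
                           final = c("last", "mean_last_k"), k = 10) {
  final <- match.arg(final)
  if (is.null(responses) && is.null(listener))
    stop("supply `responses` or a `listener`", call. = FALSE)
  if (!is.null(responses) && length(responses) == 0)
    stop("empty response sequence", call. = FALSE)
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  dn10 <- as.integer(round(cfg$step_correct_db * 10))
  up10 <- as.integer(round(cfg$step_incorrect_db * 10))
  snr10 <- as.integer(round(start_snr_db * 10))
  hist <- data.frame(trial = seq_len(n_trials), snr_db = NA_real_,
                     correct = NA, step_db = NA_real_)
  for (t in seq_len(n_trials)) {
    hist$snr_db[t] <- snr10 / 10
    correct <- if (!is.null(responses)) isTRUE(responses[t])
               else isTRUE(listener(snr10 / 10))
    step10 <- if (correct) -dn10 else up10
    if (t <= cfg$double_step_trials) step10 <- step10 * 2L
    snr10 <- snr10 + step10
    hist$correct[t] <- correct
    hist$step_db[t] <- step10 / 10
  }
  final_snr <- switch(final,
    last = snr10 / 10,
    mean_last_k = mean(tail(hist$snr_db, k)))
  list(final_snr_db = final_snr, history = hist)
}

#' SWIR training-list SNR adjustment
#'
#' After the staircase, four training lists of seven sentences verify that
#' ~95% word identification is reached. After each list the SNR is adjusted
#' by the number of correctly repeated final words: 6-7 correct leaves the
#' SNR unchanged, 4-5 raises it by 1 dB, 0-3 raises it by 2 dB. Adjustments
#' are applied sequentially; the SNR after the fourth list is used for the
#' rest of the test.
#'
#' @param start_snr_db SNR from the staircase (dB).
#' @param correct_counts integer vector (length 4 in the standard protocol)
#'   of correctly repeated words per list, each in 0..7.
#' @return final SNR in dB.
#' @export
swir_training_adjust <- function(start_snr_db, correct_counts) {
  if (any(correct_counts < 0 | correct_counts > 7))
    stop("word counts must lie in 0..7", call. = FALSE)
  delta <- ifelse(correct_counts >= 6, 0, ifelse(correct_counts >= 4, 1, 2))
  (round(start_snr_db * 10) + 10 * sum(delta)) / 10
}

#' Simulate the complete SNR-setting procedure
#'
#' Composes the staircase (simulated sentence repetitions from the listener's
#' psychometric function) with the four training lists (simulated word
#' identifications). Word identification uses the sentence psychometric
#' shifted by `log(19/4)` on the logit scale, so that word identification is
#' 95% at the SNR where sentence intelligibility is 80% — the calibration the
#' SWIR protocol assumes.
#'
#' @param psychometric list with `srt_db` and `slope_per_db`.
#' @param cfg a [pipeline_config()] for the step constants.
#' @param n_trials staircase length.
#' @param n_lists,words_per_list training structure.
#' @return list `snr_db` (SNR used for the remainder of the test),
#'   `hint_snr_db`, `history`, `training_counts`.
#' @export
simulate_snr_setting <- function(psychometric = list(srt_db = 3.9,
                                                     slope_per_db = 0.5),
                                 cfg = pipeline_config(), n_trials = 20,
                                 n_lists = 4, words_per_list = 7) {
  listener <- psychometric_listener(psychometric$srt_db,
                                    psychometric$slope_per_db)
  st <- hint_staircase(listener = listener, n_trials = n_trials, cfg = cfg)
  snr <- st$final_snr_db
  counts <- integer(n_lists)
  word_offset <- log(19 / 4)  # 95% words where sentences reach 80%
  for (l in seq_len(n_lists)) {
    p_word <- plogis((snr - psychometric$srt_db) * psychometric$slope_per_db +
                       word_offset)
    counts[l] <- rbinom(1, words_per_list, p_word)
    snr <- swir_training_adjust(snr, counts[l])
  }
  list(snr_db = snr, hint_snr_db = st$final_snr_db, history = st$history,
       training_counts = counts)
}
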