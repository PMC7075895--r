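# Recording pre-processing: head/tail trimming and interviewer excision.

#' Trim a recording and excise interviewer segments
#'
#' Removes the initial and final 30 s of the recording (their acoustics are
#' unreliable: microphone handling, instructions, wrap-up) and excises any
#' annotated interviewer intervals, splicing the remainder together so that
#' duration statistics reflect participant speech only.
#'
#' @param wave numeric waveform.
#' @param sample_rate Hz.
#' @param annotations optional data.frame with columns `start_s`, `end_s`
#'   (interviewer intervals, in original-recording time).
#' @param trim_s seconds removed from each end (default 30).
#' @return trimmed waveform; attribute `analyzed_duration_s` gives its
#'   duration.
#' @export
preprocess_audio <- function(wave, sample_rate, annotations = NULL,
                             trim_s = 30) {
  dur <- length(wave) / sample_rate
  if (dur <= 2 * trim_s)
    stop("recording must be longer than ", 2 * trim_s,
         " s to survive trimming (got ", round(dur, 1), " s)", call. = FALSE)
  keep <- rep(TRUE, length(wave))
  i0 <- round(trim_s * sample_rate)
  keep[seq_len(i0)] <- FALSE
  keep[(length(wave) - i0 + 1):length(wave)] <- FALSE
  if (!is.null(annotations) && nrow(annotations) > 0) {
    for (k in seq_len(nrow(annotations))) {
      a <- max(1, floor(annotations$start_s[k] * sample_rate) + 1)
      b <- min(length(wave), ceiling(annotations$end_s[k] * sample_rate))
      if (b >= a) keep[a:b] <- FALSE
    }
  }
  out <- wave[keep]
  attr(out, "analyzed_duration_s") <- length(out) / sample_rate
  out
}
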