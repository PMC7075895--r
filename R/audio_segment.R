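# Intensity-based pause/utterance segmentation and syllable nuclei.

#' Segment pauses, utterances, and syllable nuclei
#'
#' Intensity-threshold segmentation: frames whose intensity falls more than
#' `silence_db` below the recording's peak intensity are silent; silent
#' runs of at least `min_pause_s` are pauses, the rest is speech, and
#' speech runs shorter than `min_utt_s` are dropped. Syllable nuclei are
#' intensity peaks at least `nucleus_db` above the surrounding dips within
#' speech regions.
#'
#' @param wave preprocessed waveform.
#' @param sample_rate Hz.
#' @param silence_db threshold below peak intensity, dB (default 25).
#' @param min_pause_s minimum pause duration, s (default 0.3).
#' @param min_utt_s minimum utterance duration, s (default 0.1).
#' @param nucleus_db peak prominence for a syllable nucleus, dB.
#' @return list of class `sc_segmentation`: `pauses` and `utterances`
#'   (data.frames with `start`, `end` in s), `n_nuclei`, `duration_s`,
#'   `speech_rate` (nuclei per second of total time), `articulation_rate`
#'   (nuclei per second of phonation time), `phonation_ratio`.
#' @export
segment_pauses <- function(wave, sample_rate, silence_db = 25,
                           min_pause_s = 0.3, min_utt_s = 0.1,
                           nucleus_db = 2) {
  hop <- round(0.01 * sample_rate)
  flen <- round(0.03 * sample_rate)
  fr <- frame_signal(wave, flen, hop)
  dur <- length(wave) / sample_rate
  if (ncol(fr) == 0) {
    return(structure(list(
      pauses = data.frame(start = 0, end = dur),
      utterances = data.frame(start = numeric(0), end = numeric(0)),
      n_nuclei = 0L, duration_s = dur, speech_rate = 0,
      articulation_rate = NA_real_, phonation_ratio = 0),
      class = "sc_segmentation"))
  }
  intensity <- 10 * log10(pmax(colMeans(fr^2), 1e-12))
  tframe <- ((seq_len(ncol(fr)) - 1) * hop + flen / 2) / sample_rate
  hop_s <- hop / sample_rate
  speech <- intensity > max(intensity) - silence_db
  # frames at the intensity floor are digital silence; without this an
  # all-silent recording would count as speech (every frame ties the peak)
  speech[intensity <= 10 * log10(1e-12) + 1e-6] <- FALSE
  # classify runs
  r <- rle(speech)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg_start <- (starts - 1) * hop_s
  seg_end <- ends * hop_s
  seg_end[length(seg_end)] <- dur
  is_pause <- !r$values & (seg_end - seg_start) >= min_pause_s
  # short silent gaps are absorbed into speech
  keep_speech <- !is_pause
  merged <- list()
  k <- 1
  while (k <= length(is_pause)) {
    if (keep_speech[k]) {
      j <- k
      while (j + 1 <= length(is_pause) && keep_speech[j + 1]) j <- j + 1
      merged[[length(merged) + 1]] <- c(seg_start[k], seg_end[j], 1)
      k <- j + 1
    } else {
      merged[[length(merged) + 1]] <- c(seg_start[k], seg_end[k], 0)
      k <- k + 1
    }
  }
  m <- do.call(rbind, merged)
  utt <- m[m[, 3] == 1 & (m[, 2] - m[, 1]) >= min_utt_s, , drop = FALSE]
  pau <- m[m[, 3] == 0, , drop = FALSE]
  utterances <- data.frame(start = utt[, 1], end = utt[, 2])
  pauses <- data.frame(start = pau[, 1], end = pau[, 2])
  # syllable nuclei: peaks of the smoothed intensity contour inside
  # utterances, where consecutive nuclei must be separated by a dip of at
  # least `nucleus_db` below the lower peak (otherwise only the higher
  # peak survives) — the standard intensity-based nucleus rule
  n_nuclei <- 0L
  if (nrow(utterances) > 0) {
    sm <- as.numeric(stats::filter(intensity, rep(1 / 5, 5), sides = 2))
    sm[is.na(sm)] <- intensity[is.na(sm)]
    pk <- which(diff(sign(diff(sm))) < 0) + 1
    pk <- pk[speech[pk]]
    in_utt <- vapply(tframe[pk], function(t)
      any(t >= utterances$start & t <= utterances$end), logical(1))
    pk <- pk[in_utt]
    accepted <- integer(0)
    for (p in pk) {
      if (length(accepted) == 0) {
        accepted <- p
        next
      }
      q <- accepted[length(accepted)]
      dip <- min(sm[q:p])
      if (min(sm[p], sm[q]) - dip >= nucleus_db) {
        accepted <- c(accepted, p)
      } else if (sm[p] > sm[q]) {
        accepted[length(accepted)] <- p
      }
    }
    n_nuclei <- length(accepted)
  }
  phon_time <- sum(utterances$end - utterances$start)
  structure(list(
    pauses = pauses, utterances = utterances, n_nuclei = n_nuclei,
    duration_s = dur,
    speech_rate = n_nuclei / dur,
    articulation_rate = if (phon_time > 0) n_nuclei / phon_time else NA_real_,
    phonation_ratio = phon_time / dur), class = "sc_segmentation")
}
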