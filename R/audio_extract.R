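# Assembly of the canonical 88-feature acoustic vector.

#' Distributional descriptors of a series
#'
#' Descriptor legend: a = median, b = IQR, c = excess kurtosis,
#' d = skewness, e = 5th percentile, f = 50th percentile,
#' g = 95th percentile. Order statistics use linear interpolation between
#' closest ranks; skewness and kurtosis of a constant series are 0 by
#' convention.
#'
#' @param x numeric series.
#' @param descriptors subset of `c("a","b","c","d","e","f","g")`.
#' @return named numeric vector (names = descriptors); all NA for an empty
#'   series.
#' @export
summarize_series <- function(x, descriptors = c("a", "b", "c", "d", "e",
                                                "g")) {
  x <- x[is.finite(x)]
  out <- stats::setNames(rep(NA_real_, length(descriptors)), descriptors)
  if (length(x) == 0) return(out)
  s <- stats::sd(x)
  m <- mean(x)
  skew <- if (length(x) < 2 || s == 0) 0 else mean((x - m)^3) / s^3
  kurt <- if (length(x) < 2 || s == 0) 0 else mean((x - m)^4) / s^4 - 3
  vals <- c(a = unname(stats::median(x)),
            b = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)),
            c = kurt, d = skew,
            e = unname(stats::quantile(x, 0.05)),
            f = unname(stats::median(x)),
            g = unname(stats::quantile(x, 0.95)))
  out[] <- vals[descriptors]
  out
}

#' The canonical acoustic feature inventory
#'
#' The 88 feature names emitted by [extract_acoustic()], loaded from the
#' versioned inventory file shipped with the package.
#'
#' @param version inventory version.
#' @return character vector of 88 names.
#' @export
acoustic_inventory <- function(version = 1) {
  path <- system.file("extdata",
                      sprintf("acoustic_inventory_v%d.txt", version),
                      package = "speechcontrast", mustWork = TRUE)
  lines <- readLines(path)
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' Extract the 88-feature acoustic vector from a recording
#'
#' Runs the full acoustic chain: head/tail trimming and interviewer
#' excision, voicing/pitch tracking, jitter/shimmer/voice-break and noise
#' measures, pause/utterance segmentation, long-term spectrum and MFCCs,
#' and formant vowel-space geometry, then summarizes each series with its
#' designated descriptors. Always emits exactly the 88 inventory names;
#' features that cannot be computed are NA (imputed later at
#' table-assembly time).
#'
#' @param wave waveform (raw recording; trimming is applied here unless
#'   `preprocessed = TRUE`).
#' @param sample_rate Hz.
#' @param annotations optional interviewer intervals (`start_s`, `end_s`).
#' @param f0_band pitch search band, Hz.
#' @param preprocessed set TRUE if `wave` is already trimmed/excised.
#' @return named numeric vector, exactly the [acoustic_inventory()] names.
#' @export
extract_acoustic <- function(wave, sample_rate, annotations = NULL,
                             f0_band = c(60, 400), preprocessed = FALSE) {
  inv <- acoustic_inventory()
  out <- stats::setNames(rep(NA_real_, length(inv)), inv)
  if (!preprocessed)
    wave <- preprocess_audio(wave, sample_rate, annotations)
  track <- track_voicing(wave, sample_rate, f0_band = f0_band)
  # pitch distribution
  if (!track$empty) {
    out[paste0("Pitch_", c("a", "b", "c", "d", "e", "g"))] <-
      summarize_series(track$f0[track$voiced])
  }
  js <- jitter_shimmer(track)
  out[c("Jitter_h", "Jitter_ppq5", "Shimmer_h", "Shimmer_apq5",
        "VoiceBreaks_n", "VoiceBreaks_deg")] <-
    unlist(js[c("Jitter_h", "Jitter_ppq5", "Shimmer_h", "Shimmer_apq5",
                "VoiceBreaks_n", "VoiceBreaks_deg")])
  nm <- noise_measures(track)
  out[c("HNR", "NHR", "MeanAutocorr")] <- unlist(nm)
  sp <- spectral_block(wave, sample_rate)
  out[c("MaxdB", "MaxFreq", "Energy", "Slope")] <-
    c(sp$MaxdB, sp$MaxFreq, sp$Energy, sp$Slope)
  if (ncol(sp$mfcc) > 0) {
    for (k in 1:16) {
      s <- summarize_series(sp$mfcc[k, ], c("a", "b"))
      out[sprintf("MFCC%02d_a", k)] <- s["a"]
      out[sprintf("MFCC%02d_b", k)] <- s["b"]
    }
  }
  fb <- formant_block(wave, sample_rate, track)
  for (fi in 1:3) {
    ser <- fb[[paste0("F", fi)]]
    if (length(ser) > 0)
      out[paste0("F", fi, "_", c("a", "b", "c", "d", "e", "g"))] <-
        summarize_series(ser)
  }
  out[c("TotalArea", "AIUArea", "Angle")] <-
    c(fb$TotalArea, fb$AIUArea, fb$Angle)
  seg <- segment_pauses(wave, sample_rate)
  pd <- seg$pauses$end - seg$pauses$start
  if (length(pd) > 0) {
    out[paste0("PauseDist_", c("a", "b", "c", "d", "e", "g"))] <-
      summarize_series(pd)
    out["PauseMax"] <- max(pd)
  } else {
    out[paste0("PauseDist_", c("a", "b", "c", "d", "e", "g"))] <- 0
    out["PauseMax"] <- 0
  }
  ud <- seg$utterances$end - seg$utterances$start
  if (length(ud) > 0)
    out[paste0("UttDist_", c("a", "b", "e", "g"))] <-
      summarize_series(ud, c("a", "b", "e", "g"))
  out["PauseCount"] <- length(pd)
  out["Unvoiced_i"] <- 100 * (1 - track$voiced_fraction)
  out["SpeechRate"] <- seg$speech_rate
  out["ArticRate"] <- seg$articulation_rate
  out["PhonationRatio"] <- seg$phonation_ratio
  out
}

#' Extract acoustic features for one manifest record
#'
#' Reads the WAV and annotation files referenced by a manifest row; a
#' corrupt or unreadable recording yields NULL with a logged reason rather
#' than an error, mirroring the exclusion of unusable sessions.
#'
#' @param record one manifest row (list or single-row data.frame).
#' @param ... passed to [extract_acoustic()].
#' @return named numeric vector of 88 features, or NULL (with a warning)
#'   when the recording is unusable.
#' @export
extract_acoustic_record <- function(record, ...) {
  audio <- tryCatch(read_wav(record$audio_path), error = function(e) e)
  if (inherits(audio, "error")) {
    warning("record skipped (unusable audio ", record$audio_path, "): ",
            conditionMessage(audio), call. = FALSE)
    return(NULL)
  }
  ann <- NULL
  if (!is.null(record$annotation_path) && !is.na(record$annotation_path) &&
      nzchar(record$annotation_path))
    ann <- read.csv(record$annotation_path)
  extract_acoustic(audio$wave, audio$sample_rate, annotations = ann, ...)
}
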