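# Source-filter voice synthesis.
#
# The synthetic voice is the simplest signal on which every acoustic feature
# of the extraction stage is well defined: a glottal impulse train with
# cycle-wise period perturbation (jitter) and amplitude perturbation
# (shimmer), filtered through three second-order formant resonators cycling
# among the vowel targets /a/, /i/, /u/, interleaved with log-normally
# distributed silent pauses, over a small additive noise floor.

vowel_targets <- function() {
  # F1, F2, F3 (Hz) and bandwidths; /a/, /i/, /u/
  list(
    a = list(f = c(800, 1200, 2500), bw = c(80, 90, 120)),
    i = list(f = c(300, 2300, 3000), bw = c(60, 90, 150)),
    u = list(f = c(350, 800, 2250), bw = c(60, 80, 140))
  )
}

# Second-order resonator coefficients (denominator) at centre f, bandwidth bw
resonator_coef <- function(f, bw, sr) {
  r <- exp(-pi * bw / sr)
  c(1, -2 * r * cos(2 * pi * f / sr), r^2)
}

# Filter excitation through the cascade of three formant resonators
apply_formants <- function(x, vowel, sr) {
  tg <- vowel_targets()[[vowel]]
  for (k in 1:3) {
    a <- resonator_coef(tg$f[k], tg$bw[k], sr)
    x <- as.numeric(stats::filter(x, filter = -a[2:3], method = "recursive"))
  }
  x
}

#' Subject voice/language profile for the synthetic cohort
#'
#' Encodes the between-speaker variability (baseline pitch, jitter, pause
#' habits, verbosity, topical interests) that motivates the within-subject
#' baseline correction in the classification stage.
#'
#' @param base_f0 median fundamental frequency, Hz.
#' @param base_jitter baseline cycle-to-cycle period perturbation, percent.
#' @param base_shimmer baseline cycle amplitude perturbation, percent.
#' @param base_pause_rate pauses per minute of speech.
#' @param base_speech_rate syllables per second (drives vowel cycling).
#' @param topic_preference probability vector over background topics.
#' @param verbosity expected transcript token count.
#' @return list of class `sc_profile`.
#' @export
subject_profile <- function(base_f0 = 120, base_jitter = 1, base_shimmer = 4,
                            base_pause_rate = 8, base_speech_rate = 4,
                            topic_preference = NULL, verbosity = 400) {
  stopifnot(base_f0 > 0, base_jitter >= 0, base_shimmer >= 0,
            base_pause_rate >= 0, base_speech_rate > 0, verbosity > 0)
  if (!is.null(topic_preference)) {
    stopifnot(all(topic_preference >= 0), sum(topic_preference) > 0)
    topic_preference <- topic_preference / sum(topic_preference)
  }
  structure(list(base_f0 = base_f0, base_jitter = base_jitter,
                 base_shimmer = base_shimmer,
                 base_pause_rate = base_pause_rate,
                 base_speech_rate = base_speech_rate,
                 topic_preference = topic_preference,
                 verbosity = verbosity),
            class = "sc_profile")
}

# Draw the utterance/pause timeline. Returns data.frame(start, end, type).
draw_timeline <- function(duration_s, pause_rate, pause_meanlog = log(0.5),
                          pause_sdlog = 0.5) {
  if (pause_rate <= 0)
    return(data.frame(start = 0, end = duration_s, type = "utterance",
                      stringsAsFactors = FALSE))
  mean_pause <- exp(pause_meanlog + pause_sdlog^2 / 2)
  mean_utt <- max(60 / pause_rate - mean_pause, 0.8)
  segs <- list()
  t <- 0
  repeat {
    u <- rlnorm(1, log(mean_utt), 0.3)
    segs[[length(segs) + 1]] <- c(t, min(t + u, duration_s), 1)
    t <- t + u
    if (t >= duration_s) break
    p <- rlnorm(1, pause_meanlog, pause_sdlog)
    segs[[length(segs) + 1]] <- c(t, min(t + p, duration_s), 2)
    t <- t + p
    if (t >= duration_s) break
  }
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1], end = m[, 2],
             type = c("utterance", "pause")[m[, 3]],
             stringsAsFactors = FALSE)
}

# Synthesize one utterance; returns list(wave, periods, amps)
synth_utterance <- function(dur, f0, jitter_pct, shimmer_pct, speech_rate,
                            sr) {
  # N(0,1) cycle perturbations: E|T[i+1]-T[i]| / E T = sigma * 2/sqrt(pi),
  # so plant sigma = (jitter%/100) * sqrt(pi)/2
  sig_j <- (jitter_pct / 100) * sqrt(pi) / 2
  sig_s <- (shimmer_pct / 100) * sqrt(pi) / 2
  T0 <- 1 / f0
  n_cyc <- ceiling(dur / T0) + 2
  periods <- T0 * pmax(1 + sig_j * rnorm(n_cyc), 0.3)
  onsets <- cumsum(c(0, periods))
  keep <- onsets < dur
  onsets <- onsets[keep]
  periods <- periods[seq_len(max(length(onsets) - 1, 0))]
  amps <- pmax(1 + sig_s * rnorm(length(onsets)), 0.05)
  n <- round(dur * sr)
  exc <- numeric(n + 2)
  pos <- onsets * sr
  i0 <- floor(pos)
  frac <- pos - i0
  # fractional-delay impulse placement (linear split over two samples)
  idx <- i0 + 1L
  ok <- idx <= n
  exc[idx[ok]] <- exc[idx[ok]] + amps[ok] * (1 - frac[ok])
  exc[idx[ok] + 1L] <- exc[idx[ok] + 1L] + amps[ok] * frac[ok]
  exc <- exc[seq_len(n)]
  # glottal spectral tilt
  exc <- as.numeric(stats::filter(exc, 0.95, method = "recursive"))
  # vowel cycling at roughly the syllable rate: the full excitation is
  # filtered once per vowel and the outputs are crossfaded (raised cosine
  # over ~15 ms each side) at the vowel boundaries, so phonation never
  # dips to zero mid-utterance and no spurious voice breaks are created
  vdur <- 1 / max(speech_rate, 0.5)
  bounds <- unique(c(seq(0, dur, by = vdur), dur))
  if (length(bounds) < 2) bounds <- c(0, dur)
  vowels <- rep(c("a", "i", "u"), length.out = length(bounds) - 1)
  filt <- lapply(stats::setNames(nm = unique(vowels)),
                 function(vw) apply_formants(exc, vw, sr))
  # equalize vowel loudness: resonator gains differ by >15 dB between
  # /a/ and the close vowels, far beyond natural inter-vowel differences
  filt <- lapply(filt, function(s) {
    r <- sqrt(mean(s^2))
    if (r > 0) s / r else s
  })
  # align cycle-peak delay across vowels: each resonator cascade peaks at
  # a different lag after the glottal impulse, and an unaligned vowel
  # switch would shift the waveform peak within a cycle — read as jitter
  delays <- vapply(names(filt), function(vw) {
    h <- numeric(256); h[1] <- 1
    which.max(abs(apply_formants(h, vw, sr)))
  }, numeric(1))
  d0 <- min(delays)
  filt <- Map(function(s, d) {
    sh <- as.integer(d - d0)
    if (sh > 0) c(s[-seq_len(sh)], numeric(sh)) else s
  }, filt, delays[names(filt)])
  wave <- filt[[vowels[1]]][seq_len(n)]
  # crossfade over ~4-5 glottal cycles: an abrupt vowel switch jumps the
  # waveform peak phase within one cycle and would read as spurious jitter
  half <- max(1L, round(0.015 * sr))
  for (k in seq_along(vowels)[-1]) {
    b <- round(bounds[k] * sr)
    i0 <- max(1L, b - half)
    i1 <- min(n, b + half)
    if (i1 < n) wave[(i1 + 1):n] <- filt[[vowels[k]]][(i1 + 1):n]
    if (i1 > i0) {
      ww <- (1 - cos(pi * seq(0, 1, length.out = i1 - i0 + 1))) / 2
      wave[i0:i1] <- wave[i0:i1] * (1 - ww) +
        filt[[vowels[k]]][i0:i1] * ww
    }
  }
  # consonant-like intensity dips (~9 dB, 60 ms raised-cosine) at the
  # syllable boundaries give the intensity contour the peak/dip structure
  # that syllable-nucleus detection needs
  width <- round(0.06 * sr)
  depth <- 0.35
  for (k in seq_along(vowels)[-1]) {
    b <- round(bounds[k] * sr)
    i0 <- max(1L, b - width %/% 2)
    i1 <- min(n, b + width %/% 2)
    if (i1 <= i0) next
    rel <- (seq(i0, i1) - b) / width
    g <- 1 - (1 - depth) * cos(pi * rel)^2
    wave[i0:i1] <- wave[i0:i1] * g
  }
  # onset/offset ramps so utterance/pause joins are click-free
  nr <- min(n, round(0.005 * sr))
  if (nr > 1) {
    ramp <- (1 - cos(pi * seq_len(nr) / nr)) / 2
    wave[seq_len(nr)] <- wave[seq_len(nr)] * ramp
    wave[(n - nr + 1):n] <- wave[(n - nr + 1):n] * rev(ramp)
  }
  list(wave = wave, periods = periods, amps = amps)
}

#' Synthesize one recording with known voice parameters
#'
#' @param profile a [subject_profile()].
#' @param effects named list of additive condition offsets: `f0_shift` (Hz),
#'   `jitter_shift` (percentage points), `pause_rate_shift` (per minute).
#'   Missing entries default to 0.
#' @param duration_s recording length, seconds; must exceed 61 s so the
#'   60 s of head/tail trimming leaves material to analyze.
#' @param sample_rate Hz, at least 16000.
#' @param seed integer seed; fully determines the waveform.
#' @return list with `wave`, `sample_rate`, and `truth` (realized f0, jitter
#'   and shimmer percent, pause/utterance intervals).
#' @export
synth_voice <- function(profile, effects = list(), duration_s = 300,
                        sample_rate = 22050, seed = 1) {
  if (!is.numeric(duration_s) || duration_s <= 61)
    stop("duration_s must exceed 61 seconds (got ", duration_s, ")",
         call. = FALSE)
  if (sample_rate < 16000)
    stop("sample_rate must be at least 16000 Hz", call. = FALSE)
  f0 <- profile$base_f0 + (effects$f0_shift %||% 0)
  if (f0 <= 0) stop("fundamental frequency f0 must be positive (got ",
                    f0, ")", call. = FALSE)
  jit <- max(profile$base_jitter + (effects$jitter_shift %||% 0), 0)
  shim <- max(profile$base_shimmer + (effects$shimmer_shift %||% 0), 0)
  prate <- max(profile$base_pause_rate + (effects$pause_rate_shift %||% 0), 0)
  with_local_seed(seed, {
    tl <- draw_timeline(duration_s, prate)
    n <- round(duration_s * sample_rate)
    wave <- numeric(n)
    all_periods <- list()
    all_amps <- list()
    for (k in which(tl$type == "utterance")) {
      dur <- tl$end[k] - tl$start[k]
      if (dur < 0.05) next
      u <- synth_utterance(dur, f0, jit, shim, profile$base_speech_rate,
                           sample_rate)
      s <- floor(tl$start[k] * sample_rate) + 1
      e <- min(s + length(u$wave) - 1, n)
      wave[s:e] <- u$wave[seq_len(e - s + 1)]
      all_periods[[length(all_periods) + 1]] <- u$periods
      all_amps[[length(all_amps) + 1]] <- u$amps
    }
    peak <- max(abs(wave), 1e-12)
    wave <- wave / peak * 0.7
    # additive noise floor 50 dB below signal RMS
    rms <- sqrt(mean(wave^2))
    wave <- wave + rnorm(n, sd = rms * 10^(-50 / 20))
    realized <- function(xs) {
      per_utt <- vapply(xs, function(v) {
        if (length(v) < 3) return(NA_real_)
        100 * mean(abs(diff(v))) / mean(v)
      }, numeric(1))
      stats::weighted.mean(per_utt, vapply(xs, length, numeric(1)),
                           na.rm = TRUE)
    }
    periods_all <- unlist(all_periods)
    truth <- list(
      f0_target = f0,
      f0_realized = if (length(periods_all)) 1 / mean(periods_all) else NA,
      jitter_realized = if (length(all_periods)) realized(all_periods) else NA,
      shimmer_realized = if (length(all_amps)) realized(all_amps) else NA,
      pause_intervals = tl[tl$type == "pause", c("start", "end")],
      utterance_intervals = tl[tl$type == "utterance", c("start", "end")]
    )
    list(wave = wave, sample_rate = sample_rate, truth = truth)
  })
}
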