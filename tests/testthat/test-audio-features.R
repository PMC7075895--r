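# Acoustic feature extraction: hand oracles, recovery on constructed
# signals, and inventory closure.

test_that("summarize_series matches the interpolated order-statistic oracle", {
  s <- summarize_series(c(100, 110, 120, 130, 140))
  expect_equal(unname(s["a"]), 120)
  expect_equal(unname(s["b"]), 20)
  expect_equal(unname(s["e"]), 102)   # p5 by linear interpolation
  expect_equal(unname(s["g"]), 138)   # p95
  expect_equal(unname(s["d"]), 0)     # symmetric series
  # constant series: IQR 0; skewness/kurtosis 0 by convention
  cs <- summarize_series(rep(7, 10))
  expect_equal(unname(cs["b"]), 0)
  expect_equal(unname(cs["c"]), 0)
  expect_equal(unname(cs["d"]), 0)
  # empty series: all missing
  expect_true(all(is.na(summarize_series(numeric(0)))))
  # time-reversal invariance
  set.seed(1)
  x <- rnorm(50)
  expect_equal(summarize_series(x), summarize_series(rev(x)))
})

test_that("preprocess_audio trims 30 s per end and excises annotations", {
  sr <- 1000
  w <- sin(2 * pi * 5 * seq_len(300 * sr) / sr)
  out <- preprocess_audio(w, sr)
  expect_equal(length(out) / sr, 240)
  ann <- data.frame(start_s = 100, end_s = 110)
  out2 <- preprocess_audio(w, sr, ann)
  expect_equal(length(out2) / sr, 230, tolerance = 0.01)
  expect_error(preprocess_audio(w[seq_len(59 * sr)], sr), "60")
})

test_that("jitter and shimmer match the hand-computed oracles", {
  mk_track <- function(periods, amps) {
    structure(list(periods = periods, amplitudes = amps,
                   cycle_span = rep(1L, length(periods)),
                   amp_span = rep(1L, length(amps)),
                   voiced = rep(TRUE, 5),
                   time = seq(0, 0.04, by = 0.01),
                   r = rep(0.9, 5), empty = FALSE), class = "sc_voicing")
  }
  # constant periods: zero jitter
  js0 <- jitter_shimmer(mk_track(rep(0.010, 4), rep(1, 5)))
  expect_equal(js0$Jitter_h, 0)
  expect_equal(js0$Shimmer_h, 0)
  # periods [9,11,9,11] ms: mean |diff| = 2, mean T = 10 -> 20%
  js <- jitter_shimmer(mk_track(c(9, 11, 9, 11) / 1000, rep(1, 5)))
  expect_equal(js$Jitter_h, 20)
  # amplitudes all equal: shimmer 0 regardless of periods
  expect_equal(js$Shimmer_h, 0)
})

test_that("track_voicing recovers periodicity and rejects noise", {
  sr <- 16000
  t <- seq_len(2 * sr) / sr
  # harmonic-rich 100 Hz signal
  w <- 0.6 * sin(2 * pi * 100 * t) + 0.3 * sin(2 * pi * 200 * t) +
    0.1 * sin(2 * pi * 300 * t)
  tr <- track_voicing(w, sr)
  expect_gt(tr$voiced_fraction, 0.95)
  expect_lt(abs(median(tr$f0, na.rm = TRUE) - 100), 1)
  # white noise: (almost) nothing voiced
  set.seed(2)
  nz <- track_voicing(rnorm(2 * sr, sd = 0.1), sr)
  expect_lt(nz$voiced_fraction, 0.1)
  # all-silent input: empty track flag, not an exception
  sil <- track_voicing(numeric(sr), sr)
  expect_true(sil$empty)
  expect_error(track_voicing(w, sr, f0_band = c(40, 400)), "f0_band")
})

test_that("planted jitter is recovered within 0.5 pp on a phonated span", {
  prof <- subject_profile(base_f0 = 140, base_jitter = 2, base_shimmer = 4,
                          base_pause_rate = 0, base_speech_rate = 4)
  v <- synth_voice(prof, duration_s = 62, sample_rate = 16000, seed = 13)
  w <- v$wave[(10 * 16000):(14 * 16000)]
  js <- jitter_shimmer(track_voicing(w, 16000))
  expect_lt(abs(js$Jitter_h - v$truth$jitter_realized), 0.5)
})

test_that("noise_measures satisfy the r = 0.5 closed form and the clean-signal limit", {
  mk <- function(r, n = 10) {
    structure(list(r = rep(r, n), voiced = rep(TRUE, n)),
              class = "sc_voicing")
  }
  nm <- noise_measures(mk(0.5))
  expect_equal(nm$HNR, 0)
  expect_equal(nm$NHR, 1)
  expect_equal(nm$MeanAutocorr, 0.5)
  # clean periodic signal: r near 1, HNR large
  sr <- 16000
  t <- seq_len(sr) / sr
  w <- sin(2 * pi * 120 * t) + 0.4 * sin(2 * pi * 240 * t)
  tr <- track_voicing(w, sr)
  hn <- noise_measures(tr)
  expect_gt(hn$HNR, 30)
  # no voiced frames: missing
  expect_true(is.na(noise_measures(mk(numeric(0), n = 0))$HNR))
})

test_that("segment_pauses finds a constructed 1 s gap and handles limit cases", {
  sr <- 16000
  tone <- function(d) sin(2 * pi * 200 * seq_len(round(d * sr)) / sr)
  w <- c(tone(2), numeric(sr), tone(2))
  seg <- segment_pauses(w, sr)
  expect_equal(nrow(seg$pauses), 1)
  gap <- seg$pauses$end - seg$pauses$start
  expect_lt(abs(gap - 1.0), 0.05)
  # continuous phonation: no pauses
  expect_equal(nrow(segment_pauses(tone(3), sr)$pauses), 0)
  # silence: one all-spanning pause, zero nuclei
  s <- segment_pauses(numeric(2 * sr), sr)
  expect_equal(nrow(s$pauses), 1)
  expect_equal(s$n_nuclei, 0)
  # definition arithmetic: rates from nuclei and durations
  expect_equal(seg$phonation_ratio,
               sum(seg$utterances$end - seg$utterances$start) / 5)
})

test_that("spectral_block matches tone, scaling, and framing oracles", {
  sr <- 16000
  t <- seq_len(sr) / sr          # 1 s
  w <- sin(2 * pi * 440 * t)
  sp <- spectral_block(w, sr)
  expect_lt(abs(sp$MaxFreq - 440), 10)
  sp2 <- spectral_block(2 * w, sr)
  expect_equal(sp2$Energy / sp$Energy, 4, tolerance = 1e-6)
  expect_equal(sp2$MaxdB - sp$MaxdB, 20 * log10(2), tolerance = 1e-6)
  # MFCC frame count: floor((1 - 0.025)/0.010) + 1 = 98 on a 1 s input
  expect_equal(ncol(sp$mfcc), 98)
  expect_equal(nrow(sp$mfcc), 16)
})

test_that("vowel-space geometry matches the shoelace oracle", {
  tri <- rbind(c(800, 1200), c(300, 2300), c(350, 800))
  expect_equal(polygon_area(tri), 347500)
  expect_equal(polygon_area(tri[c(3, 2, 1), ]), 347500)  # orientation-free
  expect_equal(polygon_area(tri[1:2, ]), 0)              # degenerate
})

test_that("formant corner centroids land near the planted vowel targets", {
  prof <- subject_profile(base_f0 = 120, base_jitter = 0.5,
                          base_shimmer = 2, base_pause_rate = 0,
                          base_speech_rate = 4)
  v <- synth_voice(prof, duration_s = 62, sample_rate = 16000, seed = 17)
  w <- v$wave[(10 * 16000):(16 * 16000)]
  tr <- track_voicing(w, 16000)
  fb <- formant_block(w, 16000, tr)
  ref <- rbind(a = c(800, 1200), i = c(300, 2300), u = c(350, 800))
  expect_false(anyNA(fb$corner_centroids))
  expect_true(all(abs(fb$corner_centroids - ref) < 75))
  expect_gt(fb$AIUArea, 0)
  expect_gt(fb$TotalArea, fb$AIUArea)
})

test_that("acoustic inventory closure holds on any valid input", {
  inv <- acoustic_inventory()
  expect_length(inv, 88)
  expect_false(any(duplicated(inv)))
  fw <- fix_wave()
  av <- extract_acoustic(fw$wave, fw$sample_rate, preprocessed = TRUE)
  expect_identical(names(av), inv)
  expect_identical(av, extract_acoustic(fw$wave, fw$sample_rate,
                                        preprocessed = TRUE))
})

test_that("amplitude scaling moves only the level features", {
  fw <- fix_wave()
  a1 <- extract_acoustic(fw$wave, fw$sample_rate, preprocessed = TRUE)
  a2 <- extract_acoustic(2 * fw$wave, fw$sample_rate, preprocessed = TRUE)
  expect_equal(a2[["Jitter_h"]], a1[["Jitter_h"]], tolerance = 1e-6)
  expect_equal(a2[["Pitch_a"]], a1[["Pitch_a"]], tolerance = 1e-6)
  expect_equal(a2[["HNR"]], a1[["HNR"]], tolerance = 1e-6)
  expect_equal(a2[["MaxdB"]] - a1[["MaxdB"]], 20 * log10(2),
               tolerance = 1e-6)
  expect_equal(a2[["Energy"]] / a1[["Energy"]], 4, tolerance = 1e-6)
})

test_that("corrupt recordings are skipped with a logged reason", {
  bad <- tempfile(fileext = ".wav")
  writeBin(as.raw(sample(0:255, 64, replace = TRUE)), bad)
  rec <- list(audio_path = bad, annotation_path = NA_character_)
  expect_warning(out <- extract_acoustic_record(rec), "unusable")
  expect_null(out)
  unlink(bad)
})

test_that("WAV round-trip preserves the signal to 16-bit precision", {
  sr <- 16000
  w <- 0.5 * sin(2 * pi * 220 * seq_len(sr / 2) / sr)
  p <- tempfile(fileext = ".wav")
  write_wav(w, sr, p)
  rt <- read_wav(p)
  expect_equal(rt$sample_rate, sr)
  expect_lt(max(abs(rt$wave - w)), 1 / 32767)
  unlink(p)
})
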