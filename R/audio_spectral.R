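# Long-term average spectrum statistics and MFCCs.

#' Long-term spectral statistics and MFCC series
#'
#' The long-term average spectrum (Welch-averaged periodogram) yields the
#' maximum level, its frequency, total energy, and the spectral slope in
#' dB/octave; MFCCs 1-16 are computed on 25 ms frames with 10 ms hop and a
#' 26-filter mel bank over all frames (voiced and unvoiced).
#'
#' @param wave preprocessed waveform.
#' @param sample_rate Hz.
#' @param n_mfcc number of cepstral coefficients (the energy coefficient
#'   c0 is excluded).
#' @param n_mel number of mel filters.
#' @param frame_s,hop_s MFCC framing, seconds.
#' @return list: `MaxdB`, `MaxFreq` (Hz), `Energy` (sum of squares),
#'   `Slope` (dB/oct), and `mfcc` (matrix, `n_mfcc` rows x frames).
#' @export
spectral_block <- function(wave, sample_rate, n_mfcc = 16, n_mel = 26,
                           frame_s = 0.025, hop_s = 0.01) {
  # --- LTAS via Welch averaging ---
  wlen <- min(2048, 2^floor(log2(max(length(wave), 8))))
  fr <- frame_signal(wave, wlen, wlen %/% 2)
  if (ncol(fr) == 0) fr <- matrix(c(wave, numeric(wlen - length(wave))), ncol = 1)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  P <- abs(stats::mvfft(fr * win))^2
  ltas <- rowMeans(P)[seq_len(wlen %/% 2)]
  freqs <- (seq_len(wlen %/% 2) - 1) * sample_rate / wlen
  imax <- which.max(ltas)
  ltas_db <- 10 * log10(pmax(ltas, 1e-20))
  sel <- freqs >= 50 & freqs <= min(8000, sample_rate / 2 - 1)
  slope <- if (sum(sel) > 2) {
    fit <- stats::lm.fit(cbind(1, log2(freqs[sel])), ltas_db[sel])
    unname(fit$coefficients[2])
  } else NA_real_
  # --- MFCCs ---
  flen <- round(frame_s * sample_rate)
  hop <- round(hop_s * sample_rate)
  mf <- frame_signal(wave, flen, hop)
  mfcc <- matrix(NA_real_, n_mfcc, ncol(mf))
  if (ncol(mf) > 0) {
    nfft <- stats::nextn(flen, 2)
    hwin <- 0.5 - 0.5 * cos(2 * pi * seq_len(flen) / (flen + 1))
    S <- abs(stats::mvfft(rbind(mf * hwin,
                                matrix(0, nfft - flen, ncol(mf)))))^2
    S <- S[seq_len(nfft %/% 2 + 1), , drop = FALSE]
    fb <- mel_filterbank(n_mel, nfft, sample_rate)
    E <- log(pmax(fb %*% S, 1e-20))
    # orthonormal DCT-II over filter index; coefficients 1..n_mfcc
    k <- seq_len(n_mfcc)
    D <- sqrt(2 / n_mel) *
      cos(pi / n_mel * outer(k, seq_len(n_mel) - 0.5))
    mfcc <- D %*% E
  }
  list(MaxdB = 10 * log10(max(ltas)), MaxFreq = freqs[imax],
       Energy = sum(wave^2), Slope = slope, mfcc = mfcc)
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (n_mel x (nfft/2 + 1))
mel_filterbank <- function(n_mel, nfft, sample_rate) {
  n_bins <- nfft %/% 2 + 1
  f_bins <- (seq_len(n_bins) - 1) * sample_rate / nfft
  edges <- mel_to_hz(seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                         length.out = n_mel + 2))
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1]; hi <- edges[m + 2]
    up <- (f_bins - lo) / (ce - lo)
    dn <- (hi - f_bins) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}
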