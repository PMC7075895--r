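# Formant tracking by LPC root-solving and vowel-space geometry.

# Decimate to a 10 kHz analysis band (Praat-style: formants are estimated
# on a signal whose Nyquist sits just above F3).
decimate_for_formants <- function(wave, sample_rate, target_rate = 10000) {
  if (sample_rate <= target_rate) return(list(wave = wave, rate = sample_rate))
  bf <- signal::butter(8, (target_rate / 2 * 0.92) / (sample_rate / 2))
  low <- signal::filtfilt(bf, wave)
  t_old <- seq_along(wave) / sample_rate
  n_new <- floor(length(wave) * target_rate / sample_rate)
  t_new <- seq_len(n_new) / target_rate
  list(wave = stats::approx(t_old, low, t_new, rule = 2)$y,
       rate = target_rate)
}

# Levinson-Durbin solution of the autocorrelation LPC normal equations.
lpc_coefs <- function(x, order) {
  n <- length(x)
  r <- vapply(0:order, function(k)
    sum(x[seq_len(n - k)] * x[(k + 1):n]), numeric(1))
  if (r[1] <= 0) return(NULL)
  a <- numeric(order)
  e <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[seq_len(i - 1)] * r[i:2])
    k <- acc / e
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[seq_len(i - 1)] <- a[seq_len(i - 1)] -
        k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) return(NULL)
  }
  a   # x[n] ~ sum a_k x[n-k]
}

#' Formant series and vowel-space geometry
#'
#' Formants are found per voiced frame by LPC on a 10 kHz-decimated,
#' pre-emphasized signal (order 4 + rate/1000, i.e. 14 at 10 kHz), taking
#' the angles of the complex roots of the prediction polynomial. The
#' (F1, F2) cloud yields the total vowel-space area (convex hull), the
#' a-i-u triangle area (shoelace formula on per-corner centroids, corners
#' assigned by nearest reference target), and the apex angle at /i/.
#'
#' @param wave preprocessed waveform.
#' @param sample_rate Hz.
#' @param track an `sc_voicing` from [track_voicing()] on the same wave.
#' @param min_voiced_frames fewer voiced frames than this yields all-NA
#'   formant output.
#' @param aiu_ref reference (F1, F2) targets for /a/, /i/, /u/.
#' @return list: `F1`, `F2`, `F3` (per-voiced-frame series, Hz),
#'   `TotalArea` (Hz^2), `AIUArea` (Hz^2), `Angle` (degrees),
#'   `corner_centroids` (3x2 matrix).
#' @export
formant_block <- function(wave, sample_rate, track, min_voiced_frames = 10,
                          aiu_ref = rbind(a = c(800, 1200), i = c(300, 2300),
                                          u = c(350, 800))) {
  empty <- list(F1 = numeric(0), F2 = numeric(0), F3 = numeric(0),
                TotalArea = NA_real_, AIUArea = NA_real_, Angle = NA_real_,
                corner_centroids = NULL)
  vtimes <- track$time[track$voiced]
  if (length(vtimes) < min_voiced_frames) return(empty)
  dec <- decimate_for_formants(wave, sample_rate)
  w <- dec$wave
  x <- w - 0.97 * c(0, w[-length(w)])   # pre-emphasis

  # rate/1000 poles cover formants up to Nyquist; the 4 extra coefficients
  # let the model absorb the residual glottal tilt and noise floor, which
  # otherwise split F1 into two broad poles and displace F2
  order <- 4 + round(dec$rate / 1000)
  flen <- round(0.025 * dec$rate)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(flen) / (flen + 1))
  F123 <- matrix(NA_real_, length(vtimes), 3)
  for (j in seq_along(vtimes)) {
    c0 <- round(vtimes[j] * dec$rate)
    s <- c0 - flen %/% 2
    if (s < 1 || s + flen - 1 > length(x)) next
    fr <- x[s:(s + flen - 1)] * win
    a <- lpc_coefs(fr, order)
    if (is.null(a)) next
    # poles of 1 / (1 - sum a_k z^-k): roots of z^p - a_1 z^(p-1) - ... - a_p
    rt <- polyroot(c(-rev(a), 1))
    ang <- Arg(rt)
    keep <- ang > 0.0001 & Mod(rt) > 0.6
    fHz <- ang[keep] * dec$rate / (2 * pi)
    bw <- -dec$rate / pi * log(pmax(Mod(rt)[keep], 1e-9))
    sel <- fHz > 90 & fHz < dec$rate / 2 - 100 & bw < 700
    fs <- sort(fHz[sel])
    if (length(fs) >= 3) F123[j, ] <- fs[1:3]
  }
  ok <- stats::complete.cases(F123)
  F123 <- F123[ok, , drop = FALSE]
  if (nrow(F123) < min_voiced_frames) return(empty)
  f1 <- F123[, 1]; f2 <- F123[, 2]
  pts <- cbind(f1, f2)
  hull <- grDevices::chull(pts)
  TotalArea <- polygon_area(pts[hull, , drop = FALSE])
  # nearest-target corner assignment
  d2 <- vapply(1:3, function(k)
    (f1 - aiu_ref[k, 1])^2 + (f2 - aiu_ref[k, 2])^2, numeric(nrow(pts)))
  corner <- max.col(-d2)
  cent <- t(vapply(1:3, function(k) {
    if (!any(corner == k)) return(c(NA_real_, NA_real_))
    colMeans(pts[corner == k, , drop = FALSE])
  }, numeric(2)))
  rownames(cent) <- c("a", "i", "u")
  if (anyNA(cent)) {
    AIUArea <- NA_real_
    Angle <- NA_real_
  } else {
    AIUArea <- polygon_area(cent)
    va <- cent["a", ] - cent["i", ]
    vu <- cent["u", ] - cent["i", ]
    Angle <- acos(sum(va * vu) /
                  sqrt(sum(va^2) * sum(vu^2))) * 180 / pi
  }
  list(F1 = f1, F2 = f2, F3 = F123[, 3], TotalArea = TotalArea,
       AIUArea = AIUArea, Angle = Angle, corner_centroids = cent)
}

#' Shoelace polygon area
#' @param pts matrix of vertices (ordered), columns x and y.
#' @return area (non-negative).
#' @export
polygon_area <- function(pts) {
  if (is.null(pts) || nrow(pts) < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:nrow(pts), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
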