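# Heart-rate-variability summaries. Time-domain statistics use the sample
# (n-1) standard deviation convention. The frequency domain works on the RR
# tachogram cubic-spline resampled to 4 Hz, linearly detrended, with a Welch
# average periodogram (Hann window, 50% overlap); band powers are integrals
# over VLF 0-0.04, LF 0.04-0.15 and HF 0.15-0.4 Hz, and total power is the
# 0-0.4 Hz integral, so VLF+LF+HF = total by construction.

#' Time-domain HRV statistics
#'
#' @param rr beat-to-beat intervals in milliseconds (>= 3 intervals).
#' @return named list: `sdnn` (SD of all intervals), `rmssd` (root mean
#'   square of successive differences), `sdsd` (SD of successive
#'   differences), all in ms.
#' @examples
#' hrv_time_domain(c(800, 1000, 800, 1000, 800))
#' @export
hrv_time_domain <- function(rr) {
  if (length(rr) < 3) stop_insufficient_data("need at least 3 RR intervals")
  d <- diff(rr)
  list(sdnn = sd(rr), rmssd = sqrt(mean(d^2)), sdsd = sd(d))
}

# Welch average periodogram; returns f (Hz) and one-sided PSD (ms^2/Hz)
welch_psd <- function(x, fs, seg_len = NULL, overlap = 0.5) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- min(256L, n)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / (length(starts) * u * fs)
  # fold two-sided spectrum into one-sided
  if (seg_len %% 2 == 0) psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  else psd[2:nf] <- 2 * psd[2:nf]
  list(f = (seq_len(nf) - 1) * fs / seg_len, psd = psd)
}

#' Frequency-domain HRV statistics
#'
#' @param beats a `beat_series` (from [detect_beats()] or [beat_series()]).
#' @param resample_fs tachogram resampling rate in Hz (default 4).
#' @return named list: `total_power`, `vlf`, `lf`, `hf` in ms^2 and the
#'   `lf_hf` ratio.
#' @export
hrv_frequency_domain <- function(beats, resample_fs = 4) {
  rr <- beats$rr
  tt <- beats$rr_times
  if (length(rr) < 10) stop_insufficient_data("too few beats for spectral analysis")
  # requires about a minute of beats (the first/last RR straddle the epoch
  # edges, so the covered span is slightly under the epoch duration)
  if (diff(range(tt)) < 55)
    stop_insufficient_data("need about 60 s of beats for spectral analysis")
  grid <- seq(min(tt), max(tt), by = 1 / resample_fs)
  tach <- spline(tt, rr, xout = grid, method = "fmm")$y
  # linear detrend
  fit <- stats::lm.fit(cbind(1, grid), tach)
  tach <- fit$residuals
  sp <- welch_psd(tach, resample_fs)
  df <- sp$f[2] - sp$f[1]
  band <- function(lo, hi) sum(sp$psd[sp$f > lo & sp$f <= hi]) * df
  vlf <- band(0, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.4)
  list(total_power = vlf + lf + hf, vlf = vlf, lf = lf, hf = hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_)
}

#' Full eight-measure HRV summary
#'
#' Combines [hrv_time_domain()] and [hrv_frequency_domain()] in the canonical
#' feature order.
#'
#' @param beats a `beat_series`.
#' @return named numeric vector: sdnn, rmssd, sdsd, total_power, vlf, lf,
#'   hf, lf_hf.
#' @export
hrv_summary <- function(beats) {
  td <- hrv_time_domain(beats$rr)
  fd <- hrv_frequency_domain(beats)
  c(sdnn = td$sdnn, rmssd = td$rmssd, sdsd = td$sdsd,
    total_power = fd$total_power, vlf = fd$vlf, lf = fd$lf, hf = fd$hf,
    lf_hf = fd$lf_hf)
}
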