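# QRS detection in the Pan-Tompkins style: band-pass 5-15 Hz, derivative,
# squaring, moving-window integration (150 ms), then an adaptive
# signal/noise threshold with a 200 ms refractory period. Detected peaks are
# refined to the local maximum of the band-passed signal so beat times align
# with R-wave apices.

#' Detect heart beats in a conditioned ECG
#'
#' @param ecg a [channel_signal()] (ideally the output of [bandlimit_ecg()])
#'   or numeric vector with `fs`.
#' @param fs sampling rate for bare vectors.
#' @return a `beat_series`: list with `times` (beat times in seconds,
#'   strictly increasing) and `rr` (cleaned beat-to-beat intervals in ms;
#'   intervals outside the physiological 200-3000 ms gate are removed).
#' @examples
#' ecg <- synthesize_ecg(70, duration = 60, seed = 2)
#' beats <- detect_beats(bandlimit_ecg(ecg$signal))
#' head(beats$rr)
#' @export
detect_beats <- function(ecg, fs = NULL) {
  sig <- as_channel_like(ecg, fs)
  fs <- sig$fs
  x <- sig$values
  n <- length(x)
  if (n < fs * 2) stop_insufficient_signal("ECG shorter than 2 s")
  if (sd(x) < 1e-12) stop_insufficient_signal("flat-line ECG: no beats found")

  bp <- bandpass_zerophase(x, fs, 5, 15, order = 2)
  dx <- c(0, diff(bp)) * fs
  sq <- dx^2
  w <- max(1L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal
  refr <- round(0.2 * fs)
  is_peak <- c(FALSE, diff(sign(diff(mwi))) < 0, FALSE)
  cand <- which(is_peak)
  if (!length(cand)) stop_insufficient_signal("no candidate peaks in ECG")

  # adaptive thresholding over candidates in temporal order
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  beats_idx <- integer(0)
  last <- -Inf
  for (ci in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (mwi[ci] >= thr && (ci - last) > refr) {
      beats_idx <- c(beats_idx, ci)
      last <- ci
      spki <- 0.125 * mwi[ci] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[ci] + 0.875 * npki
    }
  }
  if (length(beats_idx) < 2) stop_insufficient_signal("fewer than 2 beats detected")

  # refine each detection to the apex of the band-passed ECG
  half <- round(0.10 * fs)
  ref_idx <- vapply(beats_idx, function(ci) {
    lo <- max(1, ci - half); hi <- min(n, ci + half)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  ref_idx <- sort(unique(ref_idx))
  # collapse refinements that landed on the same apex within refractory time
  keep <- c(TRUE, diff(ref_idx) > refr)
  ref_idx <- ref_idx[keep]
  times <- (ref_idx - 1) / fs

  rr <- diff(times) * 1000
  ok <- rr >= 200 & rr <= 3000
  structure(list(times = times, rr = rr[ok], rr_times = times[-1][ok]),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d clean RR intervals (mean %.0f ms)\n",
              length(x$times), length(x$rr),
              if (length(x$rr)) mean(x$rr) else NA))
  invisible(x)
}

#' Construct a beat series from known beat times
#'
#' Convenience constructor for tests and for feeding ground-truth beats to
#' the HRV functions.
#'
#' @param times beat times in seconds, strictly increasing.
#' @return a `beat_series`.
#' @export
beat_series <- function(times) {
  if (is.unsorted(times, strictly = TRUE))
    stop_invalid_argument("beat times must be strictly increasing")
  rr <- diff(times) * 1000
  ok <- rr >= 200 & rr <= 3000
  structure(list(times = times, rr = rr[ok], rr_times = times[-1][ok]),
            class = "beat_series")
}
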