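# Windowed physiological series: non-overlapping, contiguous 10 s windows
# over an epoch, exactly floor(duration / window) of them. Windows with no
# underlying observations are imputed from the nearest populated window and
# flagged via the `imputed` attribute.

windowed_series <- function(values, window, units, imputed = NULL) {
  structure(as.numeric(values), window = window, units = units,
            imputed = imputed %||% rep(FALSE, length(values)),
            class = "windowed_series")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.windowed_series <- function(x, ...) {
  cat(sprintf("<windowed_series> %d x %g s windows (%s)%s\n",
              length(unclass(x)), attr(x, "window"), attr(x, "units"),
              if (any(attr(x, "imputed"))) sprintf(", %d imputed",
                                                   sum(attr(x, "imputed"))) else ""))
  print(as.numeric(x))
  invisible(x)
}

impute_nearest <- function(vals) {
  bad <- which(is.na(vals)); good <- which(!is.na(vals))
  if (!length(good)) stop_insufficient_data("no populated windows")
  for (i in bad) vals[i] <- vals[good[which.min(abs(good - i))]]
  list(values = vals, imputed = seq_along(vals) %in% bad)
}

#' Windowed mean heart rate
#'
#' Average heart rate per non-overlapping 10 s window, computed as
#' `60000 / mean(RR in window)` with each RR interval assigned to the window
#' containing its ending beat. Empty windows are imputed from the nearest
#' populated window and flagged.
#'
#' @param beats a `beat_series`.
#' @param duration epoch duration in seconds (>= one window).
#' @param window window length in seconds (default 10).
#' @return a `windowed_series` in beats/min of length
#'   `floor(duration/window)`; attribute `imputed` marks filled-in windows.
#' @export
heart_rate_windows <- function(beats, duration, window = 10) {
  if (duration < window) stop_invalid_argument("epoch shorter than one window")
  nw <- floor(duration / window)
  idx <- pmin(pmax(floor(beats$rr_times / window) + 1, 1), nw)
  vals <- rep(NA_real_, nw)
  agg <- tapply(beats$rr, idx, mean)
  vals[as.integer(names(agg))] <- 60000 / agg
  imp <- impute_nearest(vals)
  windowed_series(imp$values, window, "beats/min", imp$imputed)
}

# simple local-maximum peak picking with a minimum separation (seconds)
find_peaks <- function(x, fs, min_dist, min_prominence = 0.1) {
  n <- length(x)
  is_max <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE)
  thr <- min_prominence * max(abs(x))
  cand <- which(is_max & x > thr)
  if (!length(cand)) return(integer(0))
  sep <- round(min_dist * fs)
  # enforce separation in temporal order
  keep <- integer(0)
  for (ci in cand) {
    if (!length(keep) || ci - keep[length(keep)] >= sep) keep <- c(keep, ci)
  }
  keep
}

#' Windowed respiration rate
#'
#' Band-limits the belt signal to 0.1-10 Hz (zero phase), detects breath
#' peaks, converts breath-to-breath intervals to instantaneous rates, and
#' averages per non-overlapping 10 s window (rate attributed to the interval
#' midpoint; empty windows imputed from the nearest populated one).
#'
#' @param resp a respiration [channel_signal()] or numeric with `fs`.
#' @param fs sampling rate for bare vectors.
#' @param window window length in seconds (default 10).
#' @return a `windowed_series` in breaths/min.
#' @export
respiration_rate_windows <- function(resp, fs = NULL, window = 10) {
  sig <- if (inherits(resp, "channel_signal")) resp else
    channel_signal("respiration", fs, resp)
  fs <- sig$fs
  dur <- signal_duration(sig)
  if (dur < window) stop_invalid_argument("epoch shorter than one window")
  hi <- min(10, fs / 2 * 0.9)
  v <- bandpass_zerophase(sig$values, fs, 0.1, hi, order = 2)
  pk <- find_peaks(v, fs, min_dist = 1.2)
  if (length(pk) < 2) stop_insufficient_signal("no breaths detected in epoch")
  pt <- (pk - 1) / fs
  ivl <- diff(pt)
  rate <- 60 / ivl
  mid <- pt[-length(pt)] + ivl / 2
  nw <- floor(dur / window)
  idx <- pmin(pmax(floor(mid / window) + 1, 1), nw)
  vals <- rep(NA_real_, nw)
  agg <- tapply(rate, idx, mean)
  vals[as.integer(names(agg))] <- agg
  imp <- impute_nearest(vals)
  windowed_series(imp$values, window, "breaths/min", imp$imputed)
}

# linear resampling onto a new rate
resample_linear <- function(x, fs, fs_out) {
  n <- length(x)
  t_in <- (seq_len(n) - 1) / fs
  t_out <- seq(0, t_in[n], by = 1 / fs_out)
  approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Windowed skin temperature
#'
#' Resamples to 64 Hz, low-passes at 10 Hz (zero phase; skipped when the
#' Nyquist limit makes a 10 Hz corner meaningless), and returns per-window
#' means over non-overlapping 10 s windows.
#'
#' @param st a skin-temperature [channel_signal()] or numeric with `fs`.
#' @param fs sampling rate for bare vectors.
#' @param window window length in seconds (default 10).
#' @return a `windowed_series` in degrees Celsius.
#' @export
temperature_windows <- function(st, fs = NULL, window = 10) {
  sig <- if (inherits(st, "channel_signal")) st else
    channel_signal("skin_temperature", fs, st)
  dur <- signal_duration(sig)
  if (dur < window) stop_invalid_argument("epoch shorter than one window")
  fs64 <- 64
  v <- resample_linear(sig$values, sig$fs, fs64)
  v <- zerophase(butter_design(4, 10, fs64, "low"), v)
  nw <- floor(dur / window)
  per <- window * fs64
  vals <- vapply(seq_len(nw), function(i)
    mean(v[seq((i - 1) * per + 1, min(i * per, length(v)))]), numeric(1))
  windowed_series(vals, window, "degC")
}

#' Per-window means of an arbitrary sampled trace
#'
#' Generic windowing used for the SCL (mean value) and SCR (mean absolute
#' value) segment features.
#'
#' @param x a [channel_signal()] or numeric vector with `fs`.
#' @param fs sampling rate for bare vectors.
#' @param window window length in seconds (default 10).
#' @param absolute take `abs()` of the samples first (for phasic amplitude).
#' @param units unit label carried on the result.
#' @return a `windowed_series`.
#' @export
signal_windows <- function(x, fs = NULL, window = 10, absolute = FALSE,
                           units = "") {
  sig <- as_channel_like(x, fs)
  dur <- signal_duration(sig)
  if (dur < window) stop_invalid_argument("epoch shorter than one window")
  v <- if (absolute) abs(sig$values) else sig$values
  nw <- floor(dur / window)
  per <- window * sig$fs
  vals <- vapply(seq_len(nw), function(i)
    mean(v[seq(round((i - 1) * per) + 1, min(round(i * per), length(v)))]),
    numeric(1))
  windowed_series(vals, window, units)
}
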