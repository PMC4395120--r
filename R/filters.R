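# Zero-phase IIR filtering. All conditioning filters are 4th-order
# Butterworth designs (the band-stop uses a 2nd-order prototype, i.e. four
# poles) applied forward-backward, so pass-band peak positions are not
# shifted. Signals are padded by odd reflection before filtering to suppress
# end transients, as is standard for forward-backward application.

butter_design <- function(order, cutoff, fs, type) {
  ny <- fs / 2
  if (any(cutoff <= 0) || any(cutoff >= ny))
    stop_invalid_argument(sprintf(
      "cutoff(s) %s Hz must lie strictly inside (0, %g) Hz",
      paste(cutoff, collapse = "-"), ny))
  signal::butter(order, cutoff / ny, type = type)
}

# forward-backward filtering with odd-reflection padding
zerophase <- function(filt, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1, 3000)
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(pre, x, post)
  } else xp <- x
  y <- signal::filtfilt(filt, xp)
  y[seq(pad + 1, pad + n)]
}

#' Condition a raw ECG trace
#'
#' Applies, forward-backward (zero phase), a 0.5 Hz high-pass (baseline and
#' respiration drift), a 100 Hz low-pass (high-frequency noise), and a
#' 49-51 Hz band-stop (mains hum).
#'
#' @param x a [channel_signal()] (or numeric vector with `fs` given)
#'   sampled at >= 256 Hz.
#' @param fs sampling rate, required when `x` is a bare vector.
#' @return a [channel_signal()] with the filtered trace.
#' @export
bandlimit_ecg <- function(x, fs = NULL) {
  sig <- as_channel_like(x, fs)
  if (sig$fs < 256) stop_invalid_argument("ECG sampling rate must be >= 256 Hz")
  v <- sig$values
  v <- zerophase(butter_design(4, 0.5, sig$fs, "high"), v,
                 pad = min(length(v) - 1, round(4 * sig$fs)))
  lp <- min(100, sig$fs / 2 * 0.95)
  v <- zerophase(butter_design(4, lp, sig$fs, "low"), v)
  v <- zerophase(butter_design(2, c(49, 51), sig$fs, "stop"), v)
  out <- sig
  out$values <- v
  out
}

#' Tonic skin conductance level (SCL)
#'
#' Low-pass at 1 Hz, zero phase.
#'
#' @param x a skin-conductance [channel_signal()] (or numeric with `fs`),
#'   sampled at >= 8 Hz.
#' @param fs sampling rate for bare vectors.
#' @return a [channel_signal()] holding the tonic component.
#' @export
scl_component <- function(x, fs = NULL) {
  sig <- if (inherits(x, "channel_signal")) x else
    channel_signal("skin_conductance", fs, x)
  if (sig$fs < 8) stop_invalid_argument("sampling rate must be >= 8 Hz")
  out <- sig
  out$values <- zerophase(butter_design(4, 1, sig$fs, "low"), sig$values,
                          pad = min(length(sig$values) - 1, round(4 * sig$fs)))
  out
}

#' Phasic skin conductance response (SCR)
#'
#' Low-pass at 1 Hz followed by high-pass at 0.5 Hz, both zero phase, leaving
#' the 0.5-1 Hz band that carries phasic response energy.
#'
#' @inheritParams scl_component
#' @return a [channel_signal()] holding the phasic component.
#' @export
scr_component <- function(x, fs = NULL) {
  sig <- scl_component(x, fs)
  out <- sig
  out$values <- zerophase(butter_design(4, 0.5, sig$fs, "high"), sig$values,
                          pad = min(length(sig$values) - 1, round(6 * sig$fs)))
  out
}

# band-pass via cascaded high/low zero-phase Butterworths
bandpass_zerophase <- function(x, fs, low, high, order = 4) {
  v <- zerophase(butter_design(order, low, fs, "high"), x,
                 pad = min(length(x) - 1, round(3 / low * fs)))
  zerophase(butter_design(order, high, fs, "low"), v)
}

#' Squared zero-phase gain of a conditioning filter at given frequencies
#'
#' Numerically evaluates `|H(f)|^2` (forward-backward application squares the
#' magnitude response) for one of the package's filter designs. Used as the
#' oracle in frequency-response tests.
#'
#' @param which one of `"ecg_high"`, `"ecg_low"`, `"ecg_stop"`, `"scl_low"`,
#'   `"scr_high"`.
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector of squared gains.
#' @export
filter_gain2 <- function(which = c("ecg_high", "ecg_low", "ecg_stop",
                                   "scl_low", "scr_high"), f, fs) {
  which <- match.arg(which)
  filt <- switch(which,
    ecg_high = butter_design(4, 0.5, fs, "high"),
    ecg_low  = butter_design(4, min(100, fs / 2 * 0.95), fs, "low"),
    ecg_stop = butter_design(2, c(49, 51), fs, "stop"),
    scl_low  = butter_design(4, 1, fs, "low"),
    scr_high = butter_design(4, 0.5, fs, "high"))
  w <- 2 * pi * f / fs
  H <- vapply(w, function(wi) {
    z <- exp(-1i * wi * (seq_along(filt$b) - 1))
    num <- sum(filt$b * z)
    z <- exp(-1i * wi * (seq_along(filt$a) - 1))
    Mod(num / sum(filt$a * z))
  }, numeric(1))
  H^2
}
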