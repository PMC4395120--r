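# Per-channel signal generators. These produce idealized but spectrally
# controllable traces: downstream features depend on beat timing, band power
# and slow trends, not on waveform morphology, so the models are deliberately
# minimal (Gaussian R-wave templates, bi-exponential SCRs, sinusoidal
# respiration, linear temperature drift).

#' Synthesize an ECG-like trace with known beat times
#'
#' Beat-to-beat (RR) intervals are generated as
#' `RR_i = (60/mean_hr) * (1 + hrv_scale * m(t_i))` where `m(t)` is the sum of
#' a 0.1 Hz (low-frequency, baroreflex-like) and a 0.25 Hz (high-frequency,
#' respiratory-like) sinusoidal modulation plus white jitter. A Gaussian
#' R-wave template (sd 8 ms) is placed at each beat time, so the sample-level
#' argmax of each beat coincides with the generating beat time. The exact
#' beat times are returned as ground truth for validating beat detectors.
#'
#' @param mean_hr mean heart rate in beats/min, within `[30, 200]`.
#' @param hrv_scale non-negative multiplier on all RR variability
#'   (0 = metronomic heart).
#' @param duration epoch length in seconds (> 10).
#' @param fs sampling rate in Hz (default 512).
#' @param seed integer seed for the jitter stream.
#' @param noise_sd standard deviation of additive white measurement noise.
#' @param lf_amp,hf_amp fractional RR modulation depths at 0.1 and 0.25 Hz.
#' @param jitter_sd fractional white RR jitter at `hrv_scale = 1`.
#' @return a list with `signal` (a [channel_signal()]) and `beat_times`
#'   (seconds, strictly increasing).
#' @examples
#' ecg <- synthesize_ecg(mean_hr = 60, hrv_scale = 0, duration = 30, seed = 1)
#' diff(ecg$beat_times)[1:5]  # exactly 1 s at 60 bpm, no variability
#' @export
synthesize_ecg <- function(mean_hr, hrv_scale = 1, duration = 300, fs = 512,
                           seed = 1, noise_sd = 0.02,
                           lf_amp = 0.03, hf_amp = 0.025, jitter_sd = 0.01) {
  if (!is.numeric(fs) || fs <= 0) stop_invalid_argument("`fs` must be positive")
  if (!is.numeric(duration) || duration <= 0)
    stop_invalid_argument("`duration` must be positive")
  if (duration <= 10) stop_invalid_argument("`duration` must exceed 10 s")
  if (mean_hr < 30 || mean_hr > 200)
    stop_invalid_argument("`mean_hr` must lie in [30, 200] beats/min")
  if (hrv_scale < 0) stop_invalid_argument("`hrv_scale` must be >= 0")

  mean_rr <- 60 / mean_hr
  with_seed(seed, {
    # generate beats sequentially; first beat centred half an interval in so a
    # metronomic 60 bpm heart yields exactly `duration` beats in the epoch
    n_max <- ceiling(duration / mean_rr) + 16
    jit <- rnorm(n_max, 0, jitter_sd * hrv_scale)
    beat_times <- numeric(n_max)
    t_cur <- mean_rr / 2
    i <- 0
    while (t_cur < duration) {
      i <- i + 1
      beat_times[i] <- t_cur
      mod <- lf_amp * sin(2 * pi * 0.10 * t_cur) +
             hf_amp * sin(2 * pi * 0.25 * t_cur)
      rr <- mean_rr * (1 + hrv_scale * mod + jit[i])
      rr <- max(rr, 0.2)
      t_cur <- t_cur + rr
    }
    beat_times <- beat_times[seq_len(i)]

    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    x <- numeric(n)
    width <- 0.008  # Gaussian R-wave sd, seconds
    half <- ceiling(4 * width * fs)
    for (bt in beat_times) {
      ci <- round(bt * fs) + 1
      lo <- max(1, ci - half); hi <- min(n, ci + half)
      idx <- lo:hi
      x[idx] <- x[idx] + exp(-((t[idx] - bt)^2) / (2 * width^2))
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    list(signal = channel_signal("ecg", fs, x), beat_times = beat_times)
  })
}

#' Synthesize a skin conductance trace
#'
#' Tonic component: `scl_level + scl_slope * t/60` plus a slow (0.01 Hz)
#' low-amplitude sinusoid. Phasic component: skin conductance responses with
#' standard bi-exponential kinetics (~1 s rise, ~3 s decay) at Poisson onsets
#' with the given event rate and log-normally varying amplitudes.
#'
#' @param scl_level tonic level in microsiemens (> 0).
#' @param scl_slope tonic drift in microsiemens per minute.
#' @param scr_rate phasic event rate in events/min (>= 0).
#' @param duration epoch length in seconds.
#' @param fs sampling rate in Hz (>= 32; default 256).
#' @param seed integer seed.
#' @param scr_amp median SCR amplitude in microsiemens.
#' @param drift_amp amplitude of the slow tonic sinusoid (microsiemens).
#' @param noise_sd additive measurement noise sd.
#' @return a [channel_signal()]; attribute `n_events` records the number of
#'   injected phasic responses.
#' @export
synthesize_skin_conductance <- function(scl_level, scl_slope = 0, scr_rate = 6,
                                        duration = 300, fs = 256, seed = 1,
                                        scr_amp = 0.3, drift_amp = 0.05,
                                        noise_sd = 0.005) {
  if (scl_level <= 0) stop_invalid_argument("`scl_level` must be positive")
  if (fs < 32) stop_invalid_argument("`fs` must be >= 32 Hz")
  if (scr_rate < 0) stop_invalid_argument("`scr_rate` must be >= 0")
  if (duration <= 0) stop_invalid_argument("`duration` must be positive")

  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    tonic <- scl_level + scl_slope * t / 60 +
      drift_amp * sin(2 * pi * 0.01 * t)
    phasic <- numeric(n)
    n_ev <- rpois(1, scr_rate * duration / 60)
    if (n_ev > 0) {
      onsets <- sort(runif(n_ev, 0, duration))
      amps <- scr_amp * exp(rnorm(n_ev, 0, 0.4))
      tau_r <- 1; tau_d <- 3
      for (j in seq_len(n_ev)) {
        rel <- t - onsets[j]
        idx <- which(rel >= 0 & rel < 20)
        if (!length(idx)) next
        shape <- exp(-rel[idx] / tau_d) - exp(-rel[idx] / tau_r)
        peak <- max(shape)
        if (peak > 0) phasic[idx] <- phasic[idx] + amps[j] * shape / peak
      }
    }
    x <- tonic + phasic
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    out <- channel_signal("skin_conductance", fs, x)
    attr(out, "n_events") <- n_ev
    out
  })
}

#' Synthesize a respiration trace
#'
#' A sinusoid at `rate/60` Hz plus band-limited noise (white noise smoothed
#' by a short moving average), emulating a chest-belt signal.
#'
#' @param rate breathing rate in breaths/min (> 0).
#' @param duration epoch length in seconds.
#' @param fs sampling rate in Hz (default 32).
#' @param seed integer seed.
#' @param amp sinusoid amplitude (arbitrary belt units).
#' @param noise_amp amplitude of the band-limited noise (0 for a pure tone).
#' @return a [channel_signal()].
#' @export
synthesize_respiration <- function(rate, duration = 300, fs = 32, seed = 1,
                                   amp = 1, noise_amp = 0.05) {
  if (!is.numeric(rate) || rate <= 0) stop_invalid_argument("`rate` must be positive")
  if (duration <= 0 || fs <= 0) stop_invalid_argument("positive `duration` and `fs` required")
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    x <- amp * sin(2 * pi * rate / 60 * t)
    if (noise_amp > 0) {
      w <- rnorm(n)
      k <- max(3, round(fs / 4))
      sm <- stats::filter(w, rep(1 / k, k), sides = 2)
      sm[is.na(sm)] <- 0
      x <- x + noise_amp * as.numeric(sm)
    }
    channel_signal("respiration", fs, x)
  })
}

#' Synthesize a skin temperature trace
#'
#' `level + slope * t/60` plus low-amplitude noise; skin temperature is a
#' slow signal and is modelled as drift only.
#'
#' @param level baseline temperature, degrees Celsius.
#' @param slope drift in degrees Celsius per minute.
#' @param duration epoch length in seconds.
#' @param fs sampling rate in Hz (default 32).
#' @param seed integer seed.
#' @param noise_sd additive noise sd (degrees Celsius).
#' @return a [channel_signal()].
#' @export
synthesize_temperature <- function(level, slope = 0, duration = 300, fs = 32,
                                   seed = 1, noise_sd = 0.01) {
  if (duration <= 0 || fs <= 0) stop_invalid_argument("positive `duration` and `fs` required")
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (seq_len(n) - 1) / fs
    x <- level + slope * t / 60
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    channel_signal("skin_temperature", fs, x)
  })
}

#' Draw a SAM report for one stimulus class
#'
#' Draws arousal, valence and dominance ratings from normal distributions
#' with the class's mean and standard deviation, rounds to the nearest
#' integer and clips to the 1-9 SAM scale. Rounding/clipping can be disabled
#' to inspect the latent continuous distribution.
#'
#' @param class a class label present in `profiles`.
#' @param profiles a profile set from [class_effect_profiles()].
#' @param seed integer seed.
#' @param n number of reports to draw.
#' @param round,clip apply integer rounding / 1-9 clipping (defaults `TRUE`).
#' @return an `n x 3` matrix with columns `arousal`, `valence`, `dominance`.
#' @examples
#' p <- class_effect_profiles()
#' generate_sam("anima", p, seed = 1)
#' @export
generate_sam <- function(class, profiles, seed = 1, n = 1,
                         round = TRUE, clip = TRUE) {
  pr <- profiles[[class]]
  if (is.null(pr)) stop_invalid_argument(sprintf("no profile for class '%s'", class))
  with_seed(seed, {
    out <- sapply(seq_len(3), function(j)
      rnorm(n, pr$sam_means[j], pr$sam_sds[j]))
    out <- matrix(out, nrow = n, dimnames = list(NULL, c("arousal", "valence", "dominance")))
    if (round) out <- base::round(out)
    if (clip) out <- pmin(pmax(out, 1), 9)
    out
  })
}
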