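# Filters, beat detection, HRV, windowed series.

test_that("ECG conditioning attenuates mains hum and DC, passes 10 Hz", {
  fs <- 512
  t <- seq(0, 20, by = 1 / fs)
  hum <- sin(2 * pi * 50 * t)
  expect_lt(sd(bandlimit_ecg(hum, fs = fs)$values) / sd(hum), 0.05)
  dc <- bandlimit_ecg(rep(1, length(t)), fs = fs)
  expect_lt(sqrt(mean(dc$values^2)), 0.01)
  s10 <- sin(2 * pi * 10 * t)
  g <- sd(bandlimit_ecg(s10, fs = fs)$values) / sd(s10)
  expect_gt(g, 0.9); expect_lt(g, 1.1)
  expect_error(bandlimit_ecg(s10, fs = 128), class = "archepsy_invalid_argument")
})

test_that("empirical filter gains match the analytic frequency response", {
  fs <- 512
  t <- seq(0, 30, by = 1 / fs)
  for (f0 in c(2, 10, 30, 50, 80)) {
    x <- sin(2 * pi * f0 * t)
    y <- bandlimit_ecg(x, fs = fs)$values
    mid <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
    emp <- sd(y[mid]) / sd(x[mid])
    # forward-backward application gives the squared magnitude response
    ana <- filter_gain2("ecg_high", f0, fs) *
      filter_gain2("ecg_low", f0, fs) *
      filter_gain2("ecg_stop", f0, fs)
    if (ana < 1e-3) expect_lt(emp, 1e-3)
    else expect_equal(emp, ana, tolerance = 0.02,
                      label = sprintf("gain @%g Hz", f0))
  }
})

test_that("SCL/SCR decomposition separates tonic from phasic bands", {
  fs <- 256
  t <- seq(0, 60, by = 1 / fs)
  cst <- rep(5, length(t))
  expect_equal(mean(scl_component(cst, fs = fs)$values), 5, tolerance = 1e-3)
  expect_lt(max(abs(scr_component(cst, fs = fs)$values)), 0.01)

  slow <- sin(2 * pi * 0.05 * t)
  mid <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_gt(sd(scl_component(slow, fs = fs)$values[mid]) / sd(slow[mid]), 0.9)
  expect_lt(sqrt(mean(scr_component(slow, fs = fs)$values[mid]^2)) /
            sqrt(mean(slow[mid]^2)), 0.1)

  # the phasic pass-band (0.5-1 Hz) retains 0.75 Hz content while strongly
  # rejecting the slow tonic band
  fast <- sin(2 * pi * 0.75 * t)
  g_scr_fast <- sd(scr_component(fast, fs = fs)$values[mid]) / sd(fast[mid])
  g_scr_slow <- sd(scr_component(slow, fs = fs)$values[mid]) / sd(slow[mid])
  expect_gt(g_scr_fast, 0.5)
  expect_lt(g_scr_slow, 0.05)
  # and empirical gains match the analytic response of the cascaded design
  g_scl_fast <- sd(scl_component(fast, fs = fs)$values[mid]) / sd(fast[mid])
  expect_equal(g_scl_fast, filter_gain2("scl_low", 0.75, fs),
               tolerance = 0.05)
})

test_that("zero-phase ECG conditioning leaves pulse peak positions unchanged", {
  fs <- 512
  x <- numeric(fs * 20)
  peaks <- seq(fs, length(x) - fs, by = fs)  # one pulse per second
  x[peaks] <- 1
  y <- bandlimit_ecg(x, fs = fs)$values
  for (p in peaks) {
    win <- (p - fs %/% 4):(p + fs %/% 4)
    expect_lte(abs(win[which.max(y[win])] - p), 1)
  }
})

test_that("beat detection recovers ground-truth beats at 20 dB SNR", {
  e <- synthesize_ecg(72, hrv_scale = 1, duration = 300, fs = 512, seed = 9,
                      noise_sd = 0)
  sig_rms <- sqrt(mean(e$signal$values^2))
  set.seed(10)
  noisy <- e$signal
  noisy$values <- noisy$values + rnorm(length(noisy$values),
                                       sd = sig_rms / 10^(20 / 20))
  beats <- detect_beats(bandlimit_ecg(noisy))
  dt <- vapply(e$beat_times, function(bt) min(abs(beats$times - bt)),
               numeric(1))
  expect_gte(mean(dt <= 0.010), 0.99)       # recall with |dt| <= 10 ms
  expect_lte(max(dt[dt <= 0.050]), 0.010)   # matched beats within 10 ms
})

test_that("beat detection edge cases", {
  expect_error(detect_beats(rep(0, 512 * 30), fs = 512),
               class = "archepsy_insufficient_signal")
  b <- beat_series(seq(0.5, 299.5, by = 1))
  expect_true(all(b$rr == 1000))
  expect_error(beat_series(c(1, 1, 2)), class = "archepsy_invalid_argument")
})

test_that("time-domain HRV matches direct formula evaluation", {
  rr <- c(800, 1000, 800, 1000, 800)
  td <- hrv_time_domain(rr)
  expect_equal(td$rmssd, 200.0)
  expect_equal(td$sdnn, sqrt(sum((rr - mean(rr))^2) / 4), tolerance = 1e-12)
  expect_equal(round(td$sdnn, 3), 109.545)
  cst <- hrv_time_domain(rep(900, 10))
  expect_equal(unlist(cst), c(sdnn = 0, rmssd = 0, sdsd = 0))
  expect_error(hrv_time_domain(c(800, 900)), class = "archepsy_insufficient_data")
})

test_that("time-domain HRV equals a brute-force loop reference to 1e-9", {
  brute <- function(rr) {
    n <- length(rr); m <- sum(rr) / n
    sdnn <- sqrt(sum((rr - m)^2) / (n - 1))
    ssq <- 0
    for (i in 2:n) ssq <- ssq + (rr[i] - rr[i - 1])^2
    rmssd <- sqrt(ssq / (n - 1))
    d <- rr[-1] - rr[-n]; md <- mean(d)
    sdsd <- sqrt(sum((d - md)^2) / (length(d) - 1))
    c(sdnn, rmssd, sdsd)
  }
  set.seed(42)
  for (i in 1:25) {
    rr <- 800 + rnorm(sample(5:200, 1), sd = 60)
    expect_equal(unlist(hrv_time_domain(rr)), brute(rr),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("frequency-domain HRV localizes band power correctly", {
  lf_mod <- hrv_frequency_domain(modulated_beats(0.10))
  expect_gt(lf_mod$lf_hf, 5)
  hf_mod <- hrv_frequency_domain(modulated_beats(0.30))
  expect_lt(hf_mod$lf_hf, 0.2)
  flat <- hrv_frequency_domain(beat_series(seq(0.5, 299.5, by = 1)))
  expect_lt(flat$total_power, 1e-6)
  for (fd in list(lf_mod, hf_mod)) {
    expect_true(all(unlist(fd[c("vlf", "lf", "hf")]) >= 0))
    expect_lte(fd$vlf + fd$lf + fd$hf,
               fd$total_power * (1 + 1e-6))
  }
  expect_error(hrv_frequency_domain(beat_series(seq(0.5, 30, by = 1))),
               class = "archepsy_insufficient_data")
})

test_that("windowed heart rate follows the 60000/mean(RR) rule", {
  b <- beat_series(seq(0.5, 299.5, by = 1))
  hw <- heart_rate_windows(b, 300)
  expect_length(hw, 30)
  expect_true(all(abs(as.numeric(hw) - 60) < 1e-9))

  alt <- beat_series(cumsum(c(0.5, rep(c(0.8, 1.0), 150))))
  hw2 <- heart_rate_windows(alt, 300)
  expect_equal(as.numeric(hw2)[2], 60000 / 900, tolerance = 0.5)

  # a window with no beats is imputed from its nearest neighbor and flagged
  gap <- beat_series(c(seq(0.5, 9.5, 1), seq(20.5, 29.5, 1)))
  hw3 <- heart_rate_windows(gap, 30)
  expect_true(attr(hw3, "imputed")[2])
  expect_false(attr(hw3, "imputed")[1])
  expect_error(heart_rate_windows(b, 5), class = "archepsy_invalid_argument")
})

test_that("windowed respiration rate recovers paced breathing", {
  r15 <- synthesize_respiration(15, duration = 300, fs = 32, seed = 1,
                                noise_amp = 0)
  w <- respiration_rate_windows(r15)
  expect_length(w, 30)
  expect_true(all(abs(as.numeric(w) - 15) < 0.01))

  r14 <- synthesize_respiration(14, duration = 300, fs = 32, seed = 1,
                                noise_amp = 0)
  w14 <- respiration_rate_windows(r14)
  expect_true(all(abs(as.numeric(w14) - 14) < 0.3))

  # ramped rate produces (near) monotone window means
  fs <- 32; dur <- 300
  t <- seq(0, dur, by = 1 / fs)
  inst <- 12 + (18 - 12) * t / dur            # breaths/min
  phase <- 2 * pi * cumsum(inst / 60) / fs
  w_r <- respiration_rate_windows(sin(phase), fs = fs)
  expect_true(all(diff(as.numeric(w_r)) > -0.3))
  expect_gt(as.numeric(w_r)[30] - as.numeric(w_r)[1], 4)

  expect_error(respiration_rate_windows(rep(0, 32 * 60), fs = 32),
               class = "archepsy_insufficient_signal")
})

test_that("windowed temperature averages the smoothed trace", {
  cst <- temperature_windows(rep(33, 32 * 300), fs = 32)
  expect_length(cst, 30)
  expect_true(all(abs(as.numeric(cst) - 33) < 1e-6))

  ramp <- synthesize_temperature(33, slope = 1 / 5, duration = 300,
                                 seed = 1, noise_sd = 0)  # 33 -> 34 degC
  tw <- temperature_windows(ramp)
  expect_equal(as.numeric(tw)[1], 33 + 0.5 * 10 / 300, tolerance = 2e-3)
  expect_length(tw, 30)
})
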