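# Channel generators and cohort construction.

test_that("metronomic ECG yields exact beat spacing and closed-form mean RR", {
  e <- synthesize_ecg(60, hrv_scale = 0, duration = 300, fs = 512, seed = 1,
                      noise_sd = 0)
  expect_length(e$beat_times, 300)
  expect_equal(unique(diff(e$beat_times)), 1.0, tolerance = 1e-12)

  e72 <- synthesize_ecg(72, hrv_scale = 0, duration = 300, seed = 1)
  expect_equal(mean(diff(e72$beat_times)), 60 / 72, tolerance = 1e-9)

  e_var <- synthesize_ecg(60, hrv_scale = 1, duration = 60, seed = 2)
  rr <- diff(e_var$beat_times) * 1000
  expect_gt(hrv_time_domain(rr)$rmssd, 0)
})

test_that("ECG R-wave apices coincide with the returned beat times", {
  e <- synthesize_ecg(75, hrv_scale = 1, duration = 30, fs = 512, seed = 5,
                      noise_sd = 0)
  fs <- e$signal$fs
  for (bt in e$beat_times[2:(length(e$beat_times) - 1)]) {
    ci <- round(bt * fs) + 1
    win <- (ci - 20):(ci + 20)
    apex <- win[which.max(e$signal$values[win])]
    expect_lte(abs(apex - 1 - bt * fs), 1)  # within one sample
  }
})

test_that("ECG generator rejects invalid arguments", {
  expect_error(synthesize_ecg(60, duration = -5), class = "archepsy_invalid_argument")
  expect_error(synthesize_ecg(60, duration = 60, fs = 0), class = "archepsy_invalid_argument")
  expect_error(synthesize_ecg(250, duration = 60), class = "archepsy_invalid_argument")
})

test_that("skin conductance: tonic-only trace, Poisson event count, determinism", {
  quiet <- synthesize_skin_conductance(5, scl_slope = 0, scr_rate = 0,
                                       duration = 60, seed = 3, noise_sd = 0)
  expect_equal(attr(quiet, "n_events"), 0)
  # constant tonic level +/- the slow drift component only
  expect_lt(diff(range(quiet$values)), 2 * 0.05 + 1e-6)

  # expected number of injected events = rate * duration / 60
  counts <- vapply(1:60, function(s)
    attr(synthesize_skin_conductance(5, scr_rate = 6, duration = 300,
                                     seed = s), "n_events"), numeric(1))
  expect_equal(mean(counts), 30, tolerance = 3 * sqrt(30 / 60) / 30 * 3)

  a <- synthesize_skin_conductance(5, 0.1, 6, duration = 60, seed = 42)
  b <- synthesize_skin_conductance(5, 0.1, 6, duration = 60, seed = 42)
  expect_identical(a$values, b$values)
  expect_error(synthesize_skin_conductance(5, scr_rate = -1, duration = 60),
               class = "archepsy_invalid_argument")
  expect_error(synthesize_skin_conductance(-2, duration = 60),
               class = "archepsy_invalid_argument")
})

test_that("respiration carries its dominant spectral peak at rate/60 Hz", {
  for (rate in c(15, 14)) {
    r <- synthesize_respiration(rate, duration = 300, fs = 32, seed = 1)
    v <- r$values - mean(r$values)
    spec <- Mod(fft(v))^2
    f <- (seq_along(v) - 1) * 32 / length(v)
    keep <- f > 0.05 & f < 1
    expect_equal(f[keep][which.max(spec[keep])], rate / 60,
                 tolerance = 0.01)
  }
  expect_error(synthesize_respiration(0, duration = 60),
               class = "archepsy_invalid_argument")
})

test_that("noise-free temperature is an exact linear ramp", {
  tp <- synthesize_temperature(33, slope = 0, duration = 60, seed = 1,
                               noise_sd = 0)
  expect_equal(unique(tp$values), 33)
  tp2 <- synthesize_temperature(33, slope = 1, duration = 60, seed = 1,
                                noise_sd = 0)
  expect_equal(tp2$values[length(tp2$values)] - tp2$values[1],
               (length(tp2$values) - 1) / 32 / 60, tolerance = 1e-9)
})

test_that("SAM draws follow the class profile and respect the 1-9 scale", {
  p <- class_effect_profiles()
  p$anima$sam_sds <- c(0, 0, 0)
  p$anima$sam_means <- c(5, 5, 5)
  expect_equal(as.numeric(generate_sam("anima", p, seed = 1)), c(5, 5, 5))

  # latent (unrounded, unclipped) mean matches the published anima arousal
  q <- class_effect_profiles()
  draws <- generate_sam("anima", q, seed = 2, n = 1e5, round = FALSE,
                        clip = FALSE)
  expect_equal(mean(draws[, "arousal"]), 5.320, tolerance = 0.05)

  q$anima$sam_means <- c(9.4, 9.4, 9.4)
  q$anima$sam_sds <- c(0.2, 0.2, 0.2)
  expect_true(all(generate_sam("anima", q, seed = 3, n = 100) == 9))
  r <- generate_sam("hero", q, seed = 4, n = 200)
  expect_true(all(r >= 1 & r <= 9) && all(r == round(r)))
})

test_that("cohort structure, determinism, and null construction", {
  cfg <- small_config(n_subjects = 3, stimulus_duration = 60, seed = 21)
  sessions <- generate_cohort(cfg)
  expect_length(sessions, 3)
  s <- sessions[[1]]
  expect_length(s$epochs, 8)
  for (cl in s$classes) {
    expect_named(s$epochs[[cl]], c("baseline", "stimulus"))
    expect_length(s$epochs[[cl]]$stimulus$channels, 4)
    expect_length(s$epochs[[cl]]$baseline$channels, 4)
  }
  expect_true(all(s$sam >= 1 & s$sam <= 9))

  sessions_b <- generate_cohort(cfg)
  expect_identical(
    sessions[[2]]$epochs$hero$stimulus$channels$ecg$values,
    sessions_b[[2]]$epochs$hero$stimulus$channels$ecg$values)
  expect_identical(sessions[[3]]$sam, sessions_b[[3]]$sam)

  expect_error(generate_cohort(cfg, subject_ids = c(1, 1, 2)),
               class = "archepsy_invalid_argument")
})

test_that("null cohort has no class effect on generating heart rates", {
  cfg <- small_config(n_subjects = 6, stimulus_duration = 60, seed = 31,
                      effect_size = 0)
  sessions <- generate_cohort(cfg)
  # generator-truth stimulus HR per class, centred per subject
  hr <- sapply(sessions, function(s)
    vapply(s$classes, function(cl)
      s$epochs[[cl]]$stimulus$truth$params$hr, numeric(1)))
  centred <- sweep(hr, 2, colMeans(hr))
  class_means <- rowMeans(centred)
  # epoch noise sd 2.5 / sqrt(6 subjects) ~ 1.0; class means ~ N(0, 1)
  expect_lt(max(abs(class_means)), 3.5)
  # and the SAM profiles collapse to the grand mean
  p0 <- class_effect_profiles(0)
  expect_equal(p0$anima$sam_means, p0$hero$sam_means)
  expect_equal(p0$animus$delta_hr, p0$shadow$delta_hr)
})

test_that("cohort round-trips through the on-disk manifest", {
  cfg <- cohort_config(n_subjects = 3, stimulus_duration = 20,
                       baseline_duration = 20, seed = 5,
                       fs_ecg = 256, fs_sc = 32)
  sessions <- generate_cohort(cfg)
  dir <- scratch_dir()
  write_cohort(sessions, dir)
  back <- read_cohort(dir)
  expect_length(back, 3)
  expect_equal(back[[1]]$epochs$hero$stimulus$channels$respiration$values,
               sessions[[1]]$epochs$hero$stimulus$channels$respiration$values,
               tolerance = 1e-6)
  expect_equal(unname(back[[2]]$sam), unname(sessions[[2]]$sam))
})
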