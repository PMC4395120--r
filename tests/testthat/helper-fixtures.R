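# Shared fixtures, built in code. Small cohorts use shortened stimulus
# epochs (a multiple of the 10 s segment length) to keep the suite fast.

small_config <- function(n_subjects = 4, stimulus_duration = 120, seed = 11,
                         effect_size = 1) {
  cohort_config(n_subjects = n_subjects,
                stimulus_duration = stimulus_duration,
                effect_size = effect_size, seed = seed)
}

scratch_dir <- function(prefix = "archepsy") {
  d <- tempfile(prefix)
  dir.create(d, recursive = TRUE)
  d
}

# four well-separated Gaussian clusters in `p` dimensions
separated_clusters <- function(n_per = 25, p = 5, gap = 10, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(0:3, function(g)
    matrix(rnorm(n_per * p, mean = g * gap), n_per, p)))
  list(x = x, labels = rep(c("a", "b", "c", "d"), each = n_per))
}

# beat series with a pure sinusoidal RR modulation at `f_mod` Hz
modulated_beats <- function(f_mod, depth = 0.05, duration = 300,
                            mean_rr = 1) {
  times <- numeric(0)
  t_cur <- mean_rr / 2
  while (t_cur < duration) {
    times <- c(times, t_cur)
    t_cur <- t_cur + mean_rr * (1 + depth * sin(2 * pi * f_mod * t_cur))
  }
  beat_series(times)
}
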