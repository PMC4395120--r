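# Cohort generation: a seeded study emulator. Each subject contributes one
# baseline + stimulus epoch pair per class across four channels, plus one SAM
# report per stimulus. Between-subject variance enters through subject-level
# random offsets (resting heart rate, tonic skin conductance level, baseline
# temperature, an HRV multiplier); within-class variance through per-epoch
# parameter jitter. Class effects come from the effect profiles.

#' Cohort configuration
#'
#' @param n_subjects number of subjects (>= 3, default 25).
#' @param classes ordered class labels; default the eight study classes.
#' @param stimulus_duration stimulus epoch length in seconds; must be a
#'   positive multiple of the 10 s segment length (default 300).
#' @param baseline_duration paced-breathing baseline length in seconds
#'   (default 40).
#' @param effect_size scalar in `[0, 1]` scaling all class effects
#'   (0 = null cohort).
#' @param seed root integer seed; all cohort randomness derives from it.
#' @param fs_ecg,fs_sc,fs_resp,fs_temp per-channel sampling rates in Hz.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 25, classes = study_classes(),
                          stimulus_duration = 300, baseline_duration = 40,
                          effect_size = 1, seed = 1,
                          fs_ecg = 512, fs_sc = 256, fs_resp = 32,
                          fs_temp = 32) {
  if (n_subjects < 3) stop_invalid_argument("`n_subjects` must be >= 3")
  if (anyDuplicated(classes)) stop_invalid_argument("class labels must be unique")
  if (stimulus_duration <= 0 || stimulus_duration %% 10 != 0)
    stop_invalid_argument("`stimulus_duration` must be a positive multiple of 10 s")
  if (baseline_duration <= 10)
    stop_invalid_argument("`baseline_duration` must exceed 10 s")
  if (effect_size < 0 || effect_size > 1)
    stop_invalid_argument("`effect_size` must lie in [0, 1]")
  structure(
    list(n_subjects = as.integer(n_subjects), classes = classes,
         stimulus_duration = stimulus_duration,
         baseline_duration = baseline_duration,
         effect_size = effect_size, seed = as.integer(seed),
         fs_ecg = fs_ecg, fs_sc = fs_sc, fs_resp = fs_resp,
         fs_temp = fs_temp),
    class = "cohort_config"
  )
}

# within-class epoch-to-epoch jitter (fixed study conditions, not scaled by
# effect_size; see vignette)
epoch_noise_sd <- function() {
  list(hr = 3.0, scl_slope = 0.05, scr_rate = 2.0, resp = 1.0,
       st_slope = 0.015, hrv_log = 0.15)
}

# subject-level offsets drawn once per subject
draw_subject_offsets <- function(seed) {
  with_seed(seed, list(
    resting_hr = max(45, min(110, rnorm(1, 70, 7))),
    scl_level  = max(1.5, rnorm(1, 5, 1)),
    temp_level = rnorm(1, 33, 0.5),
    hrv_mult   = exp(rnorm(1, 0, 0.25))
  ))
}

synth_epoch <- function(config, pars, duration, seed, paced = FALSE) {
  ecg <- synthesize_ecg(mean_hr = pars$hr, hrv_scale = pars$hrv,
                        duration = duration, fs = config$fs_ecg,
                        seed = substream_seed(seed, 1))
  sc <- synthesize_skin_conductance(
    scl_level = pars$scl_level, scl_slope = pars$scl_slope,
    scr_rate = pars$scr_rate, duration = duration, fs = config$fs_sc,
    seed = substream_seed(seed, 2))
  resp <- synthesize_respiration(rate = pars$resp_rate, duration = duration,
                                 fs = config$fs_resp,
                                 seed = substream_seed(seed, 3))
  temp <- synthesize_temperature(level = pars$temp_level,
                                 slope = pars$st_slope, duration = duration,
                                 fs = config$fs_temp,
                                 seed = substream_seed(seed, 4))
  list(
    channels = list(ecg = ecg$signal, skin_conductance = sc,
                    respiration = resp, skin_temperature = temp),
    truth = list(beat_times = ecg$beat_times, resp_rate = pars$resp_rate,
                 params = pars)
  )
}

#' Generate one subject's session
#'
#' @param config a [cohort_config()].
#' @param profiles class effect profiles (default derived from the config's
#'   `effect_size`).
#' @param subject_id subject identifier (integer index into the cohort's
#'   seed space).
#' @return a `session_recording`: per class a baseline and stimulus epoch
#'   (each with four [channel_signal()]s and ground-truth annotations) plus
#'   the SAM report.
#' @export
generate_session <- function(config, profiles = NULL, subject_id = 1) {
  if (is.null(profiles)) profiles <- class_effect_profiles(config$effect_size)
  missing <- setdiff(config$classes, names(profiles))
  if (length(missing))
    stop_invalid_argument(paste("no profile for class:", paste(missing, collapse = ", ")))
  sseed <- substream_seed(config$seed, "subject", subject_id)
  offs <- draw_subject_offsets(substream_seed(sseed, "offsets"))
  nsd <- epoch_noise_sd()
  ref <- profile_reference()

  epochs <- list()
  sam <- matrix(NA_real_, length(config$classes), 3,
                dimnames = list(config$classes,
                                c("arousal", "valence", "dominance")))
  for (ci in seq_along(config$classes)) {
    cl <- config$classes[ci]
    pr <- profiles[[cl]]
    eseed <- substream_seed(sseed, "epoch", ci)

    base_pars <- list(
      hr = offs$resting_hr, hrv = offs$hrv_mult,
      scl_level = offs$scl_level, scl_slope = 0,
      scr_rate = ref$scr_rate, resp_rate = 14,
      temp_level = offs$temp_level, st_slope = 0)
    noise <- with_seed(substream_seed(eseed, "noise"), list(
      hr = rnorm(1, 0, nsd$hr), scl_slope = rnorm(1, 0, nsd$scl_slope),
      scr = rnorm(1, 0, nsd$scr_rate), resp = rnorm(1, 0, nsd$resp),
      st = rnorm(1, 0, nsd$st_slope), hrv = exp(rnorm(1, 0, nsd$hrv_log))))
    stim_pars <- list(
      hr = max(35, min(190, offs$resting_hr + pr$delta_hr + noise$hr)),
      hrv = offs$hrv_mult * pr$hrv_scale * noise$hrv,
      scl_level = offs$scl_level,
      scl_slope = pr$scl_slope + noise$scl_slope,
      scr_rate = max(0, pr$scr_rate + noise$scr),
      resp_rate = max(6, pr$resp_rate + noise$resp),
      temp_level = offs$temp_level,
      st_slope = pr$st_slope + noise$st)

    epochs[[cl]] <- list(
      baseline = synth_epoch(config, base_pars, config$baseline_duration,
                             substream_seed(eseed, "baseline"), paced = TRUE),
      stimulus = synth_epoch(config, stim_pars, config$stimulus_duration,
                             substream_seed(eseed, "stimulus")))
    sam[ci, ] <- generate_sam(cl, profiles, seed = substream_seed(eseed, "sam"))
  }
  structure(
    list(subject = subject_id, classes = config$classes, epochs = epochs,
         sam = sam, config = config),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> subject %s: %d classes x (baseline + stimulus) x 4 channels\n",
              x$subject, length(x$classes)))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Holds every session in memory; for large cohorts prefer streaming one
#' session at a time via [generate_session()] (as [run_study()] does).
#'
#' @param config a [cohort_config()].
#' @param profiles optional class effect profiles.
#' @param subject_ids optional distinct subject identifiers
#'   (default `1:n_subjects`).
#' @return list of `session_recording`s.
#' @export
generate_cohort <- function(config, profiles = NULL, subject_ids = NULL) {
  if (is.null(subject_ids)) subject_ids <- seq_len(config$n_subjects)
  if (anyDuplicated(subject_ids))
    stop_invalid_argument("duplicate subject ids")
  if (length(subject_ids) != config$n_subjects)
    stop_invalid_argument("`subject_ids` must have length `n_subjects`")
  lapply(subject_ids, function(sid)
    generate_session(config, profiles, subject_id = sid))
}

#' Extract the cohort SAM table
#'
#' @param sessions list of `session_recording`s.
#' @return data.frame with columns subject, class, arousal, valence, dominance.
#' @export
cohort_sam_table <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject = s$subject, class = rownames(s$sam),
               arousal = s$sam[, "arousal"], valence = s$sam[, "valence"],
               dominance = s$sam[, "dominance"], row.names = NULL)
  }))
}

#' Write a session to disk as plain-text channel tables plus a JSON manifest
#'
#' Each epoch/channel becomes one two-column tab-separated file
#' (`time_s`, `value`); the manifest records subjects, classes, epoch
#' boundaries, relative file paths and the seed.
#'
#' @param sessions list of `session_recording`s.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sessions[[1]]$config
  entries <- list()
  for (s in sessions) {
    for (cl in s$classes) {
      for (ep in c("baseline", "stimulus")) {
        for (ch in names(s$epochs[[cl]][[ep]]$channels)) {
          sig <- s$epochs[[cl]][[ep]]$channels[[ch]]
          fn <- sprintf("s%s_%s_%s_%s.tsv", s$subject, gsub("[^a-z]", "", cl),
                        ep, ch)
          write.table(
            data.frame(time_s = signal_times(sig), value = sig$values),
            file.path(dir, fn), sep = "\t", row.names = FALSE, quote = FALSE)
          entries[[length(entries) + 1]] <- list(
            subject = s$subject, class = cl, epoch = ep, channel = ch,
            fs = sig$fs, n = length(sig$values), path = fn)
        }
      }
    }
  }
  sam <- cohort_sam_table(sessions)
  write.table(sam, file.path(dir, "sam.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  manifest <- list(
    n_subjects = cfg$n_subjects, classes = cfg$classes,
    stimulus_duration = cfg$stimulus_duration,
    baseline_duration = cfg$baseline_duration,
    effect_size = cfg$effect_size, seed = cfg$seed,
    sam = "sam.tsv", files = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Channel traces are restored from the tabular files; ground-truth
#' annotations are not serialized and are absent from the result.
#'
#' @param dir directory containing `manifest.json`.
#' @return list of `session_recording`s (without `truth` fields).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  cfg <- cohort_config(
    n_subjects = manifest$n_subjects,
    classes = unlist(manifest$classes),
    stimulus_duration = manifest$stimulus_duration,
    baseline_duration = manifest$baseline_duration,
    effect_size = manifest$effect_size, seed = manifest$seed)
  sam_all <- read.table(file.path(dir, manifest$sam), header = TRUE,
                        sep = "\t")
  sessions <- list()
  for (e in manifest$files) {
    key <- as.character(e$subject)
    if (is.null(sessions[[key]]))
      sessions[[key]] <- list(subject = e$subject, classes = cfg$classes,
                              epochs = list(), config = cfg)
    tab <- read.table(file.path(dir, e$path), header = TRUE, sep = "\t")
    sig <- channel_signal(e$channel, e$fs, tab$value)
    sessions[[key]]$epochs[[e$class]][[e$epoch]]$channels[[e$channel]] <- sig
  }
  lapply(sessions, function(s) {
    m <- sam_all[sam_all$subject == s$subject, ]
    m <- m[match(s$classes, m$class), ]
    s$sam <- as.matrix(m[, c("arousal", "valence", "dominance")])
    rownames(s$sam) <- s$classes
    class(s) <- "session_recording"
    s
  })
}
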