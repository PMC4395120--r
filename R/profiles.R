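# Class effect profiles: how each of the eight stimulus classes modulates the
# autonomic channels and the SAM report distribution. SAM means/sds are the
# published per-class descriptive statistics for the study design this
# package emulates; the autonomic deltas are documented package defaults (no
# per-class autonomic parameters are published) chosen to produce moderate,
# plausible class separation -- roughly 50% four-class LOOCV accuracy at
# effect_size = 1, against a 25% chance level.

#' Canonical class labels
#'
#' Four archetype classes followed by four explicit-emotion classes.
#' @return character vector of length 8.
#' @export
study_classes <- function() {
  c("anima", "animus", "hero", "shadow",
    "active-pleasant", "active-unpleasant", "passive-pleasant",
    "passive-unpleasant")
}

#' Classes belonging to each four-class task
#' @param task `"archetypes"` or `"emotions"`.
#' @return character vector of 4 class labels.
#' @export
task_classes <- function(task = c("archetypes", "emotions")) {
  task <- match.arg(task)
  if (task == "archetypes") study_classes()[1:4] else study_classes()[5:8]
}

# SAM descriptive statistics (mean, sd) per class: arousal, valence, dominance
sam_table <- function() {
  list(
    "anima"              = list(means = c(5.320, 5.880, 5.560), sds = c(1.520, 1.590, 2.022)),
    "animus"             = list(means = c(6.400, 3.680, 4.360), sds = c(1.893, 1.520, 2.119)),
    "hero"               = list(means = c(5.720, 4.520, 6.040), sds = c(1.768, 2.104, 2.189)),
    "shadow"             = list(means = c(6.080, 5.000, 5.080), sds = c(2.080, 2.121, 2.290)),
    "active-pleasant"    = list(means = c(4.160, 7.400, 6.640), sds = c(2.511, 1.472, 1.753)),
    "active-unpleasant"  = list(means = c(6.600, 3.040, 3.160), sds = c(2.363, 1.719, 2.444)),
    "passive-pleasant"   = list(means = c(4.360, 8.320, 7.200), sds = c(2.691, 0.748, 1.658)),
    "passive-unpleasant" = list(means = c(4.120, 4.840, 4.640), sds = c(2.571, 2.075, 2.139))
  )
}

# neutral reference values the effect_size dial interpolates from
profile_reference <- function() {
  list(delta_hr = 0, hrv_scale = 1, scr_rate = 3, scl_slope = 0,
       resp_rate = 14, st_slope = 0)
}

# per-class autonomic deltas at effect_size = 1 (see vignette for rationale)
autonomic_table <- function() {
  list(
    "anima"              = list(delta_hr = 1.0, hrv_scale = 1.00, scr_rate = 4.0, scl_slope = 0.05, resp_rate = 14.0, st_slope = -0.010),
    "animus"             = list(delta_hr = 3.5, hrv_scale = 0.85, scr_rate = 7.0, scl_slope = 0.12, resp_rate = 15.5, st_slope = -0.025),
    "hero"               = list(delta_hr = 5.0, hrv_scale = 0.90, scr_rate = 5.5, scl_slope = 0.08, resp_rate = 14.8, st_slope =  0.008),
    "shadow"             = list(delta_hr = 2.5, hrv_scale = 0.75, scr_rate = 6.0, scl_slope = 0.10, resp_rate = 15.2, st_slope = -0.018),
    "active-pleasant"    = list(delta_hr = 3.0, hrv_scale = 1.04, scr_rate = 4.6, scl_slope = 0.055, resp_rate = 14.8, st_slope =  0.008),
    "active-unpleasant"  = list(delta_hr = 3.8, hrv_scale = 0.83, scr_rate = 5.8, scl_slope = 0.095, resp_rate = 15.1, st_slope = -0.016),
    "passive-pleasant"   = list(delta_hr = 1.4, hrv_scale = 1.08, scr_rate = 3.6, scl_slope = 0.035, resp_rate = 14.1, st_slope =  0.006),
    "passive-unpleasant" = list(delta_hr = 2.1, hrv_scale = 0.87, scr_rate = 4.3, scl_slope = 0.065, resp_rate = 14.4, st_slope = -0.006)
  )
}

#' Default class effect profiles
#'
#' One profile per class, combining autonomic modulation parameters with the
#' SAM rating distribution. `effect_size` linearly interpolates every
#' parameter between a neutral reference (shared by all classes, so
#' `effect_size = 0` yields a null cohort in which the classes are
#' statistically identical) and the full class-specific value at 1. SAM means
#' are interpolated towards the grand mean across the eight classes; SAM
#' standard deviations are untouched.
#'
#' @param effect_size scalar in `[0, 1]` scaling all class effects.
#' @return named list (one element per class) with fields `delta_hr`
#'   (beats/min offset from the subject's resting rate), `hrv_scale`
#'   (multiplier on RR variability), `scr_rate` (phasic events/min),
#'   `scl_slope` (microsiemens/min), `resp_rate` (breaths/min), `st_slope`
#'   (degrees Celsius/min), `sam_means`, `sam_sds` (length-3 each:
#'   arousal, valence, dominance).
#' @examples
#' p <- class_effect_profiles()
#' p$hero$delta_hr
#' @export
class_effect_profiles <- function(effect_size = 1) {
  if (!is.numeric(effect_size) || effect_size < 0 || effect_size > 1)
    stop_invalid_argument("`effect_size` must lie in [0, 1]")
  ref <- profile_reference()
  aut <- autonomic_table()
  sam <- sam_table()
  grand <- Reduce(`+`, lapply(sam, `[[`, "means")) / length(sam)
  out <- lapply(study_classes(), function(cl) {
    a <- aut[[cl]]; s <- sam[[cl]]
    list(
      delta_hr  = ref$delta_hr  + effect_size * (a$delta_hr  - ref$delta_hr),
      hrv_scale = ref$hrv_scale + effect_size * (a$hrv_scale - ref$hrv_scale),
      scr_rate  = ref$scr_rate  + effect_size * (a$scr_rate  - ref$scr_rate),
      scl_slope = ref$scl_slope + effect_size * (a$scl_slope - ref$scl_slope),
      resp_rate = ref$resp_rate + effect_size * (a$resp_rate - ref$resp_rate),
      st_slope  = ref$st_slope  + effect_size * (a$st_slope  - ref$st_slope),
      sam_means = grand + effect_size * (s$means - grand),
      sam_sds   = s$sds
    )
  })
  names(out) <- study_classes()
  out
}
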