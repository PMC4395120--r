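# Feature extraction: baseline-referenced min-max normalization and the
# canonical per-epoch feature vector. For a 300 s stimulus the vector has
# 158 entries in fixed order: 30 heart-rate segments, 8 HRV summaries
# (unnormalized), 30 SCL segments, 30 SCR (mean absolute phasic amplitude)
# segments, 30 respiration-rate segments, 30 temperature segments.
#
# Normalization scope: for each subject and signal family, the stimulus
# window values of all of that subject's epochs are baseline-subtracted
# (baseline = mean of the windowed series over that class's 40 s
# pre-stimulus epoch), and the min/max of the pooled baseline-subtracted
# values over the subject's epochs define the 0 and 1 of the scale.

hrv_feature_names <- function() {
  c("sdnn", "rmssd", "sdsd", "total_power", "vlf", "lf", "hf", "lf_hf")
}

#' Canonical feature names
#'
#' @param n_segments segments per signal family (30 for a 300 s stimulus).
#' @return character vector of `5 * n_segments + 8` names in canonical
#'   order (heart rate, HRV, SCL, SCR, respiration, temperature).
#' @export
feature_names <- function(n_segments = 30) {
  seg <- function(p) sprintf("%s_seg%02d", p, seq_len(n_segments))
  c(seg("hr"), hrv_feature_names(), seg("scl"), seg("scr"), seg("resp"),
    seg("temp"))
}

#' Average a series over equal-length segments
#'
#' Divides the epoch time axis into `floor(duration/segment)` equal segments
#' and returns the mean of the series within each; a trailing partial
#' segment is discarded.
#'
#' @param values samples (or window values) spanning the epoch uniformly.
#' @param duration epoch duration in seconds.
#' @param segment segment length in seconds (default 10).
#' @return numeric vector of segment means.
#' @examples
#' segment_average(rep(3, 300), duration = 300)  # thirty 3s
#' @export
segment_average <- function(values, duration, segment = 10) {
  if (!length(values)) stop_invalid_argument("empty series")
  if (duration < segment) stop_invalid_argument("duration shorter than one segment")
  nseg <- floor(duration / segment)
  mid <- (seq_along(values) - 0.5) * duration / length(values)
  idx <- floor(mid / segment) + 1
  keep <- idx <= nseg
  as.numeric(tapply(values[keep], factor(idx[keep], levels = seq_len(nseg)),
                    mean))
}

#' Baseline-subtract and min-max scale a windowed series
#'
#' Computes `((x - baseline) - scope_min) / (scope_max - scope_min)`, where
#' `scope_min`/`scope_max` are the extrema of the baseline-subtracted values
#' over the normalization scope (by default the series itself). A degenerate
#' scope (`scope_max == scope_min`) yields all zeros with a classed warning.
#'
#' @param values stimulus-epoch window values.
#' @param baseline scalar baseline value to subtract.
#' @param scope_min,scope_max extrema of baseline-subtracted values over the
#'   normalization scope; defaults to the range of `values - baseline`.
#' @return numeric vector in `[0, 1]`.
#' @examples
#' baseline_correct_and_scale(c(0, 2, 4), baseline = 0)
#' @export
baseline_correct_and_scale <- function(values, baseline,
                                       scope_min = NULL, scope_max = NULL) {
  d <- values - baseline
  if (is.null(scope_min)) scope_min <- min(d)
  if (is.null(scope_max)) scope_max <- max(d)
  if (scope_max < scope_min)
    stop_invalid_argument("`scope_max` must be >= `scope_min`")
  if (scope_max == scope_min) {
    warn_classed("degenerate normalization scale: outputs set to 0",
                 "archepsy_degenerate_scale")
    return(rep(0, length(values)))
  }
  (d - scope_min) / (scope_max - scope_min)
}

# process one epoch's four channels into windowed series (+ HRV for stimulus)
process_epoch <- function(channels, with_hrv = TRUE, window = 10) {
  need <- c("ecg", "skin_conductance", "respiration", "skin_temperature")
  miss <- setdiff(need, names(channels))
  if (length(miss))
    stop_missing_channel(paste("missing channel:", paste(miss, collapse = ", ")))
  ecg <- bandlimit_ecg(channels$ecg)
  beats <- detect_beats(ecg)
  dur <- signal_duration(channels$ecg)
  sc <- channels$skin_conductance
  out <- list(
    hr = heart_rate_windows(beats, dur, window),
    scl = signal_windows(scl_component(sc), window = window, units = "uS"),
    scr = signal_windows(scr_component(sc), window = window, absolute = TRUE,
                         units = "uS"),
    resp = respiration_rate_windows(channels$respiration, window = window),
    temp = temperature_windows(channels$skin_temperature, window = window),
    beats = beats
  )
  if (with_hrv) out$hrv <- hrv_summary(beats)
  out
}

# pad (hold last, flagged) or truncate a segment vector to n_segments
fit_segments <- function(vals, n_segments) {
  flag <- FALSE
  if (length(vals) < n_segments) {
    vals <- c(vals, rep(vals[length(vals)], n_segments - length(vals)))
    flag <- TRUE
  } else if (length(vals) > n_segments) {
    vals <- vals[seq_len(n_segments)]
  }
  list(values = vals, padded = flag)
}

#' Assemble the canonical feature vector for one stimulus epoch
#'
#' @param stim processed stimulus epoch: a list with windowed series `hr`,
#'   `scl`, `scr`, `resp`, `temp` and the 8-element `hrv` summary (as
#'   produced by the internal epoch processor).
#' @param baselines named list of scalar baseline values for `hr`, `scl`,
#'   `scr`, `resp`, `temp`.
#' @param scopes named list of `c(min, max)` normalization extrema per
#'   signal family (baseline-subtracted scale); `NULL` to use each series'
#'   own range.
#' @param n_segments number of segments per family (default 30).
#' @return named numeric vector of length `5 * n_segments + 8`; attribute
#'   `padded` names families that were right-padded.
#' @export
assemble_features <- function(stim, baselines, scopes = NULL,
                              n_segments = 30) {
  fams <- c("hr", "scl", "scr", "resp", "temp")
  miss <- setdiff(c(fams, "hrv"), names(stim))
  if (length(miss))
    stop_missing_channel(paste("missing series:", paste(miss, collapse = ", ")))
  padded <- character(0)
  blocks <- lapply(fams, function(f) {
    fit <- fit_segments(as.numeric(stim[[f]]), n_segments)
    if (fit$padded) padded <<- c(padded, f)
    sc <- scopes[[f]]
    baseline_correct_and_scale(fit$values, baselines[[f]],
                               scope_min = sc[1], scope_max = sc[2])
  })
  names(blocks) <- fams
  out <- c(blocks$hr, stim$hrv, blocks$scl, blocks$scr, blocks$resp,
           blocks$temp)
  names(out) <- feature_names(n_segments)
  attr(out, "padded") <- padded
  out
}

#' Extract feature vectors for every epoch of one session
#'
#' Runs signal processing on all baseline/stimulus epoch pairs, computes the
#' per-class baselines, establishes the subject-level normalization scope
#' per signal family, and assembles one canonical feature vector per class.
#'
#' @param session a `session_recording`.
#' @param n_segments segments per family (default
#'   `stimulus_duration / 10`).
#' @return data.frame: columns `subject`, `class`, then the features.
#' @export
extract_session_features <- function(session, n_segments = NULL) {
  cfg <- session$config
  if (is.null(n_segments)) n_segments <- floor(cfg$stimulus_duration / 10)
  fams <- c("hr", "scl", "scr", "resp", "temp")
  per_class <- lapply(session$classes, function(cl) {
    ep <- session$epochs[[cl]]
    stim <- process_epoch(ep$stimulus$channels, with_hrv = TRUE)
    base <- process_epoch(ep$baseline$channels, with_hrv = FALSE)
    baselines <- lapply(fams, function(f) mean(as.numeric(base[[f]])))
    names(baselines) <- fams
    list(stim = stim, baselines = baselines)
  })
  names(per_class) <- session$classes
  # subject-level normalization scope per family over baseline-subtracted
  # stimulus windows of all classes
  scopes <- lapply(fams, function(f) {
    pooled <- unlist(lapply(per_class, function(pc)
      as.numeric(pc$stim[[f]]) - pc$baselines[[f]]))
    range(pooled)
  })
  names(scopes) <- fams
  rows <- lapply(session$classes, function(cl) {
    fv <- assemble_features(per_class[[cl]]$stim, per_class[[cl]]$baselines,
                            scopes, n_segments)
    cbind(data.frame(subject = session$subject, class = cl),
          as.data.frame(as.list(fv), check.names = FALSE))
  })
  do.call(rbind, rows)
}

#' Cohort feature matrix
#'
#' @param sessions list of `session_recording`s (e.g. from
#'   [generate_cohort()]).
#' @return data.frame of `n_subjects * n_classes` rows: `subject`, `class`,
#'   then the canonical features.
#' @export
cohort_feature_matrix <- function(sessions) {
  do.call(rbind, lapply(sessions, extract_session_features))
}

#' Write / read a cohort feature matrix
#'
#' Plain tab-separated round trip with a header row of the canonical
#' feature names plus `subject` and `class`.
#'
#' @param features data.frame from [cohort_feature_matrix()].
#' @param path file path.
#' @return `write_feature_matrix`: the path, invisibly;
#'   `read_feature_matrix`: the data.frame.
#' @export
write_feature_matrix <- function(features, path) {
  write.table(features, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}
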