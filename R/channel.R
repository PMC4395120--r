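#' Construct a single-channel physiological signal
#'
#' A `channel_signal` is the atomic container used throughout the package:
#' a regularly sampled numeric trace with a channel name, sampling rate and
#' session-clock start time.
#'
#' @param channel one of `"ecg"`, `"skin_conductance"`, `"respiration"`,
#'   `"skin_temperature"`.
#' @param fs sampling rate in Hz (> 0).
#' @param values numeric vector of samples, no missing values.
#' @param start_time epoch start in seconds on the session clock.
#' @return an object of class `channel_signal` with fields `channel`, `fs`,
#'   `values`, `start_time`.
#' @examples
#' sig <- channel_signal("respiration", 32, sin(2 * pi * 0.25 * seq(0, 60, by = 1/32)))
#' sig
#' @export
channel_signal <- function(channel = c("ecg", "skin_conductance", "respiration",
                                       "skin_temperature"),
                           fs, values, start_time = 0) {
  channel <- match.arg(channel)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_invalid_argument("`fs` must be a single positive number")
  if (!is.numeric(values) || anyNA(values))
    stop_invalid_argument("`values` must be numeric with no missing samples")
  structure(
    list(channel = channel, fs = fs, values = as.numeric(values),
         start_time = start_time),
    class = "channel_signal"
  )
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("<channel_signal> %s: %d samples @ %g Hz (%.1f s), start %.1f s\n",
              x$channel, length(x$values), x$fs,
              length(x$values) / x$fs, x$start_time))
  invisible(x)
}

#' @export
length.channel_signal <- function(x) length(x$values)

# duration in seconds
signal_duration <- function(x) length(x$values) / x$fs

# sample times relative to epoch start
signal_times <- function(x) (seq_along(x$values) - 1) / x$fs

as_channel_like <- function(x, fs = NULL) {
  if (inherits(x, "channel_signal")) return(x)
  if (is.null(fs)) stop_invalid_argument("`fs` required for a bare numeric signal")
  channel_signal("ecg", fs, x)
}
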