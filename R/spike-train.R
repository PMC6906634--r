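#' Spike train objects
#'
#' A spike train is an ordered vector of event times (seconds) for one unit and
#' spike type, recorded or simulated over a known duration. Times must be
#' non-negative, strictly increasing and no later than the duration.
#'
#' @param times numeric vector of event times in seconds.
#' @param duration_s length of the analysed recording window in seconds. The
#'   duration is the analysis window, not last spike minus first spike.
#' @return an object of class `spike_train`: the sorted times with a
#'   `duration_s` attribute.
#' @examples
#' st <- spike_train(c(0.01, 0.03, 0.07), duration_s = 0.1)
#' length(st)
#' @export
spike_train <- function(times, duration_s) {
  times <- as.numeric(times)
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop_invalid("duration_s must be a single positive number")
  if (any(times < 0)) stop_invalid("spike times must be non-negative")
  times <- sort(times)
  if (anyDuplicated(times)) stop_invalid("spike times must be strictly increasing")
  if (length(times) && times[length(times)] > duration_s)
    stop_invalid("spike times must lie within [0, duration_s]")
  structure(as.numeric(times), duration_s = as.numeric(duration_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d events over %.3f s (%.2f Hz)\n",
              length(x), duration(x),
              if (duration(x) > 0) length(x) / duration(x) else NA_real_))
  invisible(x)
}

#' Recording duration of a spike train
#' @param x a `spike_train`.
#' @return duration in seconds.
#' @export
duration <- function(x) attr(x, "duration_s")

#' Interspike intervals
#' @param x a `spike_train` (or bare numeric vector of sorted times).
#' @return numeric vector of intervals between consecutive events, seconds.
#' @export
isis <- function(x) diff(as.numeric(x))

#' Rescale the time base of a spike train
#'
#' Multiplies all event times and the duration by a positive factor. Rate is
#' divided by the factor; CV and CV2 are invariant.
#'
#' @param x a `spike_train`.
#' @param factor positive scale factor.
#' @return rescaled `spike_train`.
#' @export
rescale_train <- function(x, factor) {
  if (factor <= 0) stop_invalid("factor must be positive")
  spike_train(as.numeric(x) * factor, duration(x) * factor)
}
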