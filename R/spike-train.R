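#' Construct a spike train
#'
#' A spike train is a strictly increasing vector of action-potential times
#' (seconds from recording start) plus recording metadata. All downstream
#' rate statistics operate on this container, whether the train came from the
#' synthetic generator or from [detect_spikes()].
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing, all in `[0, duration)`.
#' @param duration Recording duration in seconds.
#' @param metadata Named list (sensillum_type, odorant_id, dose, replicate_id,
#'   stimulus_onset, stimulus_duration ... anything the caller wants carried).
#' @return An object of class `spike_train`.
#' @export
#' @examples
#' spike_train(c(0.1, 0.25, 1.2), duration = 3)
spike_train <- function(times, duration, metadata = list()) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop_invalid("`duration` must be a single positive number")
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times))) stop_invalid("spike times must be finite")
    if (any(diff(times) <= 0))
      stop_invalid("spike times must be strictly increasing")
    if (times[1] < 0 || times[length(times)] >= duration)
      stop_invalid("spike times must lie in [0, duration)")
  }
  structure(list(times = times, duration = duration,
                 metadata = as.list(metadata)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %.3g s", length(x$times),
              x$duration))
  md <- x$metadata
  if (!is.null(md$odorant_id) || !is.null(md$sensillum_type))
    cat(sprintf("  [%s / %s]",
                md$sensillum_type %||% "?", md$odorant_id %||% "?"))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a voltage trace
#'
#' Single-channel extracellular recording: a vector of amplitudes in
#' microvolts at a fixed sampling rate, with the stimulus timing attached.
#' Recordings follow the standard SSR protocol: sampled at 96 kHz for 10 s
#' with a 500 ms odor pulse, though all three are free parameters here.
#'
#' @param samples Numeric vector of amplitudes (µV).
#' @param sampling_rate Samples per second (Hz), > 0.
#' @param stimulus_onset Stimulus onset in seconds from trace start.
#' @param stimulus_duration Stimulus duration in seconds (default 0.5).
#' @param metadata Named list carried through to detected spike trains.
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, sampling_rate, stimulus_onset = 0,
                          stimulus_duration = 0.5, metadata = list()) {
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  samples <- as.numeric(samples)
  if (!length(samples)) stop_invalid("`samples` must be non-empty")
  dur <- length(samples) / sampling_rate
  check_number(stimulus_onset, "stimulus_onset", lower = 0)
  if (stimulus_onset >= dur)
    stop_invalid("`stimulus_onset` must fall inside the recording")
  check_number(stimulus_duration, "stimulus_duration", lower = 0,
               strict_lower = TRUE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stimulus_onset = stimulus_onset,
                 stimulus_duration = stimulus_duration,
                 duration = dur, metadata = as.list(metadata)),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples @ %g Hz (%.3g s), onset %.3g s\n",
              length(x$samples), x$sampling_rate, x$duration,
              x$stimulus_onset))
  invisible(x)
}
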