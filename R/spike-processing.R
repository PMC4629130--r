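#' Detect spikes in an extracellular voltage trace
#'
#' Adaptive thresholding on a robust noise estimate: the threshold is
#' `threshold_k` times the median absolute deviation of the trace scaled to
#' a Gaussian SD (`mad(x)`), applied to the rectified signal according to
#' `polarity`. A spike is recorded at each local extremum of a
#' supra-threshold excursion; events within `refractory` of the previous
#' accepted spike are suppressed. All supra-threshold events are pooled
#' (no sorting into units), matching the whole-sensillum convention for
#' multi-neuron sensilla.
#'
#' @param trace A [voltage_trace()].
#' @param threshold_k Threshold in robust-SD units (default 5).
#' @param refractory Suppression window after each spike, s (default 0.002).
#' @param polarity `"both"` (default, rectifies with `abs`), `"negative"`,
#'   or `"positive"`.
#' @param absolute_threshold Optional absolute threshold in µV; overrides the
#'   MAD-based threshold. Required for traces with zero noise scale.
#' @return A [spike_train()] with the trace's metadata.
#' @export
#' @examples
#' pr <- response_profile("Da", "x", baseline_rate = 20,
#'                        max_evoked_rate = 0, kernel = "tonic")
#' tr <- gen_spike_train(pr, -2, duration = 3, stimulus_onset = 0.6, seed = 1)
#' tpl <- spike_template(20000)
#' v <- gen_voltage_trace(tr, tpl, 20000, noise_sd = 6, seed = 2)
#' detect_spikes(v, threshold_k = 5)
detect_spikes <- function(trace, threshold_k = 5, refractory = 0.002,
                          polarity = c("both", "negative", "positive"),
                          absolute_threshold = NULL) {
  stopifnot(inherits(trace, "voltage_trace"))
  polarity <- match.arg(polarity)
  x <- trace$samples
  s <- switch(polarity, both = abs(x), negative = -x, positive = x)
  if (is.null(absolute_threshold)) {
    check_number(threshold_k, "threshold_k", lower = 0, strict_lower = TRUE)
    scale <- stats::mad(x)
    if (scale == 0)
      stop(errorCondition(
        paste0("trace noise scale is zero; the relative threshold is ",
               "degenerate - supply `absolute_threshold` instead"),
        class = c("ssr_degenerate_threshold", "error")))
    thr <- threshold_k * scale
  } else {
    thr <- check_number(absolute_threshold, "absolute_threshold",
                        lower = 0, strict_lower = TRUE)
  }
  times <- numeric(0)
  if (any(s > thr)) {
    # supra-threshold local maxima (left-closed so plateaus count once);
    # overlapping waveforms thus still yield one event per extremum
    n <- length(s)
    left <- c(-Inf, s[-n])
    right <- c(s[-1], -Inf)
    peaks <- which(s > thr & s >= left & s > right)
    times <- (peaks - 1L) / trace$sampling_rate
    if (length(times) > 1) {
      acc <- logical(length(times))
      last <- -Inf
      for (i in seq_along(times)) {
        if (times[i] - last >= refractory) {
          acc[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[acc]
    }
  }
  spike_train(times, trace$duration, metadata = c(
    trace$metadata,
    list(stimulus_onset = trace$stimulus_onset,
         stimulus_duration = trace$stimulus_duration)))
}

#' Count spikes in a half-open time window
#'
#' Counts spikes with `start <= t < start + width`. The half-open convention
#' partitions time with no double counting: a spike exactly at
#' `start + width` is excluded.
#'
#' @param train A [spike_train()].
#' @param start Window start, s.
#' @param width Window width, s.
#' @return Integer spike count.
#' @export
count_window <- function(train, start, width) {
  stopifnot(inherits(train, "spike_train"))
  check_number(start, "start")
  check_number(width, "width", lower = 0, strict_lower = TRUE)
  if (start < 0 || start + width > train$duration + 1e-9)
    stop(errorCondition(
      sprintf("window [%g, %g) lies outside the recording [0, %g]",
              start, start + width, train$duration),
      class = c("ssr_out_of_range", "error")))
  # half-open with a small tolerance so boundary spikes are classified
  # consistently despite floating-point window arithmetic
  eps <- 1e-12
  sum(train$times >= start - eps & train$times < start + width - eps)
}

#' Baseline-subtracted firing rate in spikes/s
#'
#' The standard SSR statistic: spikes in the 500 ms window starting at
#' stimulus onset, minus spikes in the 500 ms window immediately before
#' onset, doubled to convert the half-second difference to spikes/s.
#' Negative values indicate inhibitory responses and are retained.
#'
#' @param train A [spike_train()].
#' @param onset Stimulus onset, s; must be >= 0.5 so a full pre-stimulus
#'   window exists. Defaults to the train's `stimulus_onset` metadata.
#' @param window Counting window width, s (default 0.5).
#' @return Rate in spikes/s (may be negative).
#' @export
#' @examples
#' tr <- spike_train(c(seq(0.05, 0.45, length.out = 5),
#'                     seq(0.52, 0.98, length.out = 25)), duration = 2)
#' firing_rate(tr, onset = 0.5)  # (25 - 5) * 2 = 40
firing_rate <- function(train, onset = NULL, window = 0.5) {
  stopifnot(inherits(train, "spike_train"))
  onset <- onset %||% train$metadata$stimulus_onset
  if (is.null(onset)) stop_invalid("`onset` is required")
  if (onset < window)
    stop(errorCondition(
      sprintf("onset %g s leaves no full %g s pre-stimulus baseline", onset,
              window),
      class = c("ssr_insufficient_baseline", "error")))
  post <- count_window(train, onset, window)
  pre <- count_window(train, onset - window, window)
  (post - pre) / window
}

#' Peristimulus time histogram
#'
#' Bins spikes in fixed-width bins over a window anchored at stimulus
#' onset: 100 ms bins over 2 s by default, i.e. 20 bins. Bins are half-open,
#' so the per-bin counts always sum to [count_window()] over the same
#' window.
#'
#' @param train A [spike_train()].
#' @param onset Window anchor, s; defaults to the train's metadata onset.
#' @param window Total window, s (default 2).
#' @param bin_width Bin width, s (default 0.1); must divide `window`.
#' @return Object of class `psth` with `counts`, `rates` (counts /
#'   bin_width), `bin_width`, `window`, `onset`.
#' @export
compute_psth <- function(train, onset = NULL, window = 2, bin_width = 0.1) {
  stopifnot(inherits(train, "spike_train"))
  onset <- onset %||% train$metadata$stimulus_onset
  if (is.null(onset)) stop_invalid("`onset` is required")
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  check_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  nb <- window / bin_width
  if (abs(nb - round(nb)) > 1e-8)
    stop(errorCondition(
      sprintf("window %g s is not an integer multiple of bin width %g s",
              window, bin_width),
      class = c("ssr_invalid_binning", "error")))
  nb <- as.integer(round(nb))
  if (onset + window > train$duration + 1e-9)
    stop(errorCondition("PSTH window extends past the recording end",
                        class = c("ssr_out_of_range", "error")))
  eps <- 1e-12
  t <- train$times
  t <- t[t >= onset - eps & t < onset + window - eps]
  idx <- pmin(nb, pmax(1L, floor((t - onset) / bin_width + 1e-9) + 1L))
  counts <- tabulate(idx, nbins = nb)
  structure(list(counts = counts, rates = counts / bin_width,
                 bin_width = bin_width, window = window, onset = onset,
                 metadata = train$metadata),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %g s from onset %g s; %d spikes\n",
              length(x$counts), x$bin_width, x$onset, sum(x$counts)))
  invisible(x)
}

#' @rdname compute_psth
#' @param x A `psth` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psth <- function(x, ...) {
  mids <- x$onset + (seq_along(x$counts) - 0.5) * x$bin_width
  graphics::plot(mids, x$rates, type = "s", xlab = "time (s)",
                 ylab = "rate (spikes/s)", ...)
  invisible(x)
}
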