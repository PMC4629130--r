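#' Define a generative response profile for one odorant-sensillum pair
#'
#' The generator models an olfactory receptor neuron (pooled per sensillum)
#' as an inhomogeneous Poisson process with a hard refractory dead time.
#' Before stimulus onset the rate is `baseline_rate`; from onset onward it is
#' `baseline_rate + A(dose) * k(t - onset)` where the amplitude follows a
#' Hill function of dose,
#' `A(d) = max_evoked_rate / (1 + (10^ec50_dose / 10^d)^hill_coefficient)`,
#' and the kernel `k` is either tonic (sustained at 1 for the rest of the
#' recording, emulating responses whose firing stays high through the 2 s
#' analysis window) or phasic (`exp(-t / phasic_decay_constant)`, a burst at
#' onset that adapts away).
#'
#' @param sensillum_type One of [sensillum_types()] codes.
#' @param odorant_id Odorant identifier string.
#' @param baseline_rate Spontaneous rate, spikes/s, >= 0.
#' @param max_evoked_rate Asymptotic evoked rate increment at saturating
#'   dose, spikes/s, >= 0.
#' @param kernel `"tonic"` or `"phasic"`.
#' @param phasic_decay_constant Decay time constant in seconds (> 0);
#'   required iff `kernel = "phasic"`.
#' @param ec50_dose Dose of half-maximal response on the log10 scale
#'   (log10 v/v dilution for SSR work, e.g. -3 for 1:1000; log10 molar for
#'   the oocyte branch).
#' @param hill_coefficient Hill slope, > 0.
#' @return An object of class `response_profile`.
#' @export
#' @examples
#' response_profile("Da", "nonanal", baseline_rate = 10,
#'                  max_evoked_rate = 250, kernel = "tonic", ec50_dose = -4)
response_profile <- function(sensillum_type, odorant_id,
                             baseline_rate = 10, max_evoked_rate = 0,
                             kernel = c("tonic", "phasic"),
                             phasic_decay_constant = NULL,
                             ec50_dose = -3.5, hill_coefficient = 1) {
  kernel <- match.arg(kernel)
  if (!sensillum_type %in% names(sensillum_types()))
    stop_invalid("unknown sensillum type: ", sensillum_type)
  check_number(baseline_rate, "baseline_rate", lower = 0)
  check_number(max_evoked_rate, "max_evoked_rate", lower = 0)
  check_number(ec50_dose, "ec50_dose")
  check_number(hill_coefficient, "hill_coefficient", lower = 0,
               strict_lower = TRUE)
  if (kernel == "phasic") {
    if (is.null(phasic_decay_constant))
      stop_invalid("`phasic_decay_constant` is required for a phasic kernel")
    check_number(phasic_decay_constant, "phasic_decay_constant", lower = 0,
                 strict_lower = TRUE)
  } else if (!is.null(phasic_decay_constant)) {
    stop_invalid("`phasic_decay_constant` only applies to a phasic kernel")
  }
  structure(list(sensillum_type = sensillum_type, odorant_id = odorant_id,
                 baseline_rate = baseline_rate,
                 max_evoked_rate = max_evoked_rate, kernel = kernel,
                 phasic_decay_constant = phasic_decay_constant,
                 ec50_dose = ec50_dose, hill_coefficient = hill_coefficient),
            class = "response_profile")
}

#' Hill amplitude of a response profile at a given dose
#'
#' @param profile A [response_profile()].
#' @param dose Dose on the log10 scale matching `profile$ec50_dose`.
#' @return Evoked rate increment in spikes/s.
#' @export
evoked_amplitude <- function(profile, dose) {
  if (profile$max_evoked_rate == 0) return(0)
  if (identical(dose, -Inf)) return(0)
  profile$max_evoked_rate /
    (1 + 10^((profile$ec50_dose - dose) * profile$hill_coefficient))
}

# Target instantaneous firing rate r(t) for a profile at a dose (spikes/s).
profile_rate_fun <- function(profile, dose, stimulus_onset) {
  a <- evoked_amplitude(profile, dose)
  b <- profile$baseline_rate
  if (profile$kernel == "tonic") {
    function(t) ifelse(t < stimulus_onset, b, b + a)
  } else {
    tau <- profile$phasic_decay_constant
    function(t) ifelse(t < stimulus_onset, b,
                       b + a * exp(-(t - stimulus_onset) / tau))
  }
}

#' Simulate a spike train from a response profile
#'
#' Samples an inhomogeneous Poisson process by thinning, with a hard
#' refractory dead time after every accepted spike. The thinning hazard is
#' dead-time compensated (`lambda(t) = r(t) / (1 - r(t) * refractory)`) so
#' that the *realized* firing rate matches the profile's target rate
#' function `r(t)`; this caps attainable rates at `1 / refractory`
#' (500 spikes/s at the default 2 ms).
#'
#' @param profile A [response_profile()].
#' @param dose Stimulus dose, log10 scale (see [response_profile()]).
#' @param duration Recording duration, s; must exceed
#'   `stimulus_onset + 2` so a full 2 s post-onset analysis window exists.
#' @param stimulus_onset Stimulus onset, s.
#' @param stimulus_duration Stimulus duration, s (default 0.5).
#' @param refractory Hard refractory period, s (default 0.002).
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return A [spike_train()] with dose/stimulus metadata attached.
#' @export
#' @examples
#' pr <- response_profile("Dg", "hexanal", baseline_rate = 8,
#'                        max_evoked_rate = 150, kernel = "tonic",
#'                        ec50_dose = -4)
#' gen_spike_train(pr, dose = -2, duration = 3.5, stimulus_onset = 1,
#'                 seed = 1)
gen_spike_train <- function(profile, dose, duration, stimulus_onset,
                            stimulus_duration = 0.5, refractory = 0.002,
                            seed = NULL) {
  stopifnot(inherits(profile, "response_profile"))
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(stimulus_onset, "stimulus_onset", lower = 0)
  check_number(stimulus_duration, "stimulus_duration", lower = 0,
               strict_lower = TRUE)
  check_number(refractory, "refractory", lower = 0, strict_lower = TRUE)
  if (duration <= stimulus_onset + 2)
    stop_invalid("`duration` must exceed `stimulus_onset` + 2 s ",
                 "(a full post-onset analysis window is required)")
  rate_fun <- profile_rate_fun(profile, dose, stimulus_onset)
  peak <- profile$baseline_rate +
    max(evoked_amplitude(profile, dose), 0)
  if (peak * refractory >= 1)
    stop_invalid("target rate ", round(peak, 1), " spikes/s exceeds the ",
                 "refractory-limited maximum of ", round(1 / refractory, 1))
  hazard_max <- peak / (1 - peak * refractory)
  times <- with_seed(seed, {
    if (hazard_max <= 0) numeric(0) else {
      n_cand <- stats::rpois(1, hazard_max * duration)
      cand <- sort(stats::runif(n_cand, 0, duration))
      r <- rate_fun(cand)
      keep <- stats::runif(n_cand) < (r / (1 - r * refractory)) / hazard_max
      cand <- cand[keep]
      # dead-time pass: drop events inside the refractory window of the
      # previous accepted event
      if (length(cand) > 1) {
        acc <- logical(length(cand))
        last <- -Inf
        for (i in seq_along(cand)) {
          if (cand[i] - last >= refractory) {
            acc[i] <- TRUE
            last <- cand[i]
          }
        }
        cand <- cand[acc]
      }
      cand
    }
  })
  spike_train(times, duration,
              metadata = list(sensillum_type = profile$sensillum_type,
                              odorant_id = profile$odorant_id,
                              dose = dose,
                              stimulus_onset = stimulus_onset,
                              stimulus_duration = stimulus_duration,
                              kernel = profile$kernel))
}

#' Parametric extracellular spike waveform template
#'
#' A biphasic wavelet used to render synthetic voltage traces: a dominant
#' lobe of the requested polarity followed by a smaller rebound lobe of the
#' opposite sign, total support `width_ms`.
#'
#' @param sampling_rate Hz at which the waveform is realized.
#' @param width_ms Total template width in milliseconds (default 1.5; keep
#'   below the refractory period).
#' @param amplitude Peak absolute amplitude, µV (default 100).
#' @param polarity `"negative"` (typical extracellular) or `"positive"`.
#' @return Object of class `spike_template` with the realized `waveform`.
#' @export
spike_template <- function(sampling_rate, width_ms = 1.5, amplitude = 100,
                           polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE)
  check_number(width_ms, "width_ms", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  n <- max(3L, round(sampling_rate * width_ms / 1000))
  t <- seq(0, 1, length.out = n)
  # main lobe at t ~ 0.3, opposite rebound at t ~ 0.7
  w <- exp(-((t - 0.3) / 0.12)^2) - 0.35 * exp(-((t - 0.7) / 0.2)^2)
  w <- w / max(abs(w)) * amplitude
  if (polarity == "negative") w <- -w
  structure(list(waveform = w, width = width_ms, polarity = polarity,
                 sampling_rate = sampling_rate),
            class = "spike_template")
}

#' Render a spike train as a synthetic voltage trace
#'
#' Places one template occurrence at the sample index nearest each spike
#' time (summed additively when spikes overlap) and adds white Gaussian
#' noise.
#'
#' @param train A [spike_train()].
#' @param template A [spike_template()] realized at `sampling_rate`.
#' @param sampling_rate Hz.
#' @param noise_sd Noise standard deviation, µV, >= 0.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A [voltage_trace()] carrying the train's metadata.
#' @export
gen_voltage_trace <- function(train, template, sampling_rate, noise_sd = 5,
                              seed = NULL) {
  stopifnot(inherits(train, "spike_train"),
            inherits(template, "spike_template"))
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!isTRUE(all.equal(template$sampling_rate, sampling_rate)))
    stop_invalid("template was realized at ", template$sampling_rate,
                 " Hz, not ", sampling_rate, " Hz")
  n <- round(train$duration * sampling_rate)
  x <- numeric(n)
  w <- template$waveform
  half <- (length(w) - 1L) %/% 2L
  if (length(train$times)) {
    if (any(diff(train$times) < template$width / 1000))
      warning("spikes closer than the template width; waveforms overlap ",
              "and are rendered additively")
    centers <- round(train$times * sampling_rate) + 1L
    for (cc in centers) {
      i0 <- cc - half
      idx <- seq(i0, i0 + length(w) - 1L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + w[ok]
    }
  }
  if (noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  voltage_trace(x, sampling_rate,
                stimulus_onset = train$metadata$stimulus_onset %||% 0,
                stimulus_duration = train$metadata$stimulus_duration %||% 0.5,
                metadata = train$metadata)
}
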