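#' Simulate two-electrode voltage-clamp current traces
#'
#' Generates one oocyte current trace per dose for a receptor with the
#' given Hill pharmacology: a flat baseline, an inward (negative) current
#' deflection whose peak amplitude follows
#' `A(d) = emax / (1 + (ec50/d)^hill)`, exponential desensitization during
#' the application window, and a washout return to baseline. Odorant
#' applications follow the standard protocol (10 s application with
#' washes in between).
#'
#' @param ec50 Half-maximal dose, molar, > 0.
#' @param hill Hill coefficient, > 0.
#' @param emax Saturating peak amplitude, nA, > 0.
#' @param doses Vector of molar doses, positive and strictly ascending.
#' @param desensitization_tau Desensitization time constant, s (default 4).
#' @param noise_sd Additive white-noise SD, nA (default 0).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param sampling_rate Hz (default 200).
#' @param app_start,app_duration Application window, s (defaults 5 and 10).
#' @param rise_time Ramp from baseline to peak, s (default 0.2).
#' @param washout_tau Washout time constant, s (default 1).
#' @param total_duration Trace length, s (default 25).
#' @return List of `current_trace` objects (fields `time`, `current`,
#'   `window`, `dose`), one per dose.
#' @export
#' @examples
#' tr <- gen_current_trace(1e-6, 1, 1000, doses = c(1e-7, 1e-6, 1e-5))
#' sapply(tr, extract_amplitude)
gen_current_trace <- function(ec50, hill, emax, doses,
                              desensitization_tau = 4, noise_sd = 0,
                              seed = NULL, sampling_rate = 200,
                              app_start = 5, app_duration = 10,
                              rise_time = 0.2, washout_tau = 1,
                              total_duration = 25) {
  check_number(ec50, "ec50", lower = 0, strict_lower = TRUE)
  check_number(hill, "hill", lower = 0, strict_lower = TRUE)
  check_number(emax, "emax", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(desensitization_tau, "desensitization_tau", lower = 0,
               strict_lower = TRUE)
  if (!is.numeric(doses) || !length(doses) || any(doses <= 0))
    stop_invalid("`doses` must be positive")
  if (is.unsorted(doses, strictly = TRUE))
    stop_invalid("`doses` must be strictly ascending")
  tm <- seq(0, total_duration, by = 1 / sampling_rate)
  t_peak <- app_start + rise_time
  t_end <- app_start + app_duration
  with_seed(seed, lapply(doses, function(d) {
    a <- emax / (1 + (ec50 / d)^hill)
    y <- numeric(length(tm))
    ramp <- tm >= app_start & tm <= t_peak
    y[ramp] <- -a * (tm[ramp] - app_start) / rise_time
    desens <- tm > t_peak & tm <= t_end
    y[desens] <- -a * exp(-(tm[desens] - t_peak) / desensitization_tau)
    wash <- tm > t_end
    y_end <- -a * exp(-(t_end - t_peak) / desensitization_tau)
    y[wash] <- y_end * exp(-(tm[wash] - t_end) / washout_tau)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    structure(list(time = tm, current = y, window = c(app_start, t_end),
                   dose = d, units = "M"),
              class = "current_trace")
  }))
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %.3g s @ dose %.3g %s; application [%g, %g] s\n",
    max(x$time), x$dose, x$units, x$window[1], x$window[2]))
  invisible(x)
}

#' Peak response amplitude of a voltage-clamp current trace
#'
#' Absolute deviation of the most extreme current within the application
#' window from the pre-application baseline (median of the current before
#' the window opens). On noisy recordings the raw extremum is upward
#' biased by the noise tails, so when the baseline shows measurable noise
#' the trace is first smoothed with a short running mean (`smooth`
#' seconds, well below the rise and desensitization time scales); clean
#' traces are left untouched, keeping the noiseless round trip exact.
#'
#' @param trace A `current_trace` with a marked application `window`.
#' @param smooth Running-mean width in seconds applied when baseline noise
#'   is detected (default 0.045); set to 0 to force the raw extremum.
#' @return Amplitude in nA (>= 0).
#' @export
extract_amplitude <- function(trace, smooth = 0.045) {
  if (!inherits(trace, "current_trace") || is.null(trace$window))
    stop_schema("`trace` must be a current_trace with an application window")
  pre <- trace$current[trace$time < trace$window[1]]
  if (!length(pre)) stop_schema("no pre-application baseline samples")
  base <- stats::median(pre)
  x <- trace$current[trace$time >= trace$window[1] &
                       trace$time <= trace$window[2]] - base
  noisy <- stats::mad(pre) > 0
  if (noisy && smooth > 0) {
    dt <- stats::median(diff(trace$time))
    k <- max(1L, round(smooth / dt))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) x <- stats::filter(x, rep(1 / k, k), sides = 2)
  }
  max(abs(x), na.rm = TRUE)
}

#' Normalize response amplitudes to a 0-100 scale
#'
#' `mode = "max_is_100"` rescales so the series maximum is exactly 100
#' (idempotent); `mode = "reference_odorant"` expresses each amplitude as a
#' percentage of a supplied reference response (e.g. the same oocyte's
#' response to a benchmark odorant).
#'
#' @param amplitudes Numeric vector.
#' @param mode `"max_is_100"` or `"reference_odorant"`.
#' @param reference Reference amplitude, required and > 0 in reference
#'   mode.
#' @return Normalized numeric vector.
#' @export
normalize_series <- function(amplitudes,
                             mode = c("max_is_100", "reference_odorant"),
                             reference = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(amplitudes) || !length(amplitudes))
    stop_invalid("`amplitudes` must be numeric")
  ref <- if (mode == "max_is_100") max(amplitudes) else reference
  if (is.null(ref)) stop_invalid("`reference` is required in reference mode")
  if (!is.numeric(ref) || length(ref) != 1L || ref == 0)
    stop(errorCondition("reference amplitude is zero",
                        class = c("ssr_divide_by_zero", "error")))
  amplitudes / ref * 100
}

#' Fit a Hill dose-response model
#'
#' Least-squares fit of
#' \deqn{R(d) = baseline + \frac{E_{max} - baseline}{1 + (EC_{50}/d)^{n}}}
#' on the log10 dose axis, with multi-start initialization (a grid of
#' candidate log-EC50s spanning the observed dose decades) to avoid local
#' minima over the typical 5-decade dose span. The baseline is fixed at 0
#' by default (control oocytes show no response); set
#' `fit_baseline = TRUE` for the 4-parameter variant. The EC50 confidence
#' interval comes from the linear approximation at the optimum (delta
#' method on log10 EC50).
#'
#' @param doses Positive dose vector (molar, or linear v/v dilution - an
#'   EC50 fitted on dilutions is in dilution units).
#' @param responses Non-negative responses, same length, >= 4 points.
#' @param baseline Fixed baseline when `fit_baseline = FALSE` (default 0).
#' @param fit_baseline Fit the baseline as a 4th parameter (default FALSE).
#' @param conf_level CI level (default 0.95).
#' @return Object of class `hill_fit`: `emax`, `ec50`, `hill_n`,
#'   `baseline`, `ec50_ci`, `rss`, `converged`, `unidentifiable`,
#'   `extrapolated`, `data`.
#' @export
#' @examples
#' d <- 10^seq(-9, -4)
#' r <- 100 / (1 + (5.186e-7 / d))
#' fit_hill(d, r)$ec50
fit_hill <- function(doses, responses, baseline = 0, fit_baseline = FALSE,
                     conf_level = 0.95) {
  if (!is.numeric(doses) || !is.numeric(responses) ||
      length(doses) != length(responses))
    stop_invalid("`doses` and `responses` must be numeric, equal length")
  if (length(doses) < 4)
    stop(errorCondition("Hill fit needs at least 4 dose points",
                        class = c("ssr_insufficient_data", "error")))
  if (any(doses <= 0)) stop_invalid("doses must be positive")
  if (any(responses < 0)) stop_invalid("responses must be non-negative")
  dat <- data.frame(ld = log10(doses), resp = responses)
  out <- structure(list(baseline = baseline, data = dat, converged = FALSE,
                        unidentifiable = FALSE, extrapolated = FALSE),
                   class = "hill_fit")
  rng <- diff(range(responses))
  if (rng <= 1e-8 * max(abs(responses), 1)) {
    out$unidentifiable <- TRUE
    return(out)
  }
  starts_lec <- seq(min(dat$ld) - 1, max(dat$ld) + 1, by = 1)
  starts_hn <- c(1, 2, 0.5)
  best <- NULL
  for (lec0 in starts_lec) for (hn0 in starts_hn) {
    fit <- tryCatch({
      if (fit_baseline) {
        minpack.lm::nlsLM(
          resp ~ b + (emax - b) / (1 + 10^((lec - ld) * hn)),
          data = dat,
          start = list(emax = max(responses), lec = lec0, hn = hn0,
                       b = min(responses)),
          lower = c(emax = 0, lec = min(dat$ld) - 6, hn = 0.05, b = 0),
          upper = c(emax = Inf, lec = max(dat$ld) + 6, hn = 15, b = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200,
                                               ftol = 1e-14, ptol = 1e-14))
      } else {
        b <- baseline
        minpack.lm::nlsLM(
          resp ~ b + (emax - b) / (1 + 10^((lec - ld) * hn)),
          data = dat,
          start = list(emax = max(responses), lec = lec0, hn = hn0),
          lower = c(emax = 0, lec = min(dat$ld) - 6, hn = 0.05),
          upper = c(emax = Inf, lec = max(dat$ld) + 6, hn = 15),
          control = minpack.lm::nls.lm.control(maxiter = 200,
                                               ftol = 1e-14, ptol = 1e-14))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop(errorCondition(
      "Hill fit failed to converge from any start",
      class = c("ssr_fit_failure", "error")))
  cf <- stats::coef(best$fit)
  out$emax <- unname(cf["emax"])
  out$hill_n <- unname(cf["hn"])
  out$ec50 <- 10^unname(cf["lec"])
  if (fit_baseline) out$baseline <- unname(cf["b"])
  out$rss <- best$rss
  out$converged <- TRUE
  # flat-model comparison: a fit no better than the mean is unidentifiable
  rss_flat <- sum((responses - mean(responses))^2)
  if (rss_flat > 0 && (rss_flat - out$rss) / rss_flat < 1e-6)
    out$unidentifiable <- TRUE
  out$extrapolated <- out$ec50 < min(doses) / 10 ||
    out$ec50 > max(doses) * 10
  se_lec <- tryCatch(sqrt(diag(stats::vcov(best$fit)))["lec"],
                     error = function(e) NA_real_)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out$ec50_ci <- 10^(unname(cf["lec"]) + c(-1, 1) * zq * unname(se_lec))
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged && x$unidentifiable) {
    cat("<hill_fit> unidentifiable (responses do not vary with dose)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_fit> EC50 = %.4g [%.3g, %.3g], Emax = %.4g, n = %.3g%s%s\n",
    x$ec50, x$ec50_ci[1], x$ec50_ci[2], x$emax, x$hill_n,
    if (x$unidentifiable) " (flagged unidentifiable)" else "",
    if (x$extrapolated) " (EC50 extrapolated beyond tested range)" else ""))
  invisible(x)
}

#' Predict from a Hill fit
#'
#' @param object A `hill_fit`.
#' @param doses Doses at which to evaluate the fitted curve.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.hill_fit <- function(object, doses, ...) {
  if (!object$converged) stop_invalid("fit did not converge")
  object$baseline + (object$emax - object$baseline) /
    (1 + (object$ec50 / doses)^object$hill_n)
}

#' Lowest dose reaching a response criterion
#'
#' Inverts a fitted Hill curve (or linearly interpolates a raw series on
#' the log-dose axis) to find the lowest dose whose response reaches
#' `criterion`. Reported both as a continuous dose and snapped to the
#' tested log10 dose grid (the lowest tested dose whose fitted response
#' reaches the criterion).
#'
#' @param fit A `hill_fit`, or a data.frame with columns `dose` and
#'   `response`.
#' @param criterion Response criterion, same units as the responses (e.g.
#'   spikes/s, or % of Emax).
#' @return List: `reached` (logical; `FALSE` means the criterion is above
#'   the attainable range - "above tested range"), `dose`, `log10_dose`,
#'   `grid_dose` (NA when no tested dose reaches it).
#' @export
#' @examples
#' d <- 10^seq(-9, -4)
#' f <- fit_hill(d, 100 / (1 + 1e-6 / d))
#' threshold_dose(f, 50)$dose  # = EC50
threshold_dose <- function(fit, criterion) {
  check_number(criterion, "criterion")
  if (inherits(fit, "hill_fit")) {
    if (!fit$converged) stop_invalid("fit did not converge")
    span <- fit$emax - fit$baseline
    if (criterion <= fit$baseline || span <= 0)
      stop_invalid("criterion must exceed the baseline response")
    if (criterion >= fit$emax)
      return(list(reached = FALSE, dose = NA_real_, log10_dose = NA_real_,
                  grid_dose = NA_real_))
    frac <- (criterion - fit$baseline) / span
    dose <- fit$ec50 / ((1 / frac - 1)^(1 / fit$hill_n))
    tested <- sort(unique(10^fit$data$ld))
    hit <- tested[predict(fit, tested) >= criterion]
    list(reached = TRUE, dose = dose, log10_dose = log10(dose),
         grid_dose = if (length(hit)) min(hit) else NA_real_)
  } else if (is.data.frame(fit) &&
               all(c("dose", "response") %in% names(fit))) {
    o <- order(fit$dose)
    d <- fit$dose[o]; r <- fit$response[o]
    if (criterion > max(r))
      return(list(reached = FALSE, dose = NA_real_, log10_dose = NA_real_,
                  grid_dose = NA_real_))
    i <- which(r >= criterion)[1]
    dose <- if (i == 1 || r[i - 1] >= criterion) d[i] else {
      ld <- stats::approx(r[(i - 1):i], log10(d[(i - 1):i]),
                          xout = criterion)$y
      10^ld
    }
    list(reached = TRUE, dose = dose, log10_dose = log10(dose),
         grid_dose = d[i])
  } else {
    stop_invalid("`fit` must be a hill_fit or a dose/response data.frame")
  }
}
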