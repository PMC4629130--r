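#' Assemble an odorant x sensillum response matrix from replicate rates
#'
#' Cell mean = arithmetic mean of the replicate baseline-subtracted rates;
#' SEM = sample SD / sqrt(n). Cells whose mean is below
#' `non_responder_threshold` (15 spikes/s by convention) are flagged
#' `non_responder`; the flag never zeroes the stored mean - any filtering
#' is downstream and optional. Cells with fewer than 6 replicates are
#' marked non-compliant with the >= 6 replicate convention.
#'
#' @param records data.frame with columns `odorant`, `class`, `sensillum`,
#'   `rate` (spikes/s) and optionally `replicate`.
#' @param dose Reference dose label carried in the result (default
#'   `"1:100 v/v"`).
#' @param non_responder_threshold spikes/s (default 15).
#' @return Object of class `response_matrix`: matrices `mean`, `sem`, `n`,
#'   `non_responder` (odorants x sensilla), data.frame `odorants`
#'   (`odorant`, `class`), `sensilla`, `dose`.
#' @export
#' @examples
#' rec <- data.frame(odorant = "hexanal", class = "aldehyde",
#'                   sensillum = "Da", rate = rep(40, 6))
#' build_response_matrix(rec)$mean
build_response_matrix <- function(records, dose = "1:100 v/v",
                                  non_responder_threshold = 15) {
  need <- c("odorant", "class", "sensillum", "rate")
  if (!all(need %in% names(records)))
    stop_schema("records must have columns ",
                paste(need, collapse = ", "))
  if (!is.numeric(records$rate) || any(!is.finite(records$rate)))
    stop_schema("`rate` must be finite numeric")
  bad <- !records$class %in% odorant_classes()
  if (any(bad))
    stop_schema("unknown chemical class: ",
                paste(unique(records$class[bad]), collapse = ", "))
  bad <- !records$sensillum %in% names(sensillum_types())
  if (any(bad))
    stop_schema("unknown sensillum type: ",
                paste(unique(records$sensillum[bad]), collapse = ", "))
  cls <- unique(records[c("odorant", "class")])
  if (anyDuplicated(cls$odorant))
    stop_schema("odorant assigned to more than one class: ",
                paste(cls$odorant[duplicated(cls$odorant)], collapse = ", "))
  odorants <- cls[order(match(cls$odorant, records$odorant)), , drop = FALSE]
  rownames(odorants) <- NULL
  sens <- intersect(names(sensillum_types()), unique(records$sensillum))
  key <- interaction(factor(records$odorant, levels = odorants$odorant),
                     factor(records$sensillum, levels = sens), drop = FALSE)
  n <- tapply(records$rate, key, length)
  if (any(is.na(n)))
    stop_schema("every odorant-sensillum pair needs at least one replicate")
  mk <- function(v) matrix(v, nrow = nrow(odorants), ncol = length(sens),
                           dimnames = list(odorants$odorant, sens))
  m <- mk(tapply(records$rate, key, mean))
  sd_ <- mk(tapply(records$rate, key, stats::sd))
  n <- mk(as.vector(n))
  structure(list(mean = m, sem = sd_ / sqrt(n), n = n,
                 non_responder = m < non_responder_threshold,
                 odorants = odorants, sensilla = sens, dose = dose,
                 non_responder_threshold = non_responder_threshold,
                 replicate_compliant = all(n >= 6)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf(
    "<response_matrix> %d odorants x %d sensilla (%d cells) at %s\n",
    nrow(x$mean), ncol(x$mean), length(x$mean), x$dose))
  cat(sprintf("  replicates: %s; non-responders (<%g spikes/s): %d\n",
              paste(range(x$n), collapse = "-"),
              x$non_responder_threshold, sum(x$non_responder)))
  invisible(x)
}

#' Simulate a full odorant x sensillum response matrix
#'
#' Runs the spike-train generator for every cell of the panel under an
#' archetype preset: `n_replicates` seeded trains per cell, each scored
#' with the baseline-subtracted [firing_rate()], then averaged with
#' [build_response_matrix()]. With the default 104-odorant panel and six
#' sensillum types this yields 624 odorant-sensillum combinations.
#'
#' @param archetypes An `archetype_preset` (default [default_archetypes()]).
#' @param panel Odorant panel data.frame (default [default_odorant_panel()]).
#' @param n_replicates Replicates per cell, >= 1 (default 6).
#' @param dose log10 v/v dilution (default the preset's reference dose).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param duration,stimulus_onset Recording geometry for each simulated
#'   train (defaults 2.6 s and 0.5 s keep a full pre-stimulus baseline and
#'   a 2 s post-onset window while staying cheap).
#' @return A `response_matrix` with the replicate `records` data.frame
#'   attached as `$records`.
#' @export
gen_response_matrix <- function(archetypes = default_archetypes(),
                                panel = default_odorant_panel(),
                                n_replicates = 6, dose = NULL, seed = NULL,
                                duration = 2.6, stimulus_onset = 0.5) {
  if (!is.numeric(n_replicates) || n_replicates < 1)
    stop_invalid("`n_replicates` must be >= 1")
  n_replicates <- as.integer(n_replicates)
  dose <- dose %||% archetypes$reference_dose
  cells <- expand_archetypes(archetypes, panel)
  with_seed(seed, {
    recs <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      rates <- vapply(seq_len(n_replicates), function(j) {
        tr <- gen_spike_train(cells$profile[[i]], dose = dose,
                              duration = duration,
                              stimulus_onset = stimulus_onset)
        firing_rate(tr, onset = stimulus_onset)
      }, numeric(1))
      recs[[i]] <- data.frame(
        odorant = cells$odorant[i], class = cells$class[i],
        sensillum = cells$sensillum[i], replicate = seq_len(n_replicates),
        rate = rates, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    out <- build_response_matrix(
      records, dose = sprintf("1:%g v/v", 10^(-dose)))
    out$records <- records
    out
  })
}

#' Distribution of responses across firing-rate bands
#'
#' Partitions the matrix cells into the conventional strength bands
#' `<50`, `[50,100]`, `(100,150]`, `(150,200]`, `>200` spikes/s. The
#' published band edges overlap (">=50, <=100" is followed by
#' ">=100, <=150"); ties at a shared endpoint are assigned to the lower
#' band so the bands form an exact partition - a cell at exactly
#' 100 spikes/s counts in `[50,100]`.
#'
#' @param matrix A `response_matrix`.
#' @return data.frame with `band`, `count`, `fraction_pct` (1 decimal).
#' @export
band_distribution <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  x <- as.vector(matrix$mean)
  if (!length(x)) stop_invalid("response matrix has no cells")
  # right-closed intervals put shared endpoints in the lower band
  band <- cut(x, breaks = c(-Inf, 50, 100, 150, 200, Inf), right = TRUE,
              labels = c("<50", "50-100", "100-150", "150-200", ">=200"))
  # 50 itself belongs to the 50-100 band (the lower of ITS two bands):
  band[x == 50] <- "50-100"
  # cut() with right=TRUE puts (.,50] low, so values strictly below 50 only:
  band[x < 50] <- "<50"
  counts <- table(band)
  data.frame(band = names(counts), count = as.integer(counts),
             fraction_pct = round(100 * as.integer(counts) / length(x), 1),
             stringsAsFactors = FALSE)
}

#' Per-class response proportions at a firing-rate threshold
#'
#' For each chemical class, the fraction of member odorants whose response
#' reaches `threshold` spikes/s. Two variants: `"per_sensillum"` (default)
#' reports the fraction separately for each sensillum type;
#' `"max_across_sensilla"` counts an odorant as a responder if any
#' sensillum reaches the threshold.
#'
#' @param matrix A `response_matrix`.
#' @param threshold spikes/s (default 50, the excitatory-response
#'   criterion).
#' @param variant `"per_sensillum"` or `"max_across_sensilla"`.
#' @return data.frame with `class`, `n_odorants`, (`sensillum`,)
#'   `n_responders`, `fraction_pct`.
#' @export
class_bias <- function(matrix, threshold = 50,
                       variant = c("per_sensillum", "max_across_sensilla")) {
  stopifnot(inherits(matrix, "response_matrix"))
  variant <- match.arg(variant)
  cls <- matrix$odorants$class
  classes <- unique(cls)
  if (variant == "max_across_sensilla") {
    hit <- apply(matrix$mean, 1, max) >= threshold
    out <- do.call(rbind, lapply(classes, function(cl) {
      sel <- cls == cl
      data.frame(class = cl, n_odorants = sum(sel),
                 n_responders = sum(hit[sel]),
                 fraction_pct = round(100 * mean(hit[sel])),
                 stringsAsFactors = FALSE)
    }))
  } else {
    out <- do.call(rbind, lapply(classes, function(cl) {
      sel <- cls == cl
      do.call(rbind, lapply(matrix$sensilla, function(s) {
        hit <- matrix$mean[sel, s] >= threshold
        data.frame(class = cl, sensillum = s, n_odorants = sum(sel),
                   n_responders = sum(hit),
                   fraction_pct = round(100 * mean(hit)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  rownames(out) <- NULL
  out
}

#' Tuning curve of one sensillum type
#'
#' Orders the sensillum's responses to the whole panel strongest-at-center:
#' responses are sorted descending and placed alternately outward from the
#' center (rank 1 at the center, rank 2 immediately left, rank 3
#' immediately right, ...), so the weakest responses sit at the edges. Ties
#' are broken by odorant id (lexicographic), making the arrangement
#' deterministic. The arrangement is always a permutation of the matrix
#' column.
#'
#' @param matrix A `response_matrix`.
#' @param sensillum One of the matrix's sensillum codes.
#' @return Object of class `tuning_curve`: `ordered_rates`,
#'   `ordered_odorants`, `K` (excess kurtosis of the column, `NA` with a
#'   `degenerate` flag for a constant column), `sensillum`.
#' @export
#' @examples
#' rec <- data.frame(
#'   odorant = c("a", "b", "c"), class = "aldehyde",
#'   sensillum = "Da", rate = c(10, 30, 20))
#' tuning_curve(build_response_matrix(rec), "Da")$ordered_rates
tuning_curve <- function(matrix, sensillum) {
  stopifnot(inherits(matrix, "response_matrix"))
  if (!sensillum %in% matrix$sensilla)
    stop_schema("matrix has no sensillum column: ", sensillum)
  x <- matrix$mean[, sensillum]
  ids <- rownames(matrix$mean)
  ord <- order(-x, ids)
  n <- length(x)
  pos <- integer(n)
  center <- n %/% 2L + 1L
  offsets <- integer(n)
  if (n > 1) {
    k <- seq_len(n - 1L)
    # rank 2 goes one left, rank 3 one right, rank 4 two left, ...
    offsets[-1] <- ifelse(k %% 2L == 1L, -(k + 1L) %/% 2L, (k + 1L) %/% 2L)
  }
  pos[center + offsets] <- ord
  degenerate <- length(unique(x)) == 1L
  K <- if (degenerate || n < 4) NA_real_ else kurtosis_k(x)
  structure(list(sensillum = sensillum, ordered_rates = unname(x[pos]),
                 ordered_odorants = ids[pos], K = K,
                 degenerate = degenerate),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s: %d odorants, peak %.1f spikes/s, K = %s\n",
              x$sensillum, length(x$ordered_rates),
              max(x$ordered_rates),
              if (is.na(x$K)) "NA" else format(round(x$K, 2))))
  invisible(x)
}

#' @rdname tuning_curve
#' @param x A `tuning_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(seq_along(x$ordered_rates), x$ordered_rates, type = "h",
                 xlab = "odorant (center-out order)",
                 ylab = "response (spikes/s)",
                 main = sprintf("%s  K = %.2f", x$sensillum, x$K), ...)
  invisible(x)
}

#' Tuning-breadth kurtosis (K value)
#'
#' Corrected sample excess kurtosis, the convention of mainstream
#' statistics packages (SPSS/Excel type 2):
#' \deqn{K = \frac{n(n+1)}{(n-1)(n-2)(n-3)} \sum\left(\frac{x_i -
#'   \bar x}{s}\right)^4 - \frac{3(n-1)^2}{(n-2)(n-3)}}
#' with \eqn{s} the sample SD. High K means a narrowly tuned sensillum
#' (a few strong responses over a flat background); a Gaussian sample has
#' K near 0. `type = "raw"` returns the non-excess version (`K + 3`).
#'
#' @param rates Numeric vector, length >= 4, non-constant.
#' @param type `"excess"` (default) or `"raw"`.
#' @return K, dimensionless.
#' @export
#' @examples
#' kurtosis_k(c(rep(0, 20), 250))  # sharply peaked -> large K
kurtosis_k <- function(rates, type = c("excess", "raw")) {
  type <- match.arg(type)
  x <- as.numeric(rates)
  n <- length(x)
  if (n < 4)
    stop(errorCondition("kurtosis needs at least 4 values",
                        class = c("ssr_insufficient_data", "error")))
  s <- stats::sd(x)
  if (s == 0)
    stop(errorCondition("kurtosis is undefined for a constant vector",
                        class = c("ssr_undefined_kurtosis", "error")))
  z4 <- sum(((x - mean(x)) / s)^4)
  k <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * z4 -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  if (type == "raw") k + 3 else k
}
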