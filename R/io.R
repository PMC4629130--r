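#' Write / read a response matrix as tidy TSV
#'
#' Format: one row per odorant with columns `odorant`, `class`, then the
#' six sensillum codes (`Da Db Dg C E1 E2`) holding mean rates in
#' spikes/s. An optional paired SEM table uses the same layout. Values
#' round-trip losslessly at full printed precision.
#'
#' @param matrix A `response_matrix`.
#' @param path Output TSV path.
#' @param sem_path Optional path for the SEM table.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(matrix, path, sem_path = NULL) {
  stopifnot(inherits(matrix, "response_matrix"))
  df <- data.frame(odorant = matrix$odorants$odorant,
                   class = matrix$odorants$class,
                   matrix$mean, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sem_path)) {
    dfs <- df
    dfs[matrix$sensilla] <- as.data.frame(matrix$sem)
    utils::write.table(dfs, sem_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_response_matrix
#' @param dose Reference dose label for the reconstructed object.
#' @param non_responder_threshold spikes/s (default 15).
#' @return `read_response_matrix()` returns a `response_matrix` (with
#'   `n = 1` per cell and `sem` from the sidecar when given, `NA`
#'   otherwise).
#' @export
read_response_matrix <- function(path, sem_path = NULL,
                                 dose = "1:100 v/v",
                                 non_responder_threshold = 15) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("odorant", "class") %in% names(df)))
    stop_schema("response matrix file needs `odorant` and `class` columns: ",
                path)
  sens <- intersect(names(sensillum_types()), names(df))
  if (!length(sens))
    stop_schema("no sensillum columns (Da/Db/Dg/C/E1/E2) in ", path)
  if (anyDuplicated(df$odorant))
    stop_schema("duplicate odorant row(s): ",
                paste(unique(df$odorant[duplicated(df$odorant)]),
                      collapse = ", "))
  bad <- !df$class %in% odorant_classes()
  if (any(bad))
    stop_schema("unknown class in rows: ",
                paste(which(bad), collapse = ", "))
  for (s in sens)
    if (!is.numeric(df[[s]]))
      stop_schema("non-numeric cell(s) in column ", s)
  m <- as.matrix(df[sens])
  rownames(m) <- df$odorant
  sem <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (!is.null(sem_path)) {
    dfs <- utils::read.delim(sem_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!identical(dfs$odorant, df$odorant))
      stop_schema("SEM table odorants do not match the mean table")
    sem <- as.matrix(dfs[sens])
    rownames(sem) <- df$odorant
  }
  structure(list(mean = m, sem = sem,
                 n = matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m)),
                 non_responder = m < non_responder_threshold,
                 odorants = df[c("odorant", "class")], sensilla = sens,
                 dose = dose,
                 non_responder_threshold = non_responder_threshold,
                 replicate_compliant = FALSE),
            class = "response_matrix")
}

#' Write a spike train as TSV
#'
#' One row per spike: `replicate`, `time_s`. Metadata goes in `# key: value`
#' header comments.
#'
#' @param train A `spike_train` (or list of trains sharing metadata).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(train, path) {
  trains <- if (inherits(train, "spike_train")) list(train) else train
  stopifnot(all(vapply(trains, inherits, logical(1), "spike_train")))
  md <- trains[[1]]$metadata
  hdr <- c(sprintf("# duration_s: %.10g", trains[[1]]$duration),
           sprintf("# %s: %s",
                   names(md)[!vapply(md, is.null, logical(1))],
                   vapply(md[!vapply(md, is.null, logical(1))],
                          function(v) paste(format(v), collapse = ","),
                          character(1))))
  rows <- do.call(rbind, lapply(seq_along(trains), function(i)
    if (length(trains[[i]]$times))
      data.frame(replicate = i, time_s = trains[[i]]$times) else NULL))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("replicate\ttime_s", con)
  if (!is.null(rows))
    utils::write.table(format(rows, digits = 12, trim = TRUE), con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

#' Write / read a voltage trace as CSV with a metadata sidecar
#'
#' The trace goes to `path` as a one-column CSV of amplitudes (µV); the
#' sidecar `<path>.meta.yaml` records `sampling_rate`, `stimulus_onset`,
#' `stimulus_duration` and any metadata fields.
#'
#' @param trace A `voltage_trace`.
#' @param path Output CSV path.
#' @return `path` invisibly; `read_voltage_trace()` returns the
#'   reconstructed `voltage_trace`.
#' @export
write_voltage_trace <- function(trace, path) {
  stopifnot(inherits(trace, "voltage_trace"))
  utils::write.csv(data.frame(amplitude_uv = trace$samples), path,
                   row.names = FALSE)
  fixed <- c("sampling_rate", "stimulus_onset", "stimulus_duration")
  meta <- c(list(sampling_rate = trace$sampling_rate,
                 stimulus_onset = trace$stimulus_onset,
                 stimulus_duration = trace$stimulus_duration),
            trace$metadata[setdiff(names(trace$metadata), fixed)])
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path))
    stop_schema("missing metadata sidecar: ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  x <- utils::read.csv(path)$amplitude_uv
  voltage_trace(x, meta$sampling_rate, meta$stimulus_onset,
                meta$stimulus_duration,
                metadata = meta[setdiff(names(meta),
                                        c("sampling_rate", "stimulus_onset",
                                          "stimulus_duration"))])
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end pipeline in one round-trippable list:
#' the odorant panel, the six sensillum types, replicate count, the dose
#' grid (log10 v/v), window geometry (0.5 s stimulus, 2 s / 0.1 s PSTH),
#' the 15 spikes/s non-responder and 50 spikes/s excitatory thresholds,
#' and the seed.
#'
#' @param seed Integer seed (default 1).
#' @param n_replicates Replicates per odorant-sensillum cell (default 6).
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, n_replicates = 6) {
  structure(list(
    panel = default_odorant_panel(),
    sensilla = names(sensillum_types()),
    n_replicates = n_replicates,
    reference_dose = -2,
    dose_grid = c(-5, -4, -3, -2, -1),
    dose_units = "log10_vv",
    windows = list(stimulus_onset = 0.5, stimulus_duration = 0.5,
                   psth_window = 2, psth_bin = 0.1, duration = 2.6),
    thresholds = list(non_responder = 15, excitatory = 50),
    trace = list(sampling_rate = 20000, noise_sd = 6,
                 template_amplitude = 100),
    oocyte = list(ec50 = 5.186e-7, hill = 1, emax = 100,
                  doses = 10^seq(-9, -4), noise_frac = 0.05),
    seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return `config`, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_schema("not a pipeline_config")
  with(config, {
    if (!all(panel$class %in% odorant_classes()))
      stop_schema("panel classes must come from the 11-class vocabulary")
    if (anyDuplicated(panel$odorant)) stop_schema("duplicate panel odorants")
    if (!all(sensilla %in% names(sensillum_types())))
      stop_schema("unknown sensillum in config")
    if (thresholds$non_responder <= 0 || thresholds$excitatory <= 0)
      stop_schema("thresholds must be positive")
    if (n_replicates < 1) stop_schema("n_replicates must be >= 1")
    if (windows$duration <= windows$stimulus_onset + windows$psth_window)
      stop_schema("recording too short for the PSTH window")
  })
  invisible(config)
}

#' Write / read a pipeline configuration as YAML
#'
#' The round trip is lossless: `read_config(write_config(cfg, p))` equals
#' `cfg`.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_config()` returns the
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  x <- unclass(config)
  x$panel <- list(odorant = config$panel$odorant,
                  class = config$panel$class)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$panel <- data.frame(odorant = x$panel$odorant,
                        class = x$panel$class, stringsAsFactors = FALSE)
  x$seed <- as.integer(x$seed)
  x$n_replicates <- as.integer(x$n_replicates)
  validate_config(structure(x, class = "pipeline_config"))
}
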