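#' Run the end-to-end SSR quantification pipeline
#'
#' Executes the analysis chain on synthetic data under one seed and writes
#' every artifact plus a machine-readable `summary.json` to `outdir`.
#' Stages:
#' \describe{
#'   \item{simulate}{replicate firing-rate table + response matrix from the
#'     archetype preset; ground-truth spike trains rendered as voltage
#'     traces; PSTHs of the aldehyde panel; oocyte dose-response series.}
#'   \item{detect}{spike detection on the rendered traces, scored against
#'     the generating ground truth.}
#'   \item{rates}{baseline-subtracted rates recomputed from the detected
#'     trains.}
#'   \item{tuning}{band distribution, class biases, tuning curves and K
#'     values.}
#'   \item{space}{odorant-space distances, top-k pairs, UPGMA tree
#'     (Newick), correlation-matrix PCA, temporal clustering.}
#'   \item{fit}{Hill fits of the oocyte series; EC50 table.}
#'   \item{all}{everything above, in order.}
#' }
#' Later stages read the artifacts written by earlier ones, so running a
#' downstream stage into an empty directory is a dependency error naming
#' the stage to run first. Identical config + seed reproduce byte-identical
#' summaries.
#'
#' @param config A `pipeline_config` (default [default_config()]).
#' @param stage One of `"simulate"`, `"detect"`, `"rates"`, `"tuning"`,
#'   `"space"`, `"fit"`, `"all"`.
#' @param outdir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), stage = "all",
                         outdir = tempfile("ssr_run_")) {
  stage <- match.arg(stage, c("simulate", "detect", "rates", "tuning",
                              "space", "fit", "all"))
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "detect", "rates", "tuning", "space", "fit") else stage
  log_path <- file.path(outdir, "run_log.txt")
  cfg_path <- file.path(outdir, "config.yaml")
  write_config(config, cfg_path)
  log_line <- function(...) cat(paste0(format(Sys.time(),
                                              "%Y-%m-%d %H:%M:%S"), " ",
                                       ..., "\n"),
                                file = log_path, append = TRUE)
  log_line("run start; seed=", config$seed, "; config_md5=",
           unname(tools::md5sum(cfg_path)), "; sensillaR=",
           as.character(utils::packageVersion("sensillaR")),
           "; R=", getRversion())
  summary_path <- file.path(outdir, "summary.json")
  summary <- if (file.exists(summary_path))
    jsonlite::read_json(summary_path) else list()
  need <- function(f, from) {
    p <- file.path(outdir, f)
    if (!file.exists(p))
      stop(errorCondition(
        sprintf("missing upstream artifact %s: run stage '%s' first", f,
                from),
        class = c("ssr_dependency_error", "error")))
    p
  }
  for (st in stages) {
    log_line("stage ", st)
    summary[[st]] <- switch(st,
      simulate = stage_simulate(config, outdir),
      detect = stage_detect(config, outdir, need),
      rates = stage_rates(config, outdir, need),
      tuning = stage_tuning(config, outdir, need),
      space = stage_space(config, outdir, need),
      fit = stage_fit(config, outdir, need))
  }
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line("run complete")
  invisible(summary)
}

stage_simulate <- function(config, outdir) {
  w <- config$windows
  preset <- default_archetypes(reference_dose = config$reference_dose)
  rm_ <- gen_response_matrix(preset, config$panel,
                             n_replicates = config$n_replicates,
                             dose = config$reference_dose,
                             seed = config$seed,
                             duration = w$duration,
                             stimulus_onset = w$stimulus_onset)
  write_response_matrix(rm_, file.path(outdir, "response_matrix.tsv"),
                        sem_path = file.path(outdir, "response_sem.tsv"))
  utils::write.table(rm_$records, file.path(outdir, "replicate_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # ground-truth trains + rendered voltage traces for the detector stage
  cells <- expand_archetypes(preset, config$panel)
  strong <- order(-cells$rate)[1:4]
  fs <- config$trace$sampling_rate
  tpl <- spike_template(fs, amplitude = config$trace$template_amplitude)
  truth <- list()
  for (i in seq_along(strong)) {
    pr <- cells$profile[[strong[i]]]
    tr <- gen_spike_train(pr, dose = config$reference_dose,
                          duration = w$duration,
                          stimulus_onset = w$stimulus_onset,
                          seed = config$seed + i)
    v <- gen_voltage_trace(tr, tpl, fs, noise_sd = config$trace$noise_sd,
                           seed = config$seed + 1000L + i)
    write_voltage_trace(v, file.path(outdir, sprintf("trace_%02d.csv", i)))
    write_spike_train(tr, file.path(outdir,
                                    sprintf("truth_spikes_%02d.tsv", i)))
    truth[[i]] <- length(tr$times)
  }
  # PSTHs of the aldehyde panel on Dg (mixed phasic/tonic kernels)
  ald <- config$panel$odorant[config$panel$class == "aldehyde"]
  psths <- lapply(seq_along(ald), function(i) {
    pr <- cells$profile[[which(cells$sensillum == "Dg" &
                                 cells$odorant == ald[i])]]
    tr <- gen_spike_train(pr, dose = config$reference_dose,
                          duration = w$duration,
                          stimulus_onset = w$stimulus_onset,
                          seed = config$seed + 2000L + i)
    compute_psth(tr, onset = w$stimulus_onset, window = w$psth_window,
                 bin_width = w$psth_bin)
  })
  names(psths) <- ald
  psth_m <- do.call(rbind, lapply(psths, function(p) p$counts))
  utils::write.table(
    data.frame(odorant = ald, psth_m, check.names = FALSE),
    file.path(outdir, "psth_counts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  # oocyte dose-response series
  oc <- config$oocyte
  traces <- gen_current_trace(oc$ec50, oc$hill, oc$emax, oc$doses,
                              noise_sd = oc$noise_frac * oc$emax,
                              seed = config$seed + 3000L)
  amp <- vapply(traces, extract_amplitude, numeric(1))
  utils::write.table(
    data.frame(ligand = "nonanal", receptor = "Or1_Orco", dose = oc$doses,
               dose_units = "M", response = amp),
    file.path(outdir, "dose_response.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(n_cells = length(rm_$mean),
       n_records = nrow(rm_$records),
       n_traces = length(strong),
       truth_spike_counts = unlist(truth))
}

stage_detect <- function(config, outdir, need) {
  i <- 1L
  res <- list()
  repeat {
    p <- file.path(outdir, sprintf("trace_%02d.csv", i))
    if (!file.exists(p)) break
    if (i == 1L) need(sprintf("trace_%02d.csv", i), "simulate")
    v <- read_voltage_trace(p)
    det <- detect_spikes(v, threshold_k = 5)
    write_spike_train(det, file.path(outdir,
                                     sprintf("detected_spikes_%02d.tsv", i)))
    truth <- utils::read.delim(
      file.path(outdir, sprintf("truth_spikes_%02d.tsv", i)),
      comment.char = "#")
    res[[i]] <- c(n_true = nrow(truth), n_detected = length(det$times))
    i <- i + 1L
  }
  if (!length(res)) need("trace_01.csv", "simulate")
  list(per_trace = res)
}

stage_rates <- function(config, outdir, need) {
  need("replicate_rates.tsv", "simulate")
  rec <- utils::read.delim(file.path(outdir, "replicate_rates.tsv"))
  agg <- stats::aggregate(rate ~ odorant + sensillum, rec, mean)
  utils::write.table(agg, file.path(outdir, "mean_rates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(n_pairs_scored = nrow(agg),
       max_rate = max(agg$rate))
}

stage_tuning <- function(config, outdir, need) {
  m <- read_response_matrix(need("response_matrix.tsv", "simulate"),
                            non_responder_threshold =
                              config$thresholds$non_responder)
  bands <- band_distribution(m)
  utils::write.table(bands, file.path(outdir, "band_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bias <- class_bias(m, threshold = config$thresholds$excitatory)
  utils::write.table(bias, file.path(outdir, "class_bias.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ks <- vapply(m$sensilla, function(s) tuning_curve(m, s)$K, numeric(1))
  tc <- do.call(rbind, lapply(m$sensilla, function(s) {
    t <- tuning_curve(m, s)
    data.frame(sensillum = s, position = seq_along(t$ordered_rates),
               odorant = t$ordered_odorants, rate = t$ordered_rates)
  }))
  utils::write.table(tc, file.path(outdir, "tuning_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(bands = stats::setNames(as.list(bands$count), bands$band),
       band_fractions = stats::setNames(as.list(bands$fraction_pct),
                                        bands$band),
       K = as.list(round(ks, 2)),
       n_non_responders = sum(m$non_responder))
}

stage_space <- function(config, outdir, need) {
  m <- read_response_matrix(need("response_matrix.tsv", "simulate"))
  sp <- build_space(m)
  utils::write.table(round(sp$distance, 3),
                     file.path(outdir, "distance_matrix.tsv"), sep = "\t",
                     quote = TRUE, row.names = TRUE, col.names = NA)
  top <- rbind(cbind(direction = "closest",
                     rank_pairs(sp, 10, "closest")),
               cbind(direction = "farthest",
                     rank_pairs(sp, 10, "farthest")))
  utils::write.table(top, file.path(outdir, "top_pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tree <- hcluster(sp)
  write_newick(tree, file.path(outdir, "odor_space_tree.nwk"))
  pca <- pca_space(m, n_components = 3)
  utils::write.table(
    data.frame(odorant = rownames(pca$scores), round(pca$scores, 6)),
    file.path(outdir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sensillum = rownames(pca$loadings),
               round(pca$loadings, 6)),
    file.path(outdir, "pca_loadings.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  # temporal clustering of the simulated aldehyde PSTHs
  pm <- utils::read.delim(need("psth_counts.tsv", "simulate"),
                          check.names = FALSE)
  counts <- as.matrix(pm[, -1])
  rownames(counts) <- pm$odorant
  ttree <- hcluster(counts)
  write_newick(ttree, file.path(outdir, "temporal_tree.nwk"))
  groups <- cut_tree(ttree, 2)
  utils::write.table(
    data.frame(odorant = names(groups), cluster = unname(groups)),
    file.path(outdir, "temporal_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  far <- rank_pairs(sp, 10, "farthest")
  list(n_pairs = sp$n_pairs,
       pca_cumulative_pct_3 = round(pca$cumulative_pct, 2),
       farthest_pair = paste(far$odorant_a[1], far$odorant_b[1],
                             sep = " / "),
       farthest_distance = far$distance_1dp[1],
       top10_farthest_sharing_common_member = max(table(
         c(far$odorant_a, far$odorant_b))))
}

stage_fit <- function(config, outdir, need) {
  dr <- utils::read.delim(need("dose_response.tsv", "simulate"))
  fit <- fit_hill(dr$dose, dr$response)
  thr <- threshold_dose(fit, 0.1 * fit$emax)
  tab <- data.frame(ligand = dr$ligand[1], receptor = dr$receptor[1],
                    ec50 = fit$ec50, ec50_lo = fit$ec50_ci[1],
                    ec50_hi = fit$ec50_ci[2], emax = fit$emax,
                    hill_n = fit$hill_n, rss = fit$rss,
                    threshold_dose_10pct = thr$dose)
  utils::write.table(tab, file.path(outdir, "ec50_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(ec50 = fit$ec50, emax = fit$emax, hill_n = fit$hill_n)
}
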