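#' Build the 6-dimensional odorant space
#'
#' Each odorant becomes the vector of its mean baseline-subtracted
#' responses (spikes/s) across the six sensillum types, signed (inhibitory
#' values kept). Discriminability between odorants is the Euclidean
#' distance between their vectors; a 104-odorant panel yields
#' 104*103/2 = 5356 unordered pairs.
#'
#' @param matrix A `response_matrix` with all six sensillum columns.
#' @return Object of class `odor_space`: `odorant_ids`, `vectors`
#'   (odorants x sensilla matrix), `distance` (full symmetric matrix,
#'   spikes/s), `n_pairs`.
#' @export
build_space <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  missing <- setdiff(names(sensillum_types()), matrix$sensilla)
  if (length(missing))
    stop_schema("matrix is missing sensillum column(s): ",
                paste(missing, collapse = ", "))
  v <- matrix$mean[, names(sensillum_types()), drop = FALSE]
  d <- as.matrix(stats::dist(v, method = "euclidean"))
  n <- nrow(v)
  structure(list(odorant_ids = rownames(v), vectors = v, distance = d,
                 n_pairs = (n * (n - 1L)) %/% 2L),
            class = "odor_space")
}

#' @export
print.odor_space <- function(x, ...) {
  cat(sprintf("<odor_space> %d odorants in %d dimensions; %d pairs\n",
              length(x$odorant_ids), ncol(x$vectors), x$n_pairs))
  invisible(x)
}

#' Rank odorant pairs by Euclidean distance
#'
#' @param space An `odor_space`.
#' @param k Number of pairs to return (<= `n_pairs`).
#' @param direction `"closest"` (ascending) or `"farthest"` (descending).
#' @return data.frame with `odorant_a`, `odorant_b`, `distance` (full
#'   precision) and `distance_1dp` (reported to 1 decimal). Ties are broken
#'   by the lexicographic pair id.
#' @export
rank_pairs <- function(space, k = 10,
                       direction = c("closest", "farthest")) {
  stopifnot(inherits(space, "odor_space"))
  direction <- match.arg(direction)
  if (!is.numeric(k) || k <= 0) stop_invalid("`k` must be positive")
  if (k > space$n_pairs)
    stop_invalid("`k` exceeds the number of pairs (", space$n_pairs, ")")
  ids <- space$odorant_ids
  idx <- which(upper.tri(space$distance), arr.ind = TRUE)
  a <- ids[idx[, 1]]
  b <- ids[idx[, 2]]
  swap <- a > b
  pair_a <- ifelse(swap, b, a)
  pair_b <- ifelse(swap, a, b)
  d <- space$distance[idx]
  ord <- if (direction == "closest") order(d, pair_a, pair_b)
         else order(-d, pair_a, pair_b)
  sel <- ord[seq_len(k)]
  data.frame(odorant_a = pair_a[sel], odorant_b = pair_b[sel],
             distance = d[sel], distance_1dp = round(d[sel], 1),
             stringsAsFactors = FALSE)
}

#' Hierarchical clustering under between-group (UPGMA) linkage
#'
#' Agglomerative clustering of odorants (or PSTH profiles) on Euclidean
#' distances with unweighted pair-group average linkage - "between-group
#' linkage" in SPSS terminology: the distance between two clusters is the
#' mean of all between-cluster pairwise distances,
#' \deqn{d(A,B) = \frac{1}{|A||B|}\sum_{a \in A}\sum_{b \in B} d(a,b).}
#'
#' @param x An `odor_space`, a `dist`, or a numeric matrix of row profiles.
#' @return Object of class `cluster_tree` wrapping the `hclust` result
#'   (`$hclust`), with `labels` and `method`.
#' @export
hcluster <- function(x) {
  d <- if (inherits(x, "odor_space")) stats::as.dist(x$distance)
       else if (inherits(x, "dist")) x
       else if (is.matrix(x) && is.numeric(x)) stats::dist(x)
       else stop_invalid("`x` must be an odor_space, dist, or matrix")
  if (any(!is.finite(d)))
    stop_invalid("distances must be finite")
  if (attr(d, "Size") < 2) stop_invalid("need at least 2 items to cluster")
  h <- stats::hclust(d, method = "average")
  structure(list(hclust = h, labels = h$labels,
                 method = "between-group average (UPGMA)"),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %s linkage\n",
              length(x$labels %||% x$hclust$order), x$method))
  invisible(x)
}

#' Cut a cluster tree into k groups
#'
#' @param tree A `cluster_tree`.
#' @param k Number of clusters.
#' @return Named integer vector of cluster assignments.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "cluster_tree"))
  stats::cutree(tree$hclust, k = k)
}

#' Export a cluster tree as Newick
#'
#' @param tree A `cluster_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Correlation-matrix PCA of the odorant space
#'
#' Principal component analysis with odorants as observations and the six
#' sensillum types as variables. Columns are standardized to zero mean and
#' unit variance and the 6 x 6 correlation matrix is eigendecomposed; the
#' variance explained by each component is its eigenvalue divided by the
#' number of sensilla, so the full decomposition always accounts for 100%.
#'
#' @param matrix A `response_matrix` (or an `odor_space`).
#' @param n_components Components to report in the cumulative summary
#'   (default 3).
#' @return Object of class `pca_result`: `loadings` (sensilla x
#'   components), `scores` (odorants x components, standardized space),
#'   `variance_explained` (fraction per component, all components),
#'   `cumulative_pct` (percent, first `n_components`), `n_components`.
#' @export
pca_space <- function(matrix, n_components = 3) {
  v <- if (inherits(matrix, "odor_space")) matrix$vectors
       else if (inherits(matrix, "response_matrix")) matrix$mean
       else stop_invalid("`matrix` must be a response_matrix or odor_space")
  p <- ncol(v)
  if (!is.numeric(n_components) || n_components < 1 || n_components > p)
    stop_invalid("`n_components` must be between 1 and ", p)
  if (nrow(v) <= p)
    stop_invalid("PCA needs more odorants than sensilla (", p, ")")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0))
    stop(errorCondition(
      paste0("constant column(s): ",
             paste(colnames(v)[sds == 0], collapse = ", "),
             "; correlation-matrix PCA is undefined"),
      class = c("ssr_degenerate_column", "error")))
  z <- scale(v)
  e <- eigen(stats::cor(v), symmetric = TRUE)
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(v), paste0("PC", seq_len(p)))
  scores <- z %*% loadings
  var_expl <- e$values / p
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = var_expl,
                 cumulative_pct = 100 * cumsum(var_expl)[n_components],
                 n_components = as.integer(n_components)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d components retained; cumulative variance %.2f%%\n",
    x$n_components, x$cumulative_pct))
  print(round(100 * x$variance_explained, 2))
  invisible(x)
}

#' Phasic/tonic index of a PSTH
#'
#' Ratio of the mean firing rate in the late window (bins 11-20, i.e.
#' 1.0-2.0 s after onset) to the peak rate during the stimulus (bins 1-5,
#' the 500 ms odor pulse). A sustained (tonic) response keeps firing high
#' after the stimulus and scores near 1; a phasic onset burst decays and
#' scores near 0. Labelled `"tonic"` when the index reaches `threshold`
#' (0.5 by default - an operational cut, the field uses the terms
#' qualitatively).
#'
#' @param psth A 20-bin [compute_psth()] result with the stimulus occupying
#'   the first 5 bins.
#' @param threshold Tonic label threshold on the index (default 0.5).
#' @return List with `index` in `[0, 1]` (clipped) and `label`.
#' @export
phasic_tonic_index <- function(psth, threshold = 0.5) {
  stopifnot(inherits(psth, "psth"))
  if (length(psth$counts) != 20L)
    stop_invalid("phasic/tonic index expects a 20-bin PSTH")
  peak <- max(psth$rates[1:5])
  if (peak <= 0)
    stop(errorCondition(
      "no stimulus-window activity; phasic/tonic index is undefined",
      class = c("ssr_undefined_index", "error")))
  idx <- min(1, max(0, mean(psth$rates[11:20]) / peak))
  list(index = idx, label = if (idx >= threshold) "tonic" else "phasic")
}

#' Cluster stimuli by response temporal structure
#'
#' Hierarchical clustering (Euclidean, between-group average linkage) of
#' the per-bin spike counts of a set of PSTHs, the standard way to group
#' odorants by phasic/tonic response shape.
#'
#' @param psths Named list of `psth` objects with identical binning.
#' @return A `cluster_tree`.
#' @export
temporal_cluster <- function(psths) {
  if (!is.list(psths) || length(psths) < 2 ||
      !all(vapply(psths, inherits, logical(1), "psth")))
    stop_invalid("`psths` must be a list of at least two psth objects")
  nb <- vapply(psths, function(p) length(p$counts), integer(1))
  bw <- vapply(psths, function(p) p$bin_width, numeric(1))
  if (length(unique(nb)) != 1L || length(unique(bw)) != 1L)
    stop_invalid("all PSTHs must share the same bin structure")
  m <- do.call(rbind, lapply(psths, function(p) p$counts))
  rownames(m) <- names(psths) %||%
    vapply(psths, function(p) p$metadata$odorant_id %||% "?", character(1))
  hcluster(m)
}
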