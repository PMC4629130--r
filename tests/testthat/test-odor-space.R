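test_that("odor space distances satisfy the 3-4-5 check and metric axioms", {
  mm <- matrix(0, 3, 6, dimnames = list(c("zero", "threefour", "zero2"),
                                        names(sensillum_types())))
  mm["threefour", c("Da", "Db")] <- c(3, 4)
  cl <- stats::setNames(rep("ester", 3), rownames(mm))
  sp <- build_space(build_response_matrix(records_from_matrix(mm, cl)))
  expect_equal(sp$distance["zero", "threefour"], 5)
  expect_equal(sp$distance["zero", "zero2"], 0)   # identical vectors
  expect_identical(sp$n_pairs, 3L)
  # metric axioms on a random space
  m <- toy_matrix(30, seed = 7)
  d <- build_space(m)$distance
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0))
  # triangle inequality, checked exhaustively over all triples
  viol <- vapply(1:30, function(k)
    max(d - outer(d[, k], d[k, ], "+")), numeric(1))
  expect_lte(max(viol), 1e-9)
})

test_that("a 104-odorant space has 5356 pairs and a missing column errors", {
  sp <- build_space(study_matrix())
  expect_identical(sp$n_pairs, 5356L)
  rec <- data.frame(odorant = rep(c("a", "b"), each = 2), class = "ester",
                    sensillum = rep(c("Da", "Db"), 2), rate = 1:4)
  expect_error(build_space(build_response_matrix(rec)),
               class = "ssr_schema_error")
})

test_that("rank_pairs agrees with a brute-force oracle and breaks ties lexicographically", {
  m <- toy_matrix(12, seed = 3)
  sp <- build_space(m)
  # independent oracle: hand-computed distances over all index pairs
  v <- m$mean
  ids <- rownames(v)
  oracle <- NULL
  for (i in seq_len(nrow(v) - 1)) for (j in seq((i + 1), nrow(v))) {
    oracle <- rbind(oracle, data.frame(
      a = min(ids[i], ids[j]), b = max(ids[i], ids[j]),
      d = sqrt(sum((v[i, ] - v[j, ])^2))))
  }
  oracle <- oracle[order(oracle$d, oracle$a, oracle$b), ]
  got <- rank_pairs(sp, nrow(oracle), "closest")
  expect_equal(got$odorant_a, oracle$a)
  expect_equal(got$distance, oracle$d)
  far <- rank_pairs(sp, 5, "farthest")
  expect_equal(far$distance, utils::tail(oracle$d, 5)[5:1])
  expect_error(rank_pairs(sp, 0), class = "ssr_invalid_parameter")
  expect_error(rank_pairs(sp, sp$n_pairs + 1),
               class = "ssr_invalid_parameter")
})

test_that("all top-10 farthest pairs in the synthetic study share nonanal", {
  far <- rank_pairs(build_space(study_matrix()), 10, "farthest")
  expect_true(all(far$odorant_a == "nonanal" | far$odorant_b == "nonanal"))
})

test_that("UPGMA clustering merges structure correctly", {
  # two items: a single merge at their distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- hcluster(stats::as.dist(d2))
  expect_equal(t2$hclust$height, 3)
  # 4 items in two well-separated pairs: the 2-cluster cut recovers them.
  # Oracle: enumerate all 2-partitions of 4 items, pick the one whose
  # maximum within-cluster distance is smallest.
  pts <- matrix(c(0, 0, 0.4, 0, 10, 0, 10.3, 0), ncol = 2, byrow = TRUE,
                dimnames = list(c("p1", "p2", "q1", "q2"), NULL))
  d <- as.matrix(stats::dist(pts))
  parts <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1),
                c(1, 1, 1, 2), c(1, 1, 2, 1), c(1, 2, 1, 1),
                c(2, 1, 1, 1))
  width <- vapply(parts, function(p) {
    max(vapply(1:2, function(g) {
      sel <- which(p == g)
      if (length(sel) < 2) 0 else max(d[sel, sel])
    }, numeric(1)))
  }, numeric(1))
  best <- parts[[which.min(width)]]
  cut <- cut_tree(hcluster(stats::dist(pts)), 2)
  expect_true(all(outer(cut, cut, "==") == outer(best, best, "==")))
})

test_that("the stereoisomer alcohol pair merges before joining anything else", {
  tree <- hcluster(build_space(study_matrix()))
  h <- tree$hclust
  labs <- h$labels
  i_cis <- which(labs == "cis-2-hexen-1-ol")
  i_trans <- which(labs == "trans-2-hexen-1-ol")
  # find the first merge involving either leaf; it must join the other leaf
  first <- which(apply(h$merge, 1, function(r)
    any(r == -i_cis) || any(r == -i_trans)))[1]
  expect_setequal(h$merge[first, ], c(-i_cis, -i_trans))
})

test_that("average-linkage heights are invariant to input row order", {
  m <- toy_matrix(15, seed = 11)$mean
  h1 <- hcluster(m)$hclust
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(nrow(m))
    h2 <- hcluster(m[perm, ])$hclust
    expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  }
  expect_error(hcluster(matrix(c(0, NA, NA, 0), 2)),
               class = "ssr_invalid_parameter")
})

test_that("newick export round-trips through ape", {
  tree <- hcluster(toy_matrix(8)$mean)
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(toy_matrix(8)$mean))
})

test_that("correlation-matrix PCA fractions behave as eigenvalues / p", {
  m <- toy_matrix(40, seed = 13)
  p <- pca_space(m, n_components = 6)
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-12)
  expect_equal(p$cumulative_pct, 100, tolerance = 1e-9)
  # independent cross-check against prcomp on the standardized data
  pr <- prcomp(m$mean, scale. = TRUE)
  expect_equal(p$variance_explained, pr$sdev^2 / 6, tolerance = 1e-9)
  # orthogonal loadings; scores reproduce the standardized data (Gram)
  expect_equal(crossprod(p$loadings), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  z <- scale(m$mean)
  expect_lt(max(abs(p$scores %*% t(p$loadings) - z)), 1e-9)
})

test_that("a rank-1 response pattern loads almost entirely on PC1", {
  set.seed(21)
  u <- runif(30); v <- runif(6)
  x <- outer(u, v) * 100 + matrix(rnorm(180, 0, 1e-4), 30)
  rownames(x) <- paste0("o", 1:30); colnames(x) <- names(sensillum_types())
  m <- build_response_matrix(records_from_matrix(
    x, stats::setNames(rep("ester", 30), rownames(x))))
  expect_gte(pca_space(m)$variance_explained[1], 0.99)
  # constant column is a named degenerate-column error
  x2 <- x; x2[, "E2"] <- 7
  m2 <- build_response_matrix(records_from_matrix(
    x2, stats::setNames(rep("ester", 30), rownames(x2))))
  expect_error(pca_space(m2), "E2", class = "ssr_degenerate_column")
})

test_that("phasic/tonic index separates kernels and handles edge shapes", {
  flat <- structure(list(counts = rep(10L, 20), rates = rep(100, 20),
                         bin_width = 0.1, window = 2, onset = 0,
                         metadata = list()), class = "psth")
  expect_equal(phasic_tonic_index(flat)$index, 1)
  expect_identical(phasic_tonic_index(flat)$label, "tonic")
  burst <- flat
  burst$counts <- c(30L, rep(0L, 19)); burst$rates <- burst$counts * 10
  expect_equal(phasic_tonic_index(burst)$index, 0)
  expect_identical(phasic_tonic_index(burst)$label, "phasic")
  silent <- flat; silent$rates <- rep(0, 20); silent$counts <- rep(0L, 20)
  expect_error(phasic_tonic_index(silent), class = "ssr_undefined_index")
  # Monte-Carlo ordering: phasic kernel scores below tonic at matched peak
  ph <- phasic_profile(baseline = 5, evoked = 200, tau = 0.15)
  to <- tonic_profile(baseline = 5, evoked = 200)
  idx <- vapply(1:60, function(s) {
    pp <- compute_psth(gen_spike_train(ph, -2, 3, 0.6, seed = s),
                       onset = 0.6)
    pt <- compute_psth(gen_spike_train(to, -2, 3, 0.6, seed = s + 900),
                       onset = 0.6)
    c(phasic_tonic_index(pp)$index, phasic_tonic_index(pt)$index)
  }, numeric(2))
  expect_true(all(idx[1, ] < idx[2, ]))
  expect_lt(mean(idx[1, ]), 0.5)
  expect_gt(mean(idx[2, ]), 0.5)
})

test_that("temporal clustering separates phasic from tonic response shapes", {
  ph <- phasic_profile(baseline = 5, evoked = 180, tau = 0.12)
  to <- tonic_profile(baseline = 5, evoked = 180)
  mk <- function(pr, s) compute_psth(
    gen_spike_train(pr, -2, 3, 0.6, seed = s), onset = 0.6)
  psths <- list(ph1 = mk(ph, 1), ph2 = mk(ph, 2),
                to1 = mk(to, 3), to2 = mk(to, 4))
  # identical PSTHs merge at height zero
  t0 <- temporal_cluster(list(a = psths$ph1, b = psths$ph1))
  expect_equal(t0$hclust$height, 0)
  cut <- cut_tree(temporal_cluster(psths), 2)
  expect_identical(unname(cut["ph1"]), unname(cut["ph2"]))
  expect_identical(unname(cut["to1"]), unname(cut["to2"]))
  expect_false(cut[["ph1"]] == cut[["to1"]])
  bad <- psths
  bad$to2 <- compute_psth(gen_spike_train(to, -2, 3, 0.6, seed = 4),
                          onset = 0.6, bin_width = 0.2)
  expect_error(temporal_cluster(bad), class = "ssr_invalid_parameter")
})

test_that("the synthetic aldehyde panel splits into kernel groups at k = 2", {
  panel <- default_odorant_panel()
  cells <- sensillaR:::expand_archetypes(default_archetypes(), panel)
  ald <- panel$odorant[panel$class == "aldehyde"]
  sel <- cells[cells$sensillum == "Dg" & cells$odorant %in% ald &
                 cells$rate >= 50, ]
  psths <- lapply(seq_len(nrow(sel)), function(i) {
    trs <- lapply(1:8, function(r)
      gen_spike_train(sel$profile[[i]], -2, 3, 0.6, seed = 100 * i + r))
    p <- compute_psth(trs[[1]], onset = 0.6)
    p$counts <- Reduce(`+`, lapply(trs, function(tr)
      compute_psth(tr, onset = 0.6)$counts)) / 8
    p$rates <- p$counts / p$bin_width
    p
  })
  names(psths) <- sel$odorant
  cut <- cut_tree(temporal_cluster(psths), 2)
  expect_identical(unname(length(unique(cut))), 2L)
  agreement <- table(sel$kernel, cut)
  # each kernel maps to one cluster
  expect_true(all(apply(agreement, 1, function(r) sum(r > 0)) == 1))
})
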