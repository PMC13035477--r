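rand_table <- function(n, seed = 1, types = c("B", "T", "FDC")) {
  withr::with_seed(seed, data.frame(
    cell_id = sprintf("c%04d", seq_len(n)),
    x_um = runif(n, 0, 300), y_um = runif(n, 0, 300),
    cell_type = sample(types, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

test_that("transcript QC keeps cells strictly above the threshold", {
  t <- rand_table(3)
  t$total_transcripts <- c(50, 51, 200)
  kept <- qc_filter_cells(t, 50)
  expect_equal(kept$cell_id, t$cell_id[2:3])

  t0 <- t
  t0$total_transcripts <- c(0, 0, 0)
  expect_warning(k0 <- qc_filter_cells(t0, 50), "no cells")
  expect_equal(nrow(k0), 0)

  tt <- rand_table(200, seed = 5)
  tt$total_transcripts <- rpois(200, 55)
  expect_equal(nrow(qc_filter_cells(tt, 50)),
               sum(tt$total_transcripts > 50))
  expect_error(qc_filter_cells(rand_table(5), 50), "total_transcripts")
})

test_that("neighbor composition matches hand counts and brute force", {
  t1 <- rand_table(21)
  t1$cell_type <- "B"
  c1 <- neighbor_composition(t1, k = 20)
  expect_true(all(c1[, "B"] == 1))

  # a center cell whose 20 neighbors are 10 B and 10 T on a ring
  ang <- seq(0, 2 * pi, length.out = 21)[1:20]
  t2 <- data.frame(cell_id = sprintf("c%02d", 0:20),
                   x_um = c(0, 10 * cos(ang)), y_um = c(0, 10 * sin(ang)),
                   cell_type = c("Q", rep(c("B", "T"), 10)))
  c2 <- neighbor_composition(t2, k = 20)
  expect_equal(unname(c2[1, c("B", "T")]), c(0.5, 0.5))

  t3 <- rand_table(300, seed = 6)
  c3 <- neighbor_composition(t3, k = 20)
  expect_equal(unname(c3),
               unname(oracle_knn_composition(cbind(t3$x_um, t3$y_um),
                                             t3$cell_type, 20)))
  expect_true(all(abs(rowSums(c3) - 1) < 1e-12))
  expect_error(neighbor_composition(rand_table(10), k = 20), "at least")
})

test_that("k-means neighborhoods split planted compositions and are seeded", {
  set.seed(3)
  a <- matrix(rep(c(0.9, 0.1, 0), each = 50), 50) +
    matrix(rnorm(150, 0, 0.01), 50)
  b <- matrix(rep(c(0, 0.1, 0.9), each = 50), 50) +
    matrix(rnorm(150, 0, 0.01), 50)
  comp <- abs(rbind(a, b))
  colnames(comp) <- c("B", "T", "FDC")
  km <- cluster_neighborhoods(comp, 2, seed = 1)
  expect_equal(ari(km$labels, rep(c("a", "b"), each = 50)), 1.0)
  km2 <- cluster_neighborhoods(comp, 2, seed = 1)
  expect_identical(km$labels, km2$labels)
  expect_true(is.finite(km$inertia))

  ident <- matrix(0.5, 10, 2)
  expect_equal(length(unique(cluster_neighborhoods(ident, 1,
                                                   seed = 1)$labels)), 1)
  expect_error(cluster_neighborhoods(ident, 20, seed = 1), "fewer rows")
})

test_that("similar clusters merge transitively by centroid correlation", {
  comp <- rbind(
    matrix(rep(c(0.8, 0.15, 0.05), each = 20), 20),
    matrix(rep(c(0.78, 0.17, 0.05), each = 20), 20),
    matrix(rep(c(0.05, 0.15, 0.8), each = 20), 20))
  colnames(comp) <- c("B", "T", "FDC")
  labels <- rep(1:3, each = 20)
  mg <- merge_similar_clusters(labels, comp, 0.9)
  expect_equal(length(unique(mg$labels)), 2)
  expect_equal(length(unique(mg$labels[1:40])), 1)

  # identical centroids always merge; orthogonal never do
  mg_id <- merge_similar_clusters(rep(1:2, each = 10),
                                  matrix(0.5, 20, 2), 0.9)
  expect_equal(length(unique(mg_id$labels)), 1)
  orth <- rbind(matrix(rep(c(1, 0), each = 10), 10),
                matrix(rep(c(0, 1), each = 10), 10))
  mg_or <- merge_similar_clusters(rep(1:2, each = 10), orth, 0.9)
  expect_equal(length(unique(mg_or$labels)), 2)

  # hand-worked chain: cor(v1,v2)=.954, cor(v2,v3)=.931, cor(v1,v3)=.777.
  # v1-v2 merge first (highest correlation); the recomputed centroid
  # (v1+v2)/2 correlates .858 with v3, below the 0.9 threshold, so the
  # chain does not propagate and two clusters remain.
  v1 <- c(0.5, 0.3, 0.15, 0.05)
  v3 <- c(0.33, 0.42, 0.2, 0.05)
  v2 <- (v1 + v3) / 2
  stopifnot(cor(v1, v2) >= 0.9, cor(v2, v3) >= 0.9, cor(v1, v3) < 0.9)
  comp3 <- rbind(matrix(v1, 10, 4, byrow = TRUE),
                 matrix(v2, 10, 4, byrow = TRUE),
                 matrix(v3, 10, 4, byrow = TRUE))
  mg3 <- merge_similar_clusters(rep(1:3, each = 10), comp3, 0.9)
  expect_equal(length(unique(mg3$labels)), 2)
  expect_equal(length(unique(mg3$labels[1:20])), 1)
})

test_that("enrichment odds ratios and Fisher p match hand arithmetic", {
  # type A: 30/50 in-neighborhood, 10/50 outside -> OR 6
  t <- data.frame(cell_id = sprintf("c%03d", 1:100),
                  x_um = 0, y_um = 0,
                  cell_type = c(rep("A", 30), rep("Z", 20),
                                rep("A", 10), rep("Z", 40)))
  labels <- rep(c("N1", "N2"), each = 50)
  enr <- enrichment_matrix(labels, t)
  a_n1 <- enr[enr$neighborhood == "N1" & enr$cell_type == "A", ]
  expect_equal(a_n1$log2_or, log2(6), tolerance = 1e-12)
  expect_equal(a_n1$p, oracle_fisher_p(30, 20, 10, 40), tolerance = 1e-10)

  # uniform type -> OR 1, log2 0
  tu <- t
  tu$cell_type <- rep(c("A", "Z"), 50)
  enru <- enrichment_matrix(labels, tu)
  expect_equal(enru$log2_or[enru$cell_type == "A"], c(0, 0),
               tolerance = 1e-12)

  # BH monotonicity: adjusted p non-decreasing in raw-p order
  set.seed(11)
  tr <- rand_table(120, seed = 8, types = c("A", "B", "C", "D"))
  lab <- sample(c("N1", "N2", "N3"), 120, replace = TRUE)
  er <- enrichment_matrix(lab, tr)
  ord <- order(er$p)
  expect_true(all(diff(er$p_adj[ord]) >= -1e-12))
  for (i in seq_len(nrow(er)))
    expect_equal(er$p[i], do.call(oracle_fisher_p, as.list(
      lymphochemnet:::enrichment_counts(lab, tr$cell_type,
                                        er$neighborhood[i],
                                        er$cell_type[i]))),
      tolerance = 1e-10)
})

test_that("Otsu threshold maximizes between-class variance", {
  v <- c(1, 1, 1, 10, 10, 10)
  o <- otsu_positivity(v)
  expect_gt(o$threshold, 1)
  expect_lt(o$threshold, 10)
  expect_equal(sum(o$positive), 3)
  expect_error(otsu_positivity(rep(2, 5)), "distinct")

  set.seed(12)
  for (i in 1:20) {
    vv <- c(rlnorm(80, 1, 0.5), rlnorm(40, 4, 0.5))
    got <- otsu_positivity(vv)$threshold
    expect_equal(got, oracle_otsu(vv), tolerance = 1e-9)
  }

  # bimodal recovery: threshold between component medians
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    vv <- c(rlnorm(150, 1, 0.5), rlnorm(150, 4, 0.5))
    thr <- otsu_positivity(vv)$threshold
    if (thr > exp(1) && thr < exp(4)) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("spatial L-R proximity counts pairs in either orientation", {
  t <- data.frame(cell_id = c("a", "b", "c"),
                  x_um = c(0, 10, 50), y_um = 0,
                  cell_type = "X")
  lp <- c(TRUE, FALSE, FALSE)
  rp <- c(FALSE, TRUE, TRUE)
  sc <- lr_proximity_score(t, lp, rp, radius_um = 20)
  expect_equal(unname(sc), c(1, 1, 0))

  expect_equal(unname(lr_proximity_score(t, rep(FALSE, 3), rp, 20)),
               c(0, 0, 0))
  expect_error(lr_proximity_score(t, lp, rp, radius_um = -1), "positive")

  set.seed(13)
  tr <- rand_table(200, seed = 9)
  lpos <- runif(200) < 0.3
  rpos <- runif(200) < 0.3
  got <- lr_proximity_score(tr, lpos, rpos, 25)
  want <- oracle_lr_score(cbind(tr$x_um, tr$y_um), lpos, rpos, 25)
  expect_equal(unname(got), want)

  # rigid motion invariance
  th <- 0.7
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  xy2 <- cbind(tr$x_um, tr$y_um) %*% rot + 55
  tr2 <- tr
  tr2$x_um <- xy2[, 1]; tr2$y_um <- xy2[, 2]
  expect_equal(lr_proximity_score(tr2, lpos, rpos, 25), got)

  # radius below the minimal pairwise distance gives all zeros
  dmin <- min(dist(cbind(tr$x_um, tr$y_um)))
  expect_true(all(lr_proximity_score(tr, lpos, rpos, dmin * 0.9) == 0))
})

test_that("KDE densities and attraction test behave as planted", {
  # closed form at a single reference point
  h <- 12
  expect_equal(kde2d_at(cbind(3, 4), cbind(3, 4), h), 1 / (2 * pi * h^2),
               tolerance = 1e-12)

  # planted attraction: targets packed around ligand-positive senders
  set.seed(14)
  n_pos <- 40
  pos_xy <- cbind(runif(n_pos, 0, 500), runif(n_pos, 0, 500))
  neg_xy <- cbind(runif(60, 0, 500), runif(60, 0, 500))
  anchors <- pos_xy[sample(n_pos, 200, replace = TRUE), ]
  targets <- anchors + matrix(rnorm(400, 0, 8), ncol = 2)
  res <- kde_attraction_test(targets, rbind(pos_xy, neg_xy),
                             c(rep(TRUE, n_pos), rep(FALSE, 60)))
  expect_gt(res$median_pos, res$median_neg)
  expect_lt(res$p_value, 0.01)

  expect_error(kde_attraction_test(targets[1:3, ], pos_xy,
                                   rep(TRUE, n_pos)), "at least 5")
  expect_error(kde_attraction_test(targets, pos_xy, rep(TRUE, n_pos)),
               "both ligand")
})
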