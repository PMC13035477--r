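toy_pm <- function(m, sample_id = "s1") {
  lymphochemnet:::pair_matrix(
    m, data.frame(sender = sprintf("snd%03d", seq_len(nrow(m))),
                  receiver = sprintf("rcv%03d", seq_len(nrow(m))),
                  sample_id = sample_id))
}

test_that("embedding reproduces exact low-rank structure and duplicates", {
  set.seed(2)
  base <- matrix(runif(2 * 6), 2, 6)
  coef <- matrix(runif(40 * 2), 40, 2)
  m <- abs(coef %*% base)
  colnames(m) <- paste0("lr", 1:6)
  emb <- suppressMessages(embed_pairs(toy_pm(m),
                                      analysis_config(n_pcs = 2, knn = 5)))
  center <- colMeans(m)
  recon <- emb$pc_coords %*% t(emb$rotation) +
    matrix(center, nrow(m), ncol(m), byrow = TRUE)
  expect_equal(unname(recon), unname(m), tolerance = 1e-9)

  m2 <- rbind(m, m[1, , drop = FALSE])
  emb2 <- suppressMessages(embed_pairs(toy_pm(m2),
                                       analysis_config(n_pcs = 2, knn = 5)))
  expect_equal(emb2$pc_coords[41, ], emb2$pc_coords[1, ], tolerance = 1e-12)

  expect_error(suppressMessages(
    embed_pairs(toy_pm(m[1:2, , drop = FALSE]),
                analysis_config(n_pcs = 2, knn = 5))), "n_pcs")
})

test_that("first PC separates two planted pair programs", {
  pl <- make_planted_pairs(n_per = 250, seed = 21)
  emb <- suppressMessages(embed_pairs(pl$pm, analysis_config(),
                                      build_graph = FALSE))
  a <- auc_of(emb$pc_coords[, 1], pl$labels == "follicle")
  expect_gt(max(a, 1 - a), 0.95)
})

test_that("cluster_pairs recovers planted programs and degenerate cases", {
  pl <- make_planted_pairs(n_per = 200, seed = 22)
  emb <- suppressMessages(embed_pairs(pl$pm, analysis_config()))
  emb <- cluster_pairs(emb, resolution = 0.2, seed = 1)
  expect_gte(nlevels(emb$cluster), 2)
  expect_gte(ari(emb$cluster, pl$labels), 0.8)
  # stable under the same seed
  emb_b <- cluster_pairs(emb, resolution = 0.2, seed = 1)
  expect_identical(emb$cluster, emb_b$cluster)
  # resolution -> 0 collapses a connected graph to a single cluster
  set.seed(99)
  blob <- matrix(abs(rnorm(120 * 6, 1, 0.3)), 120, 6,
                 dimnames = list(NULL, paste0("lr", 1:6)))
  embb <- suppressMessages(embed_pairs(toy_pm(blob),
                                       analysis_config(n_pcs = 5, knn = 10)))
  emb0 <- cluster_pairs(embb, resolution = 1e-4, seed = 1)
  expect_equal(nlevels(emb0$cluster), 1)

  ident <- matrix(1, 40, 5, dimnames = list(NULL, paste0("lr", 1:5)))
  embi <- suppressMessages(embed_pairs(toy_pm(ident),
                                       analysis_config(n_pcs = 2, knn = 5)))
  embi <- cluster_pairs(embi, seed = 1)
  expect_equal(nlevels(embi$cluster), 1)
})

test_that("composition tables normalize per role and respect annotations", {
  pl <- make_planted_pairs(n_per = 100, seed = 23)
  emb <- suppressMessages(embed_pairs(pl$pm, analysis_config()))
  emb <- cluster_pairs(emb, resolution = 0.2, seed = 1)
  cells <- data.frame(
    cell_id = c(pl$pm$pairs$sender, pl$pm$pairs$receiver),
    cell_type = rep(c("FDC", "B"), each = nrow(pl$pm$pairs)))
  comp <- summarize_composition(emb, cells)
  sums <- aggregate(freq ~ cluster + role, comp, sum)
  expect_true(all(abs(sums$freq - 1) < 1e-9))
  snd <- comp[comp$role == "sender", ]
  expect_true(all(snd$cell_type == "FDC" | snd$freq == 0))

  expect_error(summarize_composition(emb, cells[1:3, ]), "missing")
})

test_that("cluster annotation follows the dominant ligand-receptor axis", {
  reg_cols <- lr_pair_ids(lr_registry())
  m <- matrix(0.1, 60, length(reg_cols), dimnames = list(NULL, reg_cols))
  m[1:20, "CXCL13_CXCR5"] <- 3
  m[21:40, "CCL19_CCR7"] <- 3
  m[41:60, "CXCL9_CXCR3"] <- 3
  emb <- suppressMessages(embed_pairs(toy_pm(m), analysis_config(knn = 10)))
  emb$cluster <- factor(rep(c(1, 2, 3), each = 20))
  emb <- annotate_clusters(emb)
  expect_equal(emb$zone$zone, c("follicle", "t_zone", "inflammatory"))

  embz <- emb
  embz$scores <- matrix(0, 60, length(reg_cols),
                        dimnames = list(NULL, reg_cols))
  embz <- annotate_clusters(embz)
  expect_true(all(embz$zone$zone == "unassigned"))

  # deterministic lexicographic tie-break
  embt <- emb
  embt$scores[] <- 0
  embt$scores[1:20, c("CCL21_CCR7", "CCL19_CCR7")] <- 1
  expect_message(embt <- annotate_clusters(embt), "tie")
  expect_equal(embt$zone$top_lr[1], "CCL19_CCR7")
})

test_that("diffuseness matches closed forms and the brute-force oracle", {
  # identical vectors -> 0
  m <- matrix(1, 30, 5, dimnames = list(NULL, paste0("lr", 1:5)))
  emb <- suppressMessages(embed_pairs(toy_pm(m), analysis_config(n_pcs = 2),
                                      build_graph = FALSE))
  d0 <- diffuseness(emb, fraction = 1, seed = 1)
  expect_equal(d0$score, 0)

  # 3-4-5 triangle
  emb2 <- emb
  emb2$pc_coords <- rbind(c(0, 0), c(3, 4))
  emb2$pairs <- emb$pairs[1:2, ]
  d2 <- diffuseness(emb2, fraction = 1, seed = 1)
  expect_equal(d2$score, 5)

  # oracle on 200 x 20 standard normals
  set.seed(30)
  x <- matrix(rnorm(200 * 20), 200, 20)
  emb3 <- emb
  emb3$pc_coords <- x
  emb3$pairs <- data.frame(sender = paste0("s", 1:200),
                           receiver = paste0("r", 1:200), sample_id = "p1")
  d3 <- diffuseness(emb3, fraction = 1, seed = 1)
  expect_equal(d3$score, oracle_mean_dist(x), tolerance = 1e-9)

  # translation invariance and linear scaling
  emb4 <- emb3
  emb4$pc_coords <- x + 100
  expect_equal(diffuseness(emb4, fraction = 1, seed = 1)$score, d3$score,
               tolerance = 1e-9)
  emb5 <- emb3
  emb5$pc_coords <- 2.5 * x
  expect_equal(diffuseness(emb5, fraction = 1, seed = 1)$score,
               2.5 * d3$score, tolerance = 1e-9)

  # deterministic downsampling, per-patient grouping
  emb3$pairs$sample_id <- rep(c("p1", "p2"), each = 100)
  da <- diffuseness(emb3, fraction = 0.3, seed = 4)
  db <- diffuseness(emb3, fraction = 0.3, seed = 4)
  expect_identical(da, db)
  expect_equal(da$patient, c("p1", "p2"))
  expect_equal(da$n_used, c(30, 30))
})

test_that("entity contributions are normalized by entity totals", {
  m <- matrix(runif(60 * 3), 60, 3, dimnames = list(NULL, paste0("lr", 1:3)))
  emb <- suppressMessages(embed_pairs(toy_pm(m),
                                      analysis_config(n_pcs = 2, knn = 5)))
  # entity A has 40 pairs overall, B has 20; cluster 1 has 10 of each
  entity <- c(rep("A", 40), rep("B", 20))
  emb$cluster <- factor(c(rep(1, 10), rep(2, 30), rep(1, 10), rep(2, 10)))
  ec <- entity_contribution(emb, entity)
  # hand computation: cluster1 normalized shares (10/40, 10/20) -> (1/3, 2/3)
  expect_equal(unname(ec["1", ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(rowSums(ec)), c(1, 1), tolerance = 1e-12)

  # single-entity cluster
  emb$cluster <- factor(c(rep(1, 40), rep(2, 20)))
  ec2 <- entity_contribution(emb, entity)
  expect_equal(unname(ec2["1", "A"]), 1)
})

test_that("spatial concordance behaves on identical and orthogonal vectors", {
  composition <- data.frame(
    cluster = "1", role = "sender",
    cell_type = c("B", "FDC", "T_FH"),
    freq = c(0.6, 0.3, 0.1), displayed = TRUE)
  zones <- data.frame(cluster = "1", top_lr = "CXCL13_CXCR5",
                      zone = "follicle")
  nh_comp <- matrix(c(0.6, 0.3, 0.1), 1,
                    dimnames = list("N1", c("B", "FDC", "T_FH")))
  conc <- concordance_with_spatial(composition, zones, nh_comp,
                                   c(N1 = "follicle"))
  expect_equal(conc$correlation, 1, tolerance = 1e-12)

  nh_orth <- matrix(c(0, 0, 1), 1,
                    dimnames = list("N1", c("B", "FDC", "T_FH")))
  conc2 <- concordance_with_spatial(composition, zones, nh_orth,
                                    c(N1 = "follicle"))
  expect_lt(conc2$correlation, 0)

  expect_error(concordance_with_spatial(composition, zones, nh_comp,
                                        c(N1 = "t_zone")), "no shared")
})
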