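## blockwise cosine kNN on a coordinate matrix; returns n x k neighbor indices
cosine_knn <- function(x, k, block = 1024L) {
  n <- nrow(x)
  norms <- sqrt(rowSums(x^2))
  norms[norms == 0] <- 1e-12
  xn <- x / norms
  out <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    sim <- xn[idx, , drop = FALSE] %*% t(xn)
    ## exclude self before selection
    sim[cbind(seq_along(idx), idx)] <- -Inf
    out[idx, ] <- .top_k_rows(sim, k, TRUE)
  }
  out
}

#' Embed a pair feature matrix
#'
#' Treats the geometric-mean ligand-receptor scores as features: principal
#' component analysis (centered, not re-scaled) to `n_pcs` components,
#' followed by a cosine k-nearest-neighbor graph on the PC coordinates and,
#' optionally, a 2-D force-directed layout of that graph for visualization.
#' `n_pcs` is clamped to `min(n_pcs, ncol - 1, nrow - 1)` when the matrix is
#' narrower than requested.
#'
#' @param pm a filtered `pair_matrix` (see [filter_pairs()]).
#' @param cfg an [analysis_config()]; uses `n_pcs`, `knn`, `seed`.
#' @param build_graph logical; skip the kNN graph (and layout) when only PC
#'   coordinates are needed, e.g. for the diffuseness score.
#' @param layout `"fr"` for a Fruchterman-Reingold layout of the kNN graph,
#'   `"none"` to skip.
#' @return An object of class `pair_embedding`: list with `pc_coords`,
#'   `knn_idx`, `graph` (igraph or NULL), `coords_2d` (or NULL), `pairs`
#'   (the pair id table), `cluster` (NULL until [cluster_pairs()]),
#'   `zone` (NULL until [annotate_clusters()]), and the source `scores`.
#' @export
embed_pairs <- function(pm, cfg = analysis_config(), build_graph = TRUE,
                        layout = c("fr", "none")) {
  stopifnot(inherits(pm, "pair_matrix"))
  layout <- match.arg(layout)
  n <- nrow(pm$scores)
  n_pcs <- min(cfg$n_pcs, ncol(pm$scores))
  if (n < n_pcs + 1)
    stop("only ", n, " pair rows; need at least n_pcs + 1 = ",
         n_pcs + 1, " (reduce n_pcs)")
  if (n_pcs < cfg$n_pcs)
    message("n_pcs reduced to ", n_pcs, " (matrix has ",
            ncol(pm$scores), " columns)")
  pca <- prcomp(pm$scores, center = TRUE, scale. = FALSE, rank. = n_pcs)
  pc <- pca$x

  knn_idx <- NULL
  graph <- NULL
  coords_2d <- NULL
  if (build_graph) {
    k <- min(cfg$knn, n - 1L)
    knn_idx <- cosine_knn(pc, k)
    edges <- cbind(rep(seq_len(n), each = k), as.vector(t(knn_idx)))
    graph <- igraph::graph_from_edgelist(edges, directed = FALSE)
    graph <- igraph::simplify(graph)
    if (layout == "fr") {
      coords_2d <- withr::with_seed(cfg$seed,
        igraph::layout_with_fr(graph))
      dimnames(coords_2d) <- list(NULL, c("dim1", "dim2"))
    }
  }
  structure(list(pc_coords = pc, knn_idx = knn_idx, graph = graph,
                 coords_2d = coords_2d, pairs = pm$pairs,
                 scores = pm$scores, rotation = pca$rotation,
                 cluster = NULL, zone = NULL, cfg = cfg),
            class = "pair_embedding")
}

#' @export
print.pair_embedding <- function(x, ...) {
  cat(sprintf("<pair_embedding> %d pairs, %d PCs%s%s\n",
              nrow(x$pc_coords), ncol(x$pc_coords),
              if (!is.null(x$graph)) ", kNN graph" else "",
              if (!is.null(x$cluster))
                sprintf(", %d clusters", nlevels(x$cluster)) else ""))
  invisible(x)
}

#' Cluster cell pairs on the kNN graph
#'
#' Modularity-based community detection (multilevel/Louvain) on the cosine
#' kNN graph of the pair embedding. Labels are deterministic for a fixed
#' seed.
#'
#' @param emb a [embed_pairs()] result with a graph.
#' @param resolution modularity resolution; smaller values give fewer
#'   clusters (values near 0 give one).
#' @param seed integer seed.
#' @return The embedding with `cluster` filled (factor, one label per pair).
#' @export
cluster_pairs <- function(emb, resolution = 1, seed = 1) {
  stopifnot(inherits(emb, "pair_embedding"))
  if (is.null(emb$graph))
    stop("embedding has no kNN graph; rerun embed_pairs(build_graph = TRUE)")
  comm <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(emb$graph, resolution = resolution))
  emb$cluster <- factor(igraph::membership(comm))
  emb
}

#' Sender and receiver cell-type composition per pair cluster
#'
#' For each cluster, the frequency of each cell type among senders and among
#' receivers. A display filter drops, per cluster and role, contributions
#' below the given percentile of the nonzero frequencies; the full table is
#' always returned.
#'
#' @param emb a clustered [pair_embedding()].
#' @param cells cell annotation data.frame (`cell_id`, `cell_type`).
#' @param display_percentile percentile (0-100) below which contributions are
#'   hidden in the `displayed` flag (default 50).
#' @return A data.frame (`cluster`, `role`, `cell_type`, `freq`,
#'   `displayed`); `freq` sums to 1 per cluster and role.
#' @export
summarize_composition <- function(emb, cells, display_percentile = 50) {
  stopifnot(inherits(emb, "pair_embedding"))
  if (is.null(emb$cluster)) stop("run cluster_pairs first")
  type_of <- setNames(cells$cell_type, cells$cell_id)
  unknown <- setdiff(unique(c(emb$pairs$sender, emb$pairs$receiver)),
                     names(type_of))
  if (length(unknown))
    stop("cell ids missing from annotation: ",
         paste(head(unknown, 5), collapse = ", "))
  res <- list()
  for (cl in levels(emb$cluster)) {
    in_cl <- emb$cluster == cl
    for (role in c("sender", "receiver")) {
      tt <- table(type_of[emb$pairs[[role]][in_cl]])
      freq <- as.numeric(tt) / sum(tt)
      cutoff <- stats::quantile(freq[freq > 0], display_percentile / 100,
                                names = FALSE)
      res[[length(res) + 1]] <- data.frame(
        cluster = cl, role = role, cell_type = names(tt), freq = freq,
        displayed = freq >= cutoff, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## zone label of a ligand-receptor pair id
lr_zone_of <- function(lr_id) {
  ligand <- sub("_.*$", "", lr_id)
  if (ligand == "CXCL13") "follicle"
  else if (ligand %in% c("CCL19", "CCL21")) "t_zone"
  else if (ligand %in% c("CXCL9", "CXCL10", "CXCL11")) "inflammatory"
  else "other"
}

#' Annotate pair clusters by their dominant ligand-receptor axis
#'
#' Labels each cluster with its top mean-scoring ligand-receptor column and
#' the tissue zone that axis defines: CXCL13-CXCR5 marks follicle-like
#' clusters, CCL19/CCL21-CCR7 T-zone-like, CXCL9/10/11-CXCR3 inflammatory;
#' anything else is `other`, and clusters with all-zero mean scores are
#' `unassigned`. Ties are broken lexicographically (logged via message).
#'
#' @param emb a clustered [pair_embedding()].
#' @return The embedding with `zone` filled: data.frame (`cluster`,
#'   `top_lr`, `zone`).
#' @export
annotate_clusters <- function(emb) {
  stopifnot(inherits(emb, "pair_embedding"))
  if (is.null(emb$cluster)) stop("run cluster_pairs first")
  res <- lapply(levels(emb$cluster), function(cl) {
    mu <- colMeans(emb$scores[emb$cluster == cl, , drop = FALSE])
    if (all(mu == 0))
      return(data.frame(cluster = cl, top_lr = NA_character_,
                        zone = "unassigned", stringsAsFactors = FALSE))
    top <- names(mu)[mu == max(mu)]
    if (length(top) > 1) {
      top <- sort(top)
      message("annotate_clusters: tie in cluster ", cl, " between ",
              paste(top, collapse = ", "), "; using ", top[1])
    }
    data.frame(cluster = cl, top_lr = top[1], zone = lr_zone_of(top[1]),
               stringsAsFactors = FALSE)
  })
  emb$zone <- do.call(rbind, res)
  emb
}

#' Diffuseness score of chemokine interaction profiles
#'
#' Quantifies heterogeneity of cell-pair attraction profiles as the mean
#' Euclidean distance between pair feature vectors in principal-component
#' space, after randomly downsampling each group's pairs to `fraction` of
#' their original number. Scores are computed per patient/sample and reported
#' with the grouping entity; identical vectors give 0, and the score scales
#' linearly with the coordinates.
#'
#' @param emb a [pair_embedding()] (PC coordinates are used).
#' @param patient character vector, one label per pair row; defaults to the
#'   pair table's `sample_id`.
#' @param entity optional entity label per pair row (recycled into the
#'   output).
#' @param fraction downsampling fraction in (0, 1] (default 0.3).
#' @param seed integer seed for the downsampling draw.
#' @return A data.frame (`patient`, `entity`, `n_used`, `score`); groups left
#'   with fewer than 2 pairs are skipped with a warning.
#' @export
diffuseness <- function(emb, patient = NULL, entity = NULL, fraction = 0.3,
                        seed = 1) {
  stopifnot(inherits(emb, "pair_embedding"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (is.null(patient)) patient <- emb$pairs$sample_id
  if (is.null(entity)) entity <- NA_character_
  entity <- rep(entity, length.out = length(patient))
  stopifnot(length(patient) == nrow(emb$pc_coords))
  ent_of <- tapply(as.character(entity), patient, function(v) v[1])
  withr::with_seed(as.integer(seed), {
    res <- lapply(unique(patient), function(p) {
      idx <- which(patient == p)
      m <- max(2L, ceiling(fraction * length(idx)))
      if (length(idx) < 2 || m < 2) {
        warning("group ", p, " has fewer than 2 pairs after downsampling; skipped")
        return(NULL)
      }
      use <- if (m < length(idx)) sample(idx, m) else idx
      data.frame(patient = p, entity = ent_of[[p]], n_used = length(use),
                 score = .mean_pairwise_dist(emb$pc_coords[use, , drop = FALSE]),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Entity contribution per pair cluster
#'
#' The share of each disease entity in each cluster, normalized by entity
#' totals so that differently sized entities are comparable: raw per-cluster
#' counts are divided by the entity's total pair count, then rescaled to sum
#' to 1 within the cluster.
#'
#' @param emb a clustered [pair_embedding()].
#' @param entity entity label per pair row.
#' @return A matrix, clusters x entities, rows summing to 1.
#' @export
entity_contribution <- function(emb, entity) {
  stopifnot(inherits(emb, "pair_embedding"))
  if (is.null(emb$cluster)) stop("run cluster_pairs first")
  stopifnot(length(entity) == nrow(emb$pc_coords))
  tab <- table(emb$cluster, entity)
  totals <- colSums(tab)
  norm <- sweep(unclass(tab), 2, totals, "/")
  out <- norm / rowSums(norm)
  out[rowSums(norm) == 0, ] <- 0
  out
}

#' Concordance of in silico interaction composition with spatial neighborhoods
#'
#' Compares, for each tissue-zone label shared between annotated pair
#' clusters and annotated spatial neighborhoods, the cell-type frequency
#' vector of the pair clusters (senders and receivers pooled) with the
#' composition of the matching neighborhood. Vectors are aligned on the union
#' of cell types, min-max scaled, and summarized by their Pearson
#' correlation.
#'
#' @param composition output of [summarize_composition()].
#' @param cluster_zones `zone` table of an annotated embedding
#'   (see [annotate_clusters()]).
#' @param nhood_composition matrix of spatial neighborhood centroids
#'   (neighborhoods x cell types), e.g. `centroids` from
#'   [merge_similar_clusters()].
#' @param nhood_zones named character vector mapping neighborhood labels to
#'   zone labels.
#' @param scaling `"minmax"` (default) or `"z"`.
#' @return A data.frame (`zone`, `correlation`, `n_types`); unmatched zone
#'   labels are reported in `attr(, "unmatched")`.
#' @export
concordance_with_spatial <- function(composition, cluster_zones,
                                     nhood_composition, nhood_zones,
                                     scaling = c("minmax", "z")) {
  scaling <- match.arg(scaling)
  shared <- intersect(unique(cluster_zones$zone), unique(nhood_zones))
  shared <- setdiff(shared, c("unassigned", "other"))
  if (!length(shared))
    stop("no shared zone labels between pair clusters and neighborhoods")
  unmatched <- union(setdiff(cluster_zones$zone, shared),
                     setdiff(nhood_zones, shared))
  scale_vec <- function(v) {
    if (scaling == "minmax") {
      rng <- range(v)
      if (diff(rng) == 0) return(rep(0, length(v)))
      (v - rng[1]) / diff(rng)
    } else {
      if (sd(v) == 0) return(rep(0, length(v)))
      (v - mean(v)) / sd(v)
    }
  }
  res <- lapply(shared, function(z) {
    cls <- cluster_zones$cluster[cluster_zones$zone == z]
    sub <- composition[composition$cluster %in% cls, , drop = FALSE]
    pair_freq <- tapply(sub$freq, sub$cell_type, mean)
    nh <- which(nhood_zones == z)
    nh_freq <- colMeans(nhood_composition[names(nhood_zones)[nh], ,
                                          drop = FALSE])
    types <- union(names(pair_freq), names(nh_freq))
    a <- setNames(rep(0, length(types)), types)
    b <- a
    a[names(pair_freq)] <- pair_freq
    b[names(nh_freq)] <- nh_freq
    data.frame(zone = z, correlation = cor(scale_vec(a), scale_vec(b)),
               n_types = length(types), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "unmatched") <- unmatched
  out
}
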