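## validate the minimal spatial table contract
check_spatial <- function(t) {
  req <- c("cell_id", "x_um", "y_um", "cell_type")
  miss <- setdiff(req, names(t))
  if (length(miss))
    stop("spatial table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(t$x_um)) || !all(is.finite(t$y_um)))
    stop("coordinates must be finite")
  invisible(t)
}

#' Transcript-count quality filter
#'
#' Keeps cells with strictly more than `min_transcripts` total transcripts,
#' the standard QC rule for in situ transcriptomic panels.
#'
#' @param t spatial cell table with a `total_transcripts` column.
#' @param min_transcripts strict lower bound (default 50).
#' @return The filtered table; warns when nothing survives.
#' @export
qc_filter_cells <- function(t, min_transcripts = 50L) {
  check_spatial(t)
  if (is.null(t$total_transcripts))
    stop("total_transcripts column required for QC filtering")
  keep <- t$total_transcripts > min_transcripts
  if (!any(keep)) warning("no cells pass the transcript filter")
  t[keep, , drop = FALSE]
}

#' Neighbor cell-type composition
#'
#' For every cell, the cell-type frequency vector of its `k` nearest
#' neighbors by Euclidean distance in the section plane (self excluded;
#' distance ties broken by cell order). These composition vectors are the
#' features for neighborhood detection.
#'
#' @param t spatial cell table.
#' @param k neighbors per cell (default 20).
#' @return A numeric matrix, cells x cell types, rows summing to 1; row
#'   names are cell ids.
#' @export
neighbor_composition <- function(t, k = 20L) {
  check_spatial(t)
  n <- nrow(t)
  if (n < k + 1)
    stop("need at least k + 1 = ", k + 1, " cells, got ", n)
  nn <- .knn_points(cbind(t$x_um, t$y_um), as.integer(k))
  types <- sort(unique(t$cell_type))
  type_idx <- match(t$cell_type, types)
  comp <- matrix(0, nrow = n, ncol = length(types),
                 dimnames = list(t$cell_id, types))
  for (j in seq_len(k)) {
    tj <- type_idx[nn[, j]]
    comp[cbind(seq_len(n), tj)] <- comp[cbind(seq_len(n), tj)] + 1
  }
  comp / k
}

#' Cluster composition vectors with k-means
#'
#' Unsupervised grouping of neighbor-composition vectors into `k_clusters`
#' raw neighborhoods (k-means with `nstart` restarts under a fixed seed).
#'
#' @param comp composition matrix from [neighbor_composition()].
#' @param k_clusters number of clusters (default 20).
#' @param seed integer seed.
#' @param nstart random restarts (default 5).
#' @param iter_max maximum iterations (default 50).
#' @return A list with `labels` (integer per cell), `centers` and `inertia`
#'   (total within-cluster sum of squares).
#' @export
cluster_neighborhoods <- function(comp, k_clusters = 20L, seed = 1,
                                  nstart = 5L, iter_max = 50L) {
  if (nrow(comp) < k_clusters)
    stop("fewer rows (", nrow(comp), ") than clusters (", k_clusters, ")")
  km <- withr::with_seed(as.integer(seed),
    kmeans(comp, centers = k_clusters, nstart = nstart,
           iter.max = iter_max))
  list(labels = km$cluster, centers = km$centers,
       inertia = km$tot.withinss)
}

#' Merge raw clusters with similar composition
#'
#' Agglomerative binning of redundant k-means clusters: while any two
#' cluster centroids have Pearson correlation at or above the threshold, the
#' most correlated pair is merged (centroids recomputed as cell-weighted
#' means) until a fixed point. Clusters with constant centroids merge only
#' when identical.
#'
#' The default threshold of 0.75 tolerates the sampling noise of k-nearest-
#' neighbor composition vectors (with k around 20, same-microdomain
#' subclusters typically correlate between about 0.6 and 0.97, while
#' centroids of distinct microdomains stay below about 0.5).
#'
#' @param labels raw cluster labels from [cluster_neighborhoods()].
#' @param comp the composition matrix the labels were fit on.
#' @param similarity_threshold centroid correlation needed to merge
#'   (default 0.75).
#' @return A list with `labels` (merged labels `"N1"`, `"N2"`, ... per
#'   cell, ordered by decreasing size), `mapping` (raw label -> merged
#'   label) and `centroids` (merged composition means).
#' @export
merge_similar_clusters <- function(labels, comp,
                                   similarity_threshold = 0.75) {
  groups <- split(seq_along(labels), labels)
  centroid <- function(ix) colMeans(comp[ix, , drop = FALSE])
  cents <- lapply(groups, centroid)
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0)
      return(if (isTRUE(all.equal(a, b))) 1 else -Inf)
    cor(a, b)
  }
  repeat {
    ng <- length(groups)
    if (ng < 2) break
    best <- c(0, 0)
    best_cor <- -Inf
    for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
      cc <- safe_cor(cents[[i]], cents[[j]])
      if (cc > best_cor) { best_cor <- cc; best <- c(i, j) }
    }
    if (best_cor < similarity_threshold) break
    i <- best[1]; j <- best[2]
    groups[[i]] <- c(groups[[i]], groups[[j]])
    cents[[i]] <- centroid(groups[[i]])
    groups[[j]] <- NULL
    cents[[j]] <- NULL
  }
  ord <- order(vapply(groups, length, integer(1)), decreasing = TRUE)
  groups <- groups[ord]
  cents <- cents[ord]
  merged_names <- paste0("N", seq_along(groups))
  out <- character(length(labels))
  mapping <- list()
  for (g in seq_along(groups)) {
    out[groups[[g]]] <- merged_names[g]
    mapping[[merged_names[g]]] <-
      sort(unique(as.character(labels[groups[[g]]])))
  }
  centroids <- do.call(rbind, cents)
  rownames(centroids) <- merged_names
  list(labels = out, mapping = mapping, centroids = centroids)
}

## 2x2 counts for one (neighborhood, cell type) combination
enrichment_counts <- function(labels, cell_types, nh, ty) {
  in_nh <- labels == nh
  is_ty <- cell_types == ty
  c(a = sum(in_nh & is_ty), b = sum(in_nh & !is_ty),
    c_ = sum(!in_nh & is_ty), d = sum(!in_nh & !is_ty))
}

#' Cell-type enrichment per neighborhood
#'
#' For every (neighborhood, cell type) combination, the odds ratio of the
#' 2x2 table cells in/out of the neighborhood vs of/not of the type, as
#' log2(OR) with a Haldane-Anscombe 0.5 correction applied when any table
#' cell is zero, plus a two-sided Fisher exact p-value, Benjamini-Hochberg
#' adjusted across the whole matrix.
#'
#' @param labels neighborhood label per cell.
#' @param t the spatial cell table (uses `cell_type`).
#' @return A tidy data.frame (`neighborhood`, `cell_type`, `log2_or`, `p`,
#'   `p_adj`).
#' @export
enrichment_matrix <- function(labels, t) {
  check_spatial(t)
  stopifnot(length(labels) == nrow(t))
  nhoods <- sort(unique(labels))
  if (length(nhoods) < 2)
    stop("need at least 2 neighborhoods for enrichment")
  types <- sort(unique(t$cell_type))
  res <- list()
  for (nh in nhoods) {
    for (ty in types) {
      cnt <- enrichment_counts(labels, t$cell_type, nh, ty)
      a <- cnt[["a"]]; b <- cnt[["b"]]; c_ <- cnt[["c_"]]; d <- cnt[["d"]]
      tab <- c(a, b, c_, d)
      if (any(tab == 0)) tab <- tab + 0.5
      or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
      p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
      res[[length(res) + 1]] <- data.frame(
        neighborhood = nh, cell_type = ty, log2_or = log2(or), p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Annotate merged neighborhoods with tissue zones
#'
#' Assigns each neighborhood the zone of its most enriched structural cell
#' type: FDC-enriched neighborhoods are follicular, FRC-enriched are T-zone,
#' rFRC-enriched inflammatory, LEC/Macro-enriched sinus; neighborhoods with
#' no positive structural enrichment are `other`.
#'
#' @param enrichment output of [enrichment_matrix()].
#' @return Named character vector, neighborhood -> zone label.
#' @export
annotate_neighborhoods <- function(enrichment) {
  anchor <- c(FDC = "follicle", FRC = "t_zone", rFRC = "inflammatory",
              LEC = "sinus", Macro = "sinus")
  nhoods <- unique(enrichment$neighborhood)
  out <- setNames(rep("other", length(nhoods)), nhoods)
  for (nh in nhoods) {
    sub <- enrichment[enrichment$neighborhood == nh &
                        enrichment$cell_type %in% names(anchor), ]
    if (!nrow(sub)) next
    sub <- sub[order(-sub$log2_or), ]
    if (sub$log2_or[1] > 0) out[nh] <- anchor[[sub$cell_type[1]]]
  }
  out
}

#' Otsu threshold for marker positivity
#'
#' Histogram-based threshold maximizing the between-class variance over
#' `n_bins` equal-width bins; a cell is positive when its value exceeds the
#' threshold. Used to binarize bimodal marker intensity distributions.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return A list with `threshold` and `positive` (logical vector).
#' @export
otsu_positivity <- function(values, n_bins = 256L) {
  if (length(unique(values)) < 2)
    stop("Otsu thresholding requires at least two distinct values")
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_total <- mu_cum[n_bins]
  w1 <- 1 - w0
  ## between-class variance at a split after each bin
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_total * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  t_bin <- which.max(bcv)
  threshold <- breaks[t_bin + 1L]
  list(threshold = threshold, positive = values > threshold)
}

#' Gene positivity in a spatial table
#'
#' Positivity rule for spatial transcript data: a raw count of at least 1
#' when `count_<gene>` columns are present, otherwise normalized expression
#' above `threshold` when `expr_<gene>` columns are present.
#'
#' @param t spatial cell table.
#' @param gene gene symbol.
#' @param threshold normalized-expression cutoff (default 2, strict).
#' @return Logical vector, one entry per cell.
#' @export
gene_positivity <- function(t, gene, threshold = 2) {
  cnt <- paste0("count_", gene)
  ex <- paste0("expr_", gene)
  if (cnt %in% names(t)) t[[cnt]] >= 1
  else if (ex %in% names(t)) t[[ex]] > threshold
  else stop("no count_ or expr_ column for gene ", gene)
}

#' Radius-based ligand-receptor proximity score
#'
#' For every cell, the number of neighbors within `radius_um` microns that
#' complete a ligand-receptor pair with it in either orientation: a neighbor
#' d counts for cell c when (c ligand-positive and d receptor-positive) or
#' (c receptor-positive and d ligand-positive). Each qualifying pair
#' contributes once to both cells.
#'
#' @param t spatial cell table.
#' @param ligand_pos,receptor_pos logical positivity vectors (one per cell),
#'   e.g. from [gene_positivity()] or [otsu_positivity()].
#' @param radius_um neighborhood radius in microns (default 20).
#' @return Integer vector of per-cell scores, named by cell id.
#' @export
lr_proximity_score <- function(t, ligand_pos, receptor_pos,
                               radius_um = 20) {
  check_spatial(t)
  if (radius_um <= 0) stop("radius_um must be positive")
  n <- nrow(t)
  stopifnot(length(ligand_pos) == n, length(receptor_pos) == n)
  score <- integer(n)
  prs <- .radius_pairs(cbind(t$x_um, t$y_um), radius_um)
  if (nrow(prs)) {
    i <- prs[, 1]; j <- prs[, 2]
    hit <- (ligand_pos[i] & receptor_pos[j]) |
      (receptor_pos[i] & ligand_pos[j])
    score <- tabulate(c(i[hit], j[hit]), nbins = n)
  }
  setNames(score, t$cell_id)
}

#' Two-dimensional Gaussian kernel density at arbitrary points
#'
#' Isotropic product-Gaussian KDE with bandwidth `h`:
#' `f(p) = (1 / (n 2 pi h^2)) * sum_i exp(-||p - x_i||^2 / (2 h^2))`.
#' A single reference point evaluated at itself gives `1 / (2 pi h^2)`.
#'
#' @param points n x 2 matrix of reference coordinates.
#' @param eval_at m x 2 matrix of evaluation coordinates.
#' @param h bandwidth (microns).
#' @return Numeric vector of densities at `eval_at`.
#' @export
kde2d_at <- function(points, eval_at, h) {
  points <- as.matrix(points); eval_at <- as.matrix(eval_at)
  stopifnot(ncol(points) == 2, ncol(eval_at) == 2, h > 0)
  d2 <- outer(eval_at[, 1], points[, 1], "-")^2 +
    outer(eval_at[, 2], points[, 2], "-")^2
  rowSums(exp(-d2 / (2 * h^2))) / (nrow(points) * 2 * pi * h^2)
}

#' Kernel-density attraction test
#'
#' Tests whether target cells (for example CXCR3-positive T cells)
#' accumulate around ligand-positive sender cells (for example
#' CXCL9-positive FRCs): a Gaussian KDE of target coordinates is evaluated
#' at ligand-positive and ligand-negative sender positions and the two
#' density samples are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param target_xy n x 2 coordinates of target cells (at least 5).
#' @param sender_xy m x 2 coordinates of sender cells.
#' @param sender_pos logical, ligand positivity of each sender; both groups
#'   must be non-empty.
#' @param bandwidth_um KDE bandwidth; default is Silverman's rule of thumb
#'   (geometric mean over the two coordinates of the targets).
#' @return A list with `density` (per sender), `bandwidth_um`, `p_value`,
#'   `median_pos`, `median_neg`.
#' @export
kde_attraction_test <- function(target_xy, sender_xy, sender_pos,
                                bandwidth_um = NULL) {
  target_xy <- as.matrix(target_xy); sender_xy <- as.matrix(sender_xy)
  if (nrow(target_xy) < 5) stop("need at least 5 target cells")
  stopifnot(length(sender_pos) == nrow(sender_xy))
  if (!any(sender_pos) || all(sender_pos))
    stop("both ligand-positive and ligand-negative senders are required")
  if (is.null(bandwidth_um))
    bandwidth_um <- sqrt(bw.nrd0(target_xy[, 1]) * bw.nrd0(target_xy[, 2]))
  dens <- kde2d_at(target_xy, sender_xy, bandwidth_um)
  wt <- wilcox.test(dens[sender_pos], dens[!sender_pos], exact = FALSE)
  list(density = dens, bandwidth_um = bandwidth_um,
       p_value = wt$p.value,
       median_pos = median(dens[sender_pos]),
       median_neg = median(dens[!sender_pos]))
}
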