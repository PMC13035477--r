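#' Chemokine ligand-receptor registry
#'
#' Loads a curated table of chemokine ligand to receptor gene pairs, each
#' labelled homeostatic (lymphoid-tissue-organizing: CXCL13-CXCR5,
#' CXCL12-CXCR4, CCL19/CCL21-CCR7), inflammatory (interferon-inducible CXCR3
#' ligands CXCL9/10/11) or other. The bundled default covers the canonical
#' zonation-defining axes plus common constitutive chemokine pairs; supply
#' `path` to use a larger curated registry (CSV with columns
#' `ligand,receptor,class`).
#'
#' @param path optional path to a registry CSV; `NULL` loads the bundled
#'   default.
#' @return A data.frame with columns `ligand`, `receptor`, `class` and class
#'   `lr_registry`; row names are `"<ligand>_<receptor>"` pair ids.
#' @export
lr_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "chemokine_lr_registry.csv",
                        package = "lymphochemnet", mustWork = TRUE)
  if (!file.exists(path)) stop("registry file not found: ", path)
  reg <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("ligand", "receptor", "class")
  if (!all(required %in% names(reg)))
    stop("registry must have columns: ", paste(required, collapse = ", "))
  bad_class <- setdiff(unique(reg$class),
                       c("homeostatic", "inflammatory", "other"))
  if (length(bad_class))
    stop("unknown registry class values: ", paste(bad_class, collapse = ", "))
  pair_id <- paste(reg$ligand, reg$receptor, sep = "_")
  if (anyDuplicated(pair_id))
    stop("duplicate ligand-receptor pairs: ",
         paste(unique(pair_id[duplicated(pair_id)]), collapse = ", "))
  rownames(reg) <- pair_id
  class(reg) <- c("lr_registry", "data.frame")
  reg
}

#' Pair identifiers of a registry
#' @param reg an [lr_registry()].
#' @return Character vector `"<ligand>_<receptor>"`.
#' @export
lr_pair_ids <- function(reg) paste(reg$ligand, reg$receptor, sep = "_")

#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline with defaults matching the
#' reference analysis: pair rows are kept when at least `min_lr_pairs`
#' ligand-receptor scores are positive; pair embeddings use `n_pcs` principal
#' components and a cosine `knn`-nearest-neighbor graph; the diffuseness score
#' downsamples pairs to `diffuseness_fraction`; spatial neighborhoods use
#' `nhood_k` nearest neighbors and `nhood_kmeans_k` k-means clusters;
#' ligand-receptor proximity uses a `lr_radius_um` micron radius; spatial
#' positivity calls normalized expression above `positivity_threshold`; cells
#' need more than `min_transcripts` transcripts to pass QC; clonotypes are
#' expanded above `clonal_threshold` cells.
#'
#' @param min_lr_pairs minimum positive ligand-receptor scores per retained
#'   cell pair (default 4).
#' @param n_pcs principal components for the pair embedding (default 20).
#' @param knn neighbors in the pair kNN graph (default 30).
#' @param pair_metric distance measure for the pair graph (cosine).
#' @param diffuseness_fraction downsampling fraction for the diffuseness
#'   score (default 0.3).
#' @param nhood_k spatial nearest neighbors per cell (default 20).
#' @param nhood_kmeans_k k-means clusters for neighborhood detection
#'   (default 20).
#' @param lr_radius_um radius in microns for spatial ligand-receptor
#'   proximity (default 20).
#' @param positivity_threshold normalized-expression positivity cutoff
#'   (default 2).
#' @param min_transcripts QC transcript-count threshold, strict (default 50).
#' @param clonal_threshold clonal-expansion cell-count threshold, strict
#'   (default 7).
#' @param seed root random seed for all stochastic steps.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(min_lr_pairs = 4L, n_pcs = 20L, knn = 30L,
                            pair_metric = c("cosine"),
                            diffuseness_fraction = 0.3, nhood_k = 20L,
                            nhood_kmeans_k = 20L, lr_radius_um = 20,
                            positivity_threshold = 2, min_transcripts = 50L,
                            clonal_threshold = 7L, seed = 1L) {
  pair_metric <- match.arg(pair_metric)
  cfg <- list(min_lr_pairs = as.integer(min_lr_pairs),
              n_pcs = as.integer(n_pcs), knn = as.integer(knn),
              pair_metric = pair_metric,
              diffuseness_fraction = diffuseness_fraction,
              nhood_k = as.integer(nhood_k),
              nhood_kmeans_k = as.integer(nhood_kmeans_k),
              lr_radius_um = lr_radius_um,
              positivity_threshold = positivity_threshold,
              min_transcripts = as.integer(min_transcripts),
              clonal_threshold = as.integer(clonal_threshold),
              seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), c("pair_metric", "seed"))]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, logical(1))]
  if (length(bad))
    stop("configuration values must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (cfg$diffuseness_fraction > 1)
    stop("diffuseness_fraction must lie in (0, 1]")
  class(cfg) <- "analysis_config"
  cfg
}
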