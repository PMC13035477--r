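#' Pair feature matrix constructor
#'
#' Internal container for directed cell-pair chemokine attraction scores:
#' one row per (sender, receiver) pair within a sample, one column per
#' ligand-receptor pair.
#'
#' @param scores numeric matrix, pairs x ligand-receptor columns.
#' @param pairs data.frame with columns `sender`, `receiver`, `sample_id`.
#' @param provenance list of parameters used.
#' @return An object of class `pair_matrix`.
#' @keywords internal
pair_matrix <- function(scores, pairs, provenance = list()) {
  stopifnot(nrow(scores) == nrow(pairs),
            all(c("sender", "receiver", "sample_id") %in% names(pairs)))
  if (nrow(scores) && min(scores) < 0)
    stop("attraction scores must be non-negative")
  structure(list(scores = scores, pairs = pairs, provenance = provenance),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %d directed cell pairs x %d L-R pairs, %d sample(s)\n",
              nrow(x$scores), ncol(x$scores),
              length(unique(x$pairs$sample_id))))
  invisible(x)
}

#' Compute directed cell-pair chemokine attraction potentials
#'
#' For every ordered pair of distinct cells (i sender, j receiver) in one
#' sample and every registry ligand-receptor pair (l, r), the attraction
#' potential is the geometric mean of ligand expression in the sender and
#' receptor expression in the receiver, `sqrt(expr_i(l) * expr_j(r))`,
#' computed on log-normalized expression. Registry pairs whose ligand or
#' receptor is absent from the matrix are dropped with a warning. Because the
#' number of pairs grows quadratically in cells, an optional per-cell-type
#' downsampling cap bounds cost; it is applied with the given seed.
#'
#' @param expr a log-normalized [gene_expression()] object.
#' @param cells a cell annotation data.frame (`cell_id`, `sample_id`,
#'   `cell_type`, ...); only cells of `sample_id` are used.
#' @param registry an [lr_registry()].
#' @param sample_id sample to process; default the single sample present.
#' @param downsample_per_type optional integer cap on cells per type
#'   (default 100; `NULL` disables).
#' @param seed seed for the downsampling draw.
#' @return A `pair_matrix` with `n * (n - 1)` rows for `n` retained cells.
#' @export
compute_attraction <- function(expr, cells, registry, sample_id = NULL,
                               downsample_per_type = 100L, seed = 1) {
  stopifnot(inherits(expr, "gexpr"))
  if (!expr$normalized)
    stop("expression must be log-normalized (see log_normalize)")
  if (is.null(sample_id)) {
    sample_id <- unique(cells$sample_id)
    if (length(sample_id) != 1)
      stop("multiple samples present; specify sample_id")
  }
  cells <- cells[cells$sample_id == sample_id, , drop = FALSE]
  if (nrow(cells) < 2)
    stop("sample ", sample_id, " has fewer than 2 cells")
  missing_cells <- setdiff(cells$cell_id, expr$cell_ids)
  if (length(missing_cells))
    stop("annotated cells absent from expression matrix: ",
         paste(head(missing_cells, 5), collapse = ", "))

  keep <- registry$ligand %in% expr$gene_ids &
    registry$receptor %in% expr$gene_ids
  if (!any(keep))
    stop("no registry ligand-receptor pair has both genes in the matrix")
  if (any(!keep))
    warning("dropping ", sum(!keep),
            " registry pairs with genes absent from the matrix: ",
            paste(head(lr_pair_ids(registry)[!keep], 5), collapse = ", "))
  reg <- registry[keep, , drop = FALSE]

  if (!is.null(downsample_per_type)) {
    cells <- withr::with_seed(as.integer(seed), {
      idx <- unlist(lapply(split(seq_len(nrow(cells)), cells$cell_type),
                           function(ix) {
                             if (length(ix) > downsample_per_type)
                               sample(ix, downsample_per_type)
                             else ix
                           }), use.names = FALSE)
      cells[sort(idx), , drop = FALSE]
    })
  }

  ids <- cells$cell_id
  n <- length(ids)
  vals <- expr$values[, ids, drop = FALSE]
  lr_ids <- lr_pair_ids(reg)

  ## ordered pairs, sender-major, self-pairs excluded
  sender_idx <- rep(seq_len(n), each = n)
  receiver_idx <- rep(seq_len(n), times = n)
  off <- sender_idx != receiver_idx
  sender_idx <- sender_idx[off]
  receiver_idx <- receiver_idx[off]

  scores <- matrix(0, nrow = length(sender_idx), ncol = length(lr_ids),
                   dimnames = list(NULL, lr_ids))
  for (k in seq_along(lr_ids)) {
    l <- sqrt(vals[reg$ligand[k], ])
    r <- sqrt(vals[reg$receptor[k], ])
    scores[, k] <- l[sender_idx] * r[receiver_idx]
  }
  pairs <- data.frame(sender = ids[sender_idx], receiver = ids[receiver_idx],
                      sample_id = sample_id, stringsAsFactors = FALSE)
  pair_matrix(scores, pairs,
              provenance = list(sample_id = sample_id,
                                downsample_per_type = downsample_per_type,
                                seed = seed, n_cells = n))
}

#' Filter cell pairs by the minimum ligand-receptor support rule
#'
#' Retains exactly the pair rows with at least `min_lr_pairs` strictly
#' positive ligand-receptor scores; pairs supported by fewer axes carry too
#' little chemotactic information to embed.
#'
#' @param pm a `pair_matrix`.
#' @param min_lr_pairs minimum number of positive entries (default 4,
#'   inclusive).
#' @return The filtered `pair_matrix` (possibly empty, with a message).
#' @export
filter_pairs <- function(pm, min_lr_pairs = 4L) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (min_lr_pairs < 1) stop("min_lr_pairs must be at least 1")
  npos <- rowSums(pm$scores > 0)
  keep <- npos >= min_lr_pairs
  if (!any(keep)) message("filter_pairs: no pair rows retained")
  pair_matrix(pm$scores[keep, , drop = FALSE],
              pm$pairs[keep, , drop = FALSE],
              c(pm$provenance, list(min_lr_pairs = min_lr_pairs)))
}

#' Merge per-sample pair matrices
#'
#' Row-concatenates pair matrices computed per sample, aligning columns by
#' ligand-receptor pair id. No cross-sample pairs are ever created.
#'
#' @param ms list of `pair_matrix` objects with identical column sets.
#' @return A single merged `pair_matrix`.
#' @export
merge_samples <- function(ms) {
  stopifnot(length(ms) >= 1, all(vapply(ms, inherits, logical(1),
                                        "pair_matrix")))
  ref_cols <- colnames(ms[[1]]$scores)
  for (i in seq_along(ms)) {
    cols <- colnames(ms[[i]]$scores)
    extra <- setdiff(cols, ref_cols)
    miss <- setdiff(ref_cols, cols)
    if (length(extra) || length(miss))
      stop("column sets differ at input ", i, "; missing: ",
           paste(miss, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
  }
  scores <- do.call(rbind, lapply(ms, function(m)
    m$scores[, ref_cols, drop = FALSE]))
  pairs <- do.call(rbind, lapply(ms, function(m) m$pairs))
  rownames(pairs) <- NULL
  pair_matrix(scores, pairs,
              provenance = list(merged_from =
                                  lapply(ms, function(m) m$provenance)))
}
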