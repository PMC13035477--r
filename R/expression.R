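#' Gene expression matrix container
#'
#' A light container for a genes x cells expression matrix with unique gene
#' and cell identifiers and a flag recording whether values are raw counts or
#' log-normalized expression. All downstream scoring assumes log-normalized
#' input; generators emit raw counts.
#'
#' @param values numeric matrix, genes in rows, cells in columns; no negative
#'   entries.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column.
#' @param normalized logical; `FALSE` for raw counts (the default),
#'   `TRUE` after [log_normalize()].
#' @return An object of class `gexpr`: a list with elements `values`,
#'   `gene_ids`, `cell_ids` and `normalized`.
#' @seealso [load_expression()], [log_normalize()]
#' @export
gene_expression <- function(values, gene_ids = rownames(values),
                            cell_ids = colnames(values),
                            normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (row/column names or arguments)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(values), ")")
  if (length(cell_ids) != ncol(values))
    stop("cell_ids length (", length(cell_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 normalized = isTRUE(normalized)),
            class = "gexpr")
}

#' @export
print.gexpr <- function(x, ...) {
  cat(sprintf("<gexpr> %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "log-normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.gexpr <- function(x) dim(x$values)

#' Load an expression matrix from MatrixMarket or dense CSV
#'
#' Reads either a sparse MatrixMarket triplet file accompanied by TSV gene and
#' cell id files (first column used; ids in file order), or a single dense CSV
#' with gene rows and cell columns.
#'
#' @param matrix_path path to a `.mtx` file or a dense `.csv` file.
#' @param genes_path,cells_path paths to TSV id files; required for MTX input,
#'   ignored for CSV.
#' @return A [gene_expression()] object with `normalized = FALSE`.
#' @export
load_expression <- function(matrix_path, genes_path = NULL, cells_path = NULL) {
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input requires genes_path and cells_path")
    if (!file.exists(genes_path)) stop("gene id file not found: ", genes_path)
    if (!file.exists(cells_path)) stop("cell id file not found: ", cells_path)
    m <- as.matrix(Matrix::readMM(matrix_path))
    storage.mode(m) <- "double"
    genes <- read.delim(genes_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(cells_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop("MTX declares ", nrow(m), " genes but id file lists ",
           length(genes))
    if (length(cells) != ncol(m))
      stop("MTX declares ", ncol(m), " cells but id file lists ",
           length(cells))
    gene_expression(m, genes, cells, normalized = FALSE)
  } else {
    df <- read.csv(matrix_path, row.names = 1, check.names = FALSE)
    gene_expression(as.matrix(df), rownames(df), colnames(df),
                    normalized = FALSE)
  }
}

#' Write an expression matrix
#'
#' Inverse of [load_expression()]: MTX plus id files when `matrix_path` ends
#' in `.mtx`, otherwise a dense CSV with gene rows.
#'
#' @param x a [gene_expression()] object.
#' @param matrix_path output path (`.mtx` or `.csv`).
#' @param genes_path,cells_path output id TSV paths (MTX only).
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(x, matrix_path, genes_path = NULL,
                             cells_path = NULL) {
  stopifnot(inherits(x, "gexpr"))
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX output requires genes_path and cells_path")
    nz <- which(x$values != 0, arr.ind = TRUE)
    sm <- Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2],
                               x = as.double(x$values[nz]),
                               dims = dim(x$values))
    Matrix::writeMM(sm, matrix_path)
    writeLines(x$gene_ids, genes_path)
    writeLines(x$cell_ids, cells_path)
  } else {
    df <- as.data.frame(x$values)
    write.csv(df, matrix_path, row.names = TRUE)
  }
  invisible(matrix_path)
}

#' Log-normalize raw counts
#'
#' Per-cell depth normalization followed by a log transform:
#' `x_gc -> ln(1 + scale * x_gc / colsum_c)`. This is the standard
#' library-size correction for UMI count data; the scale factor is
#' configurable because different platforms report different depths.
#'
#' @param x a raw-count [gene_expression()] object.
#' @param scale positive scale factor applied after depth division
#'   (default 10,000).
#' @return A [gene_expression()] object with `normalized = TRUE`.
#' @export
log_normalize <- function(x, scale = 1e4) {
  stopifnot(inherits(x, "gexpr"))
  if (x$normalized) stop("input is already log-normalized")
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("scale must be a positive number")
  totals <- colSums(x$values)
  if (any(totals == 0))
    stop("cells with zero total counts cannot be normalized: ",
         paste(head(x$cell_ids[totals == 0], 5), collapse = ", "))
  vals <- log1p(sweep(x$values, 2, totals / scale, "/"))
  gene_expression(vals, x$gene_ids, x$cell_ids, normalized = TRUE)
}
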