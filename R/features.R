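#' Construct a gene-by-cell feature matrix
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_names,cell_names row/column identities.
#' @param logcpm optional matrix of pre-scaling log-CPM values (same shape),
#'   kept for expression-bin procedures such as [module_score()].
#' @param preprocessing_log character vector describing applied filters.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, gene_names, cell_names,
                           logcpm = NULL, preprocessing_log = character()) {
  values <- as.matrix(values)
  if (nrow(values) != length(gene_names) || ncol(values) != length(cell_names)) {
    stop("dimensions of `values` do not match gene/cell name lengths")
  }
  dimnames(values) <- list(gene_names, cell_names)
  if (!is.null(logcpm)) {
    logcpm <- as.matrix(logcpm)
    stopifnot(identical(dim(logcpm), dim(values)))
    dimnames(logcpm) <- dimnames(values)
  }
  structure(
    list(gene_names = as.character(gene_names),
         cell_names = as.character(cell_names),
         values = values, logcpm = logcpm,
         preprocessing_log = preprocessing_log),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", length(x$gene_names), "genes x",
      length(x$cell_names), "cells\n")
  if (length(x$preprocessing_log)) {
    cat(paste0("  - ", x$preprocessing_log, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Preprocess a raw single-cell count matrix
#'
#' Applies the standard single-cell filters and transforms: genes with
#' nonzero counts in fewer than `min_cells_expressed` cells are removed,
#' then cells expressing fewer than `min_genes_expressed` genes are removed,
#' counts are converted to log(CPM + 1) per cell (natural log), and each
#' gene row is finally z-scored across all cells. Gene rows constant after
#' log-CPM (zero variance) are left centred at 0 rather than divided by 0.
#'
#' @param raw_counts nonnegative integer matrix (dense or `Matrix` sparse),
#'   genes in rows, cells in columns; dimnames supply gene/cell names.
#' @param min_cells_expressed gene filter: minimum number of cells with a
#'   nonzero count (default 3).
#' @param min_genes_expressed cell filter: minimum number of expressed genes
#'   (default 200).
#' @return A [feature_matrix] whose `values` are the scaled log-CPM and
#'   whose `logcpm` keeps the pre-scaling values.
#' @export
preprocess_features <- function(raw_counts, min_cells_expressed = 3,
                                min_genes_expressed = 200) {
  counts <- as.matrix(raw_counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  gn <- rownames(counts); cn <- colnames(counts)
  if (is.null(gn)) gn <- sprintf("gene%d", seq_len(nrow(counts)))
  if (is.null(cn)) cn <- sprintf("cell%d", seq_len(ncol(counts)))
  log_entries <- character()

  keep_genes <- rowSums(counts > 0) >= min_cells_expressed
  log_entries <- c(log_entries, sprintf(
    "gene filter (expressed in >= %d cells): %d of %d genes kept",
    min_cells_expressed, sum(keep_genes), nrow(counts)))
  counts <- counts[keep_genes, , drop = FALSE]
  gn <- gn[keep_genes]
  if (nrow(counts) == 0L) stop("gene filter removed all genes")

  keep_cells <- colSums(counts > 0) >= min_genes_expressed
  log_entries <- c(log_entries, sprintf(
    "cell filter (>= %d expressed genes): %d of %d cells kept",
    min_genes_expressed, sum(keep_cells), ncol(counts)))
  counts <- counts[, keep_cells, drop = FALSE]
  cn <- cn[keep_cells]
  if (ncol(counts) == 0L) stop("cell filter removed all cells")

  totals <- colSums(counts)
  logcpm <- log1p(sweep(counts, 2, totals, "/") * 1e6)
  log_entries <- c(log_entries, "log(CPM + 1) per cell (natural log)")

  mu <- rowMeans(logcpm)
  sdv <- apply(logcpm, 1, stats::sd)
  scaled <- (logcpm - mu) / ifelse(sdv > 0, sdv, 1)
  log_entries <- c(log_entries, "per-gene z-score across cells")

  feature_matrix(scaled, gn, cn, logcpm = logcpm,
                 preprocessing_log = log_entries)
}

#' Align a feature matrix to a gene graph's node order
#'
#' Feature genes absent from the graph are dropped; graph genes absent from
#' the features are added as all-zero rows; the output row order equals the
#' graph's gene order. Idempotent.
#'
#' @param graph a [gene_graph].
#' @param features a [feature_matrix].
#' @return A [feature_matrix] with `gene_names` identical to
#'   `graph$gene_names`.
#' @export
align_genes <- function(graph, features) {
  stopifnot(inherits(graph, "gene_graph"), inherits(features, "feature_matrix"))
  shared <- intersect(graph$gene_names, features$gene_names)
  if (!length(shared)) stop("zero genes in common between graph and features")
  n <- n_genes(graph)
  nc <- length(features$cell_names)
  align_one <- function(mat) {
    if (is.null(mat)) return(NULL)
    out <- matrix(0, n, nc, dimnames = list(graph$gene_names, features$cell_names))
    pos <- match(shared, features$gene_names)
    out[shared, ] <- mat[pos, , drop = FALSE]
    out
  }
  n_dropped <- length(setdiff(features$gene_names, graph$gene_names))
  n_zero <- n - length(shared)
  feature_matrix(
    align_one(features$values), graph$gene_names, features$cell_names,
    logcpm = align_one(features$logcpm),
    preprocessing_log = c(
      features$preprocessing_log,
      sprintf("aligned to graph: %d genes dropped, %d zero rows added",
              n_dropped, n_zero))
  )
}

#' Read counts from MatrixMarket triplet plus sidecar name files
#'
#' @param mtx path to the `.mtx` file (genes x cells).
#' @param genes,cells paths to plain-text name lists, one per line.
#' @return A sparse `Matrix` of counts with dimnames.
#' @export
read_counts_mtx <- function(mtx, genes, cells) {
  m <- Matrix::readMM(mtx)
  gn <- readLines(genes, warn = FALSE)
  cn <- readLines(cells, warn = FALSE)
  if (nrow(m) != length(gn) || ncol(m) != length(cn)) {
    stop("matrix dimensions do not match gene/cell name files")
  }
  dimnames(m) <- list(gn, cn)
  m
}

#' Read counts from a dense CSV (gene rows x cell columns)
#'
#' @param path CSV path; first column holds gene names, header holds cells.
#' @return A dense numeric matrix with dimnames.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a count or feature matrix as MatrixMarket triplet plus name files
#'
#' @param mat matrix (dense or sparse), genes x cells.
#' @param mtx,genes,cells output paths.
#' @return `mtx`, invisibly.
#' @export
write_counts_mtx <- function(mat, mtx, genes, cells) {
  sm <- methods::as(methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix"),
                    "CsparseMatrix")
  Matrix::writeMM(sm, mtx)
  writeLines(rownames(mat), genes)
  writeLines(colnames(mat), cells)
  invisible(mtx)
}
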