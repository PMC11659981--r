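#' Construct a gene interaction graph
#'
#' A `gene_graph` stores an undirected, unweighted gene-gene interaction
#' network: an ordered gene universe, a sparse symmetric binary adjacency
#' matrix with zero diagonal, per-gene degrees and the edge count `m`.
#'
#' @param edges two-column character matrix or data.frame of gene-symbol
#'   pairs (undirected; duplicates, reversed duplicates and self-loops are
#'   removed).
#' @param gene_names optional character vector fixing the node universe and
#'   order; defaults to first-appearance order in `edges`. Genes listed here
#'   but absent from `edges` become isolated nodes.
#' @return An object of class `gene_graph` with elements `gene_names`,
#'   `adjacency` (sparse `dgCMatrix`), `degrees` and `m`.
#' @export
gene_graph <- function(edges, gene_names = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have exactly two columns")
  storage.mode(edges) <- "character"
  edges[] <- trimws(edges)
  # node universe is collected before dropping self-loops, so a gene seen
  # only in a self-loop line is kept as an isolated node
  seen <- as.vector(t(edges))
  seen <- seen[nzchar(seen)]
  keep <- edges[, 1L] != edges[, 2L] & nzchar(edges[, 1L]) & nzchar(edges[, 2L])
  edges <- edges[keep, , drop = FALSE]
  if (is.null(gene_names)) {
    gene_names <- unique(seen)
  } else {
    gene_names <- trimws(as.character(gene_names))
    if (anyDuplicated(gene_names)) stop("`gene_names` contains duplicates")
    unknown <- setdiff(unique(as.vector(edges)), gene_names)
    if (length(unknown)) {
      stop("edges mention genes absent from `gene_names`: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  n <- length(gene_names)
  i <- match(edges[, 1L], gene_names)
  j <- match(edges[, 2L], gene_names)
  # canonical unordered representation, then dedup
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (length(lo)) {
    key <- !duplicated(lo + (hi - 1) * n)
    lo <- lo[key]; hi <- hi[key]
  }
  adjacency <- Matrix::sparseMatrix(
    i = c(lo, hi), j = c(hi, lo), x = 1,
    dims = c(n, n), dimnames = list(gene_names, gene_names)
  )
  adjacency <- methods::as(adjacency, "CsparseMatrix")
  degrees <- Matrix::rowSums(adjacency)
  structure(
    list(
      gene_names = gene_names,
      adjacency = adjacency,
      degrees = as.integer(degrees),
      m = as.integer(sum(degrees) / 2)
    ),
    class = "gene_graph"
  )
}

#' @export
print.gene_graph <- function(x, ...) {
  cat("gene_graph:", length(x$gene_names), "genes,", x$m, "edges\n")
  invisible(x)
}

n_genes <- function(graph) length(graph$gene_names)

#' Read an undirected gene edge list
#'
#' Reads a two-column TSV edge list (or a BioGRID tab3 export, using the two
#' official-symbol columns) into a [gene_graph]. Lines starting with `#` are
#' ignored; self-loops are dropped; duplicate and reversed-duplicate edges
#' collapse to a single undirected edge; node order is first-appearance order.
#'
#' @param path path to the file.
#' @param dialect `"two_column_tsv"` (default) or `"biogrid_tab3"`.
#' @return A [gene_graph].
#' @export
load_edge_list <- function(path, dialect = c("two_column_tsv", "biogrid_tab3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (dialect == "biogrid_tab3" && length(idx)) {
    # tab3 exports carry a non-'#' header line naming the columns
    first <- strsplit(lines[idx[1]], "\t", fixed = TRUE)[[1]]
    if (any(grepl("official symbol", first, ignore.case = TRUE))) idx <- idx[-1]
  }
  if (!length(idx)) stop("no edge lines found in ", path)
  cols <- if (dialect == "two_column_tsv") c(1L, 2L) else c(8L, 9L)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < max(cols))
  if (length(bad)) {
    stop("unparseable line ", idx[bad[1]], " in ", path,
         ": expected at least ", max(cols), " tab-separated fields")
  }
  a <- trimws(vapply(parts, `[[`, "", cols[1]))
  b <- trimws(vapply(parts, `[[`, "", cols[2]))
  graph <- gene_graph(cbind(a, b))
  if (graph$m == 0L) stop("zero edges remain after removing self-loops/duplicates")
  graph
}

#' Write a gene graph as a two-column TSV edge list
#'
#' Inverse of [load_edge_list()] for the `two_column_tsv` dialect; isolated
#' nodes are not representable in an edge list and are dropped on round-trip.
#'
#' @param graph a [gene_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  ut <- Matrix::triu(graph$adjacency)
  idx <- Matrix::which(ut != 0, arr.ind = TRUE)
  df <- data.frame(
    a = graph$gene_names[idx[, 1]],
    b = graph$gene_names[idx[, 2]]
  )
  ord <- order(idx[, 1], idx[, 2])
  utils::write.table(df[ord, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the edge list of a gene graph as an index matrix
#'
#' @param graph a [gene_graph].
#' @return integer matrix with columns `i`, `j` (i < j), one row per edge.
#' @keywords internal
edge_index <- function(graph) {
  ut <- Matrix::triu(graph$adjacency)
  idx <- Matrix::which(ut != 0, arr.ind = TRUE)
  m <- cbind(i = idx[, 1], j = idx[, 2])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Build a gene graph from an edge index matrix
#' @keywords internal
graph_from_edge_index <- function(edges_ij, gene_names) {
  gene_graph(cbind(gene_names[edges_ij[, 1]], gene_names[edges_ij[, 2]]),
             gene_names = gene_names)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected",
                                      weighted = NULL, diag = FALSE)
}
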