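#' Detect primary communities with the Louvain algorithm
#'
#' Runs greedy Louvain modularity maximization on the interaction network to
#' obtain the hard "primary" partition that seeds the enhanced adjacency.
#' Isolated nodes form singleton communities. Deterministic given `seed`.
#'
#' @param graph a [gene_graph] with at least one edge.
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed recorded in the result (default 0).
#' @return An object of class `community_assignment`: sparse binary
#'   membership matrix `membership` (n x k, each row sums to 1),
#'   `community_sizes`, `labels` (integer community id per gene),
#'   `resolution`, `seed`.
#' @export
detect_primary_communities <- function(graph, resolution = 1, seed = 0) {
  stopifnot(inherits(graph, "gene_graph"))
  if (graph$m == 0L) stop("graph has no edges; cannot detect communities")
  g <- as_igraph(graph)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(comm))
  community_assignment(labels, graph$gene_names, resolution = resolution,
                       seed = seed)
}

#' @rdname detect_primary_communities
#' @param labels integer community id per gene (1..k).
#' @param gene_names gene symbols, same length as `labels`.
#' @export
community_assignment <- function(labels, gene_names, resolution = NA_real_,
                                 seed = NA_integer_) {
  labels <- as.integer(factor(labels))  # compact to 1..k
  n <- length(labels)
  k <- max(labels)
  membership <- Matrix::sparseMatrix(i = seq_len(n), j = labels, x = 1,
                                     dims = c(n, k),
                                     dimnames = list(gene_names, NULL))
  structure(
    list(membership = membership,
         labels = labels,
         gene_names = as.character(gene_names),
         community_sizes = as.integer(tabulate(labels, k)),
         resolution = resolution, seed = seed),
    class = "community_assignment"
  )
}

#' @export
print.community_assignment <- function(x, ...) {
  cat("community_assignment:", length(x$labels), "genes in",
      length(x$community_sizes), "communities (sizes ",
      paste(utils::head(sort(x$community_sizes, decreasing = TRUE), 5),
            collapse = ", "),
      if (length(x$community_sizes) > 5) ", ...)" else ")", "\n", sep = "")
  invisible(x)
}

#' Write a community assignment as a two-column TSV (gene, community id)
#' @param assignment a `community_assignment`.
#' @param path output path.
#' @export
write_community_assignment <- function(assignment, path) {
  utils::write.table(
    data.frame(gene = assignment$gene_names, community = assignment$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Node community matrix
#'
#' Computes `A_c = M M^T - I`: a binary matrix with `A_c[i, j] = 1` iff
#' genes i and j (i != j) share a primary community.
#'
#' @param assignment a `community_assignment`.
#' @return Sparse symmetric binary matrix with zero diagonal.
#' @export
community_matrix <- function(assignment) {
  stopifnot(inherits(assignment, "community_assignment"))
  M <- assignment$membership
  A_c <- Matrix::tcrossprod(M) - Matrix::Diagonal(nrow(M))
  methods::as(methods::as(Matrix::drop0(A_c), "generalMatrix"), "CsparseMatrix")
}

#' Sparsify the community matrix to s representatives per community
#'
#' Within each community, every node keeps community links only to the `s`
#' members with highest degree in the original graph (ties broken by gene
#' name, self excluded); the result is symmetrized by union. Communities of
#' size <= s + 1 are left complete.
#'
#' @param A_c community matrix from [community_matrix()].
#' @param assignment the `community_assignment` that produced `A_c`.
#' @param graph the original [gene_graph] supplying degrees for the
#'   representative ranking.
#' @param s number of representatives kept per node (default 10).
#' @return Sparse symmetric binary matrix, a subset of `A_c`'s support.
#' @export
sparsify_community <- function(A_c, assignment, graph, s = 10) {
  stopifnot(inherits(assignment, "community_assignment"),
            inherits(graph, "gene_graph"), s >= 1)
  s <- as.integer(s)
  n <- length(assignment$labels)
  ii <- integer(0); jj <- integer(0)
  for (cid in seq_along(assignment$community_sizes)) {
    members <- which(assignment$labels == cid)
    sz <- length(members)
    if (sz < 2L) next
    if (sz <= s + 1L) {
      pairs <- utils::combn(members, 2L)
      ii <- c(ii, pairs[1L, ]); jj <- c(jj, pairs[2L, ])
      next
    }
    ord <- members[order(-graph$degrees[members], graph$gene_names[members])]
    for (node in members) {
      reps <- setdiff(ord, node)[seq_len(s)]
      ii <- c(ii, rep.int(node, length(reps))); jj <- c(jj, reps)
    }
  }
  if (!length(ii)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n),
                                dimnames = dimnames(A_c)))
  }
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  keep <- !duplicated(lo + (hi - 1) * n)
  lo <- lo[keep]; hi <- hi[keep]
  Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = 1, dims = c(n, n),
                       dimnames = dimnames(A_c))
}

#' Enhanced adjacency
#'
#' Computes `A_n = A + lambda * A_c`, adding weighted (sparsified)
#' same-community links to the observed interaction edges. Entries are kept
#' real-valued: an observed edge inside a community link becomes
#' `1 + lambda`.
#'
#' @param graph a [gene_graph] supplying `A`.
#' @param A_c_sparse (sparsified) community matrix.
#' @param lambda_weight positive weight on the community links (default 1).
#' @param sparsity_s the `s` used to sparsify `A_c_sparse`, recorded for
#'   provenance (default `NA`).
#' @return An object of class `enhanced_adjacency` with elements `matrix`
#'   (sparse symmetric, zero diagonal), `lambda_weight`, `sparsity_s` and
#'   `source_graph_hash`.
#' @export
enhance_adjacency <- function(graph, A_c_sparse, lambda_weight = 1,
                              sparsity_s = NA_integer_) {
  stopifnot(inherits(graph, "gene_graph"))
  if (lambda_weight <= 0) stop("lambda_weight must be > 0")
  if (!identical(dim(graph$adjacency), dim(A_c_sparse))) {
    stop("shape mismatch: adjacency is ", nrow(graph$adjacency), "x",
         ncol(graph$adjacency), " but A_c is ", nrow(A_c_sparse), "x",
         ncol(A_c_sparse))
  }
  A_n <- graph$adjacency + lambda_weight * A_c_sparse
  structure(
    list(matrix = methods::as(methods::as(A_n, "generalMatrix"), "CsparseMatrix"),
         lambda_weight = lambda_weight,
         sparsity_s = sparsity_s,
         source_graph_hash = sprintf("n%d_m%d", n_genes(graph), graph$m)),
    class = "enhanced_adjacency"
  )
}

#' @export
print.enhanced_adjacency <- function(x, ...) {
  cat("enhanced_adjacency:", nrow(x$matrix), "x", ncol(x$matrix),
      sprintf("(lambda = %g, s = %s, nnz = %d)\n", x$lambda_weight,
              as.character(x$sparsity_s), Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' Write an enhanced adjacency in MatrixMarket format
#' @param enhanced an `enhanced_adjacency`.
#' @param path output `.mtx` path.
#' @export
write_enhanced_adjacency <- function(enhanced, path) {
  Matrix::writeMM(enhanced$matrix, path)
  invisible(path)
}

# RNG bookkeeping: save/restore .Random.seed so seeded helpers do not
# perturb the caller's RNG stream.
.Random.seed_store <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
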