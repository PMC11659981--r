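#' Specification for the synthetic network + expression generator
#'
#' Describes a stochastic-block-model gene network with planted communities
#' paired with a count matrix whose gene blocks are differentially elevated
#' in coupled simulated cell types, with dropout noise.
#'
#' @param n_genes,n_blocks network size and number of planted blocks.
#' @param p_in,p_out within-/between-block edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param n_cells,n_cell_types count-matrix size and number of cell types.
#' @param effect_size mean log-expression lift of a block's genes in its
#'   coupled cell type(s) (default 1).
#' @param dropout_rate Bernoulli dropout probability in `[0, 1)`
#'   (default 0.3).
#' @param base_logmean,logsd baseline log mean expression and
#'   gene/cell-level lognormal noise SD.
#' @param seed RNG seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 200, n_blocks = 4, p_in = 0.25,
                           p_out = 0.02, n_cells = 400, n_cell_types = 4,
                           effect_size = 1, dropout_rate = 0.3,
                           base_logmean = log(2), logsd = 0.3, seed = 0) {
  stopifnot(n_genes >= 2, n_blocks >= 1, n_cells >= 1, n_cell_types >= 1,
            p_out >= 0, p_out < p_in, p_in <= 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_genes = as.integer(n_genes), n_blocks = as.integer(n_blocks),
                 p_in = p_in, p_out = p_out, n_cells = as.integer(n_cells),
                 n_cell_types = as.integer(n_cell_types),
                 effect_size = effect_size, dropout_rate = dropout_rate,
                 base_logmean = base_logmean, logsd = logsd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a stochastic-block-model gene network
#'
#' @param spec a [synthetic_spec()].
#' @return List with `graph` (a [gene_graph] whose universe covers all
#'   simulated genes, isolated ones included) and `blocks` (integer planted
#'   block label per gene).
#' @export
simulate_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  gene_names <- sprintf("G%04d", seq_len(n))
  blocks <- rep(seq_len(spec$n_blocks), length.out = n)
  blocks <- sort(blocks)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  ut <- which(upper.tri(matrix(0, n, n)))
  ii <- ((ut - 1) %% n) + 1
  jj <- ((ut - 1) %/% n) + 1
  p <- ifelse(blocks[ii] == blocks[jj], spec$p_in, spec$p_out)
  draw <- stats::runif(length(p)) < p
  if (!any(draw)) {
    warning("simulated graph has no edges under this spec")
    graph <- gene_graph(matrix(character(0), 0, 2), gene_names = gene_names)
  } else {
    graph <- gene_graph(cbind(gene_names[ii[draw]], gene_names[jj[draw]]),
                        gene_names = gene_names)
  }
  list(graph = graph, blocks = blocks)
}

#' Simulate a gene-by-cell count matrix with block-coupled cell types
#'
#' Counts are Poisson-lognormal: each gene has a baseline log-mean, lifted
#' by `effect_size` in cells of the cell type coupled to the gene's block
#' (identity coupling when block and cell-type counts match, round-robin
#' otherwise), with lognormal gene-by-cell noise and Bernoulli dropout.
#'
#' @param blocks integer block label per gene (length `spec$n_genes`).
#' @param spec a [synthetic_spec()].
#' @return List with `counts` (integer matrix genes x cells, dimnames set),
#'   `cell_types` (integer per cell) and `coupling` (block -> cell type).
#' @export
simulate_features <- function(blocks, spec) {
  stopifnot(inherits(spec, "synthetic_spec"),
            length(blocks) == spec$n_genes)
  n <- spec$n_genes; nc <- spec$n_cells
  gene_names <- sprintf("G%04d", seq_len(n))
  cell_names <- sprintf("C%04d", seq_len(nc))
  cell_types <- rep(seq_len(spec$n_cell_types), length.out = nc)
  coupling <- ((seq_len(spec$n_blocks) - 1L) %% spec$n_cell_types) + 1L
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed + 1L)
  gene_base <- spec$base_logmean + stats::rnorm(n, 0, spec$logsd)
  lift <- outer(coupling[blocks], cell_types, "==") * spec$effect_size
  logmu <- gene_base + lift + matrix(stats::rnorm(n * nc, 0, spec$logsd), n, nc)
  counts <- matrix(stats::rpois(n * nc, exp(logmu)), n, nc)
  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::runif(n * nc) >= spec$dropout_rate, n, nc)
    counts <- counts * keep
  }
  dimnames(counts) <- list(gene_names, cell_names)
  list(counts = counts, cell_types = cell_types, coupling = coupling)
}

#' Write a self-contained synthetic fixture bundle to disk
#'
#' `tiny` (30 genes / 3 blocks / 60 cells) supports fast unit tests;
#' `sbm_recovery` (200 genes / 4 blocks, p_in 0.25, p_out 0.02 / 400 cells /
#' 4 cell types) supports full-pipeline recovery checks. Files written:
#' `edges.tsv`, `counts.mtx`, `genes.txt`, `cells.txt`, `truth.tsv`
#' (gene, planted block), `cell_types.tsv`. Regeneration with the same seed
#' is byte-identical.
#'
#' @param name `"tiny"` or `"sbm_recovery"`.
#' @param seed RNG seed.
#' @param out_dir output directory (created if needed).
#' @return Named list of file paths, plus the `spec`, `blocks` and
#'   `cell_types` used, invisibly.
#' @export
fixture_bundle <- function(name = c("tiny", "sbm_recovery"), seed = 0,
                           out_dir = tempfile("fixture_")) {
  name <- match.arg(name)
  spec <- switch(name,
    tiny = synthetic_spec(n_genes = 30, n_blocks = 3, p_in = 0.35,
                          p_out = 0.03, n_cells = 60, n_cell_types = 3,
                          seed = seed),
    sbm_recovery = synthetic_spec(n_genes = 200, n_blocks = 4, p_in = 0.25,
                                  p_out = 0.02, n_cells = 400,
                                  n_cell_types = 4, seed = seed))
  sim <- simulate_graph(spec)
  feats <- simulate_features(sim$blocks, spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    edges = file.path(out_dir, "edges.tsv"),
    counts = file.path(out_dir, "counts.mtx"),
    genes = file.path(out_dir, "genes.txt"),
    cells = file.path(out_dir, "cells.txt"),
    truth = file.path(out_dir, "truth.tsv"),
    cell_types = file.path(out_dir, "cell_types.tsv"))
  write_edge_list(sim$graph, paths$edges)
  write_counts_mtx(feats$counts, paths$counts, paths$genes, paths$cells)
  utils::write.table(
    data.frame(gene = sim$graph$gene_names, block = sim$blocks),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell = colnames(feats$counts), cell_type = feats$cell_types),
    paths$cell_types, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(spec = spec, blocks = sim$blocks,
                          cell_types = feats$cell_types, dir = out_dir)))
}
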