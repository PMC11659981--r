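#' Neighbourhood-expansion configuration
#'
#' @param radius Euclidean search radius in the 2-D embedding (default 0.5;
#'   0.8 was used for the melanoma regulatory-gene search).
#' @param min_cluster minimum initial cluster size including the seed
#'   (strictly more than `min_cluster` genes are required; default 6).
#' @param require_direct_interactor keep only candidates at network distance
#'   1 from the seed gene? (default `TRUE`)
#' @return A `neighbor_config`.
#' @export
neighbor_config <- function(radius = 0.5, min_cluster = 6,
                            require_direct_interactor = TRUE) {
  stopifnot(radius > 0, min_cluster >= 1)
  structure(list(radius = radius, min_cluster = as.integer(min_cluster),
                 require_direct_interactor = isTRUE(require_direct_interactor)),
            class = "neighbor_config")
}

#' Candidate genes by embedding-space neighbourhood expansion
#'
#' For each seed gene: genes within `radius` of the seed in the 2-D
#' embedding form the initial cluster (seed included); seeds whose initial
#' cluster does not exceed `min_cluster` genes yield no candidates. The
#' cluster is then expanded iteratively - any gene within `radius` of any
#' member joins - until no further genes can be added. Finally, genes that
#' are not direct interactors (network distance 1) of the seed are removed
#' when `require_direct_interactor` is set. The seed itself is excluded
#' from the returned candidates.
#'
#' @param coords2d n x 2 embedding coordinates.
#' @param gene_names gene symbols in coordinate order.
#' @param seeds character vector of seed genes; seeds absent from
#'   `gene_names` are reported via a warning and skipped.
#' @param graph the [gene_graph] used for the direct-interactor filter.
#' @param config a [neighbor_config()].
#' @return Named list (one entry per retained seed) of data.frames with
#'   columns `candidate`, `distance_to_seed`, `is_direct_interactor`.
#' @export
neighbor_gene_clusters <- function(coords2d, gene_names, seeds, graph,
                                   config = neighbor_config()) {
  coords2d <- as.matrix(coords2d)
  stopifnot(nrow(coords2d) == length(gene_names))
  missing <- setdiff(seeds, gene_names)
  if (length(missing)) {
    warning("seed genes absent from the embedding, skipped: ",
            paste(missing, collapse = ", "))
  }
  seeds <- intersect(seeds, gene_names)
  r2 <- config$radius^2
  out <- list()
  for (sd_gene in seeds) {
    si <- match(sd_gene, gene_names)
    d2_seed <- rowSums((coords2d - rep(coords2d[si, ], each = nrow(coords2d)))^2)
    initial <- which(d2_seed <= r2)
    if (length(initial) <= config$min_cluster) next
    members <- rep(FALSE, nrow(coords2d))
    members[initial] <- TRUE
    frontier <- initial
    # iterative expansion: anything within radius of a member joins
    while (length(frontier)) {
      cand <- which(!members)
      if (!length(cand)) break
      added <- integer(0)
      for (f in frontier) {
        d2 <- rowSums((coords2d[cand, , drop = FALSE] -
                         rep(coords2d[f, ], each = length(cand)))^2)
        hit <- cand[d2 <= r2]
        if (length(hit)) {
          members[hit] <- TRUE
          added <- c(added, hit)
          cand <- setdiff(cand, hit)
        }
      }
      frontier <- unique(added)
    }
    idx <- setdiff(which(members), si)
    if (!length(idx)) next
    direct <- as.logical(graph$adjacency[si, idx] != 0)
    df <- data.frame(candidate = gene_names[idx],
                     distance_to_seed = sqrt(d2_seed[idx]),
                     is_direct_interactor = direct)
    if (config$require_direct_interactor) {
      df <- df[df$is_direct_interactor, , drop = FALSE]
    }
    df <- df[order(df$distance_to_seed), , drop = FALSE]
    rownames(df) <- NULL
    out[[sd_gene]] <- df
  }
  out
}

#' Write neighbourhood-expansion results as TSV
#' @param neighbors result of [neighbor_gene_clusters()].
#' @param path output path.
#' @export
write_neighbor_clusters <- function(neighbors, path) {
  rows <- lapply(names(neighbors), function(s) {
    cbind(seed = s, neighbors[[s]])
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = character(), candidate = character(),
               distance_to_seed = numeric(), is_direct_interactor = logical())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed-gene list (one symbol per line, '#' comments)
#' @param path file path.
#' @return Character vector of gene symbols.
#' @export
read_seed_genes <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`; 0 when both sets are empty.
#'
#' @param set_a,set_b character vectors.
#' @return Numeric scalar in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' One-sided Fisher enrichment test of a gene set overlap
#'
#' Tests over-representation of `annotated_set` among `cluster_genes` within
#' `universe` (one-sided Fisher's exact test on the 2x2 table; identical to
#' the hypergeometric upper tail). The same test validates
#' neighbourhood-expansion candidates against external gene lists.
#'
#' @param cluster_genes,annotated_set gene sets (subsets of `universe`).
#' @param universe the background gene set.
#' @param n_families number of tests in the family for the adjustment
#'   (e.g. 50 when testing 50 hallmark sets); default 1.
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @return List with `odds_ratio`, `p`, `p_adjusted`, `overlap` and the 2x2
#'   `table`.
#' @export
enrichment_test <- function(cluster_genes, annotated_set, universe,
                            n_families = 1, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  universe <- unique(universe)
  cluster_genes <- intersect(unique(cluster_genes), universe)
  annotated_set <- intersect(unique(annotated_set), universe)
  a <- length(intersect(cluster_genes, annotated_set))
  b <- length(cluster_genes) - a
  cc <- length(annotated_set) - a
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2, 2,
                dimnames = list(c("in_set", "out_set"),
                                c("in_cluster", "out_cluster")))
  ft <- stats::fisher.test(tab, alternative = "greater")
  p_adj <- if (method == "bonferroni") min(1, ft$p.value * n_families) else
    ft$p.value  # BH requires the whole family; see adjust_family()
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, p_adjusted = p_adj,
       overlap = a, table = tab)
}

#' Adjust a family of enrichment p-values
#' @param p numeric vector of raw p-values.
#' @param method `p.adjust` method (default `"bonferroni"`).
#' @return Adjusted p-values.
#' @export
adjust_family <- function(p, method = "bonferroni") {
  stats::p.adjust(p, method = method)
}

#' Tissue-specific cluster calling
#'
#' For every cluster of every tissue, each cluster of each *other* tissue is
#' tested for gene overlap (one-sided Fisher enrichment over the shared
#' universe), p-values are Bonferroni-corrected within the cluster's own
#' comparison family, and a cluster is called tissue specific when fewer
#' than 5% of the other-tissue clusters overlap it significantly
#' (adjusted p < 0.05).
#'
#' @param catalogs named list (tissue -> gene-set list as returned by
#'   [catalog_gene_sets()], or a `cluster_catalog`).
#' @param universe shared background gene set.
#' @param alpha significance level after Bonferroni (default 0.05).
#' @param specific_fraction maximum fraction of significantly overlapping
#'   other-tissue clusters for a specific call (default 0.05).
#' @return data.frame with one row per (tissue, cluster): `tissue`,
#'   `cluster_id`, `n_sig_overlaps`, `total_other_clusters`, `is_specific`.
#' @export
tissue_specific_clusters <- function(catalogs, universe, alpha = 0.05,
                                     specific_fraction = 0.05) {
  if (length(catalogs) < 2) stop("need at least two tissues")
  if (!length(universe)) stop("empty gene universe")
  sets <- lapply(catalogs, function(x) {
    if (inherits(x, "cluster_catalog")) catalog_gene_sets(x) else x
  })
  tissues <- names(sets)
  rows <- list()
  for (t in tissues) {
    others <- tissues[tissues != t]
    other_sets <- unlist(lapply(others, function(o) sets[[o]]),
                         recursive = FALSE)
    total_other <- length(other_sets)
    for (cid in names(sets[[t]])) {
      p <- vapply(other_sets, function(os) {
        enrichment_test(sets[[t]][[cid]], os, universe)$p
      }, numeric(1))
      p_adj <- stats::p.adjust(p, method = "bonferroni")
      n_sig <- sum(p_adj < alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = t, cluster_id = cid, n_sig_overlaps = n_sig,
        total_other_clusters = total_other,
        is_specific = n_sig < specific_fraction * total_other)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Internal vs external closeness centrality of gene clusters
#'
#' Partitions the network's edges into intracluster edges (both endpoints in
#' the same retained cluster) and out-of-cluster edges, computes each gene's
#' closeness centrality separately on the two edge sets (within its
#' connected component, scaled by the reachable fraction; 0 for genes with
#' no reachable peers), averages per cluster, and compares the per-cluster
#' internal vs external means with a Wilcoxon rank-sum test.
#'
#' @param graph a [gene_graph].
#' @param catalog a `cluster_catalog` aligned to the graph's gene order.
#' @return List with `per_cluster` (data.frame: cluster_id, n_genes,
#'   internal_closeness, external_closeness) and `p_value`.
#' @export
closeness_split <- function(graph, catalog) {
  labels <- catalog$labels
  stopifnot(length(labels) == n_genes(graph))
  E <- edge_index(graph)
  same <- !is.na(labels[E[, 1]]) & !is.na(labels[E[, 2]]) &
    labels[E[, 1]] == labels[E[, 2]]
  gn <- graph$gene_names
  internal <- scaled_closeness(E[same, , drop = FALSE], gn)
  external <- scaled_closeness(E[!same, , drop = FALSE], gn)
  ks <- sort(unique(labels[!is.na(labels)]))
  per_cluster <- do.call(rbind, lapply(ks, function(k) {
    idx <- which(!is.na(labels) & labels == k)
    data.frame(cluster_id = k, n_genes = length(idx),
               internal_closeness = mean(internal[idx]),
               external_closeness = mean(external[idx]))
  }))
  p <- if (nrow(per_cluster) >= 1) {
    suppressWarnings(stats::wilcox.test(per_cluster$internal_closeness,
                                        per_cluster$external_closeness,
                                        exact = FALSE, correct = FALSE)$p.value)
  } else NA_real_
  list(per_cluster = per_cluster, p_value = p)
}

# Wasserman-Faust closeness on an edge subset over a fixed node universe:
# for node u with r reachable peers at total distance s (within its
# component), closeness = (r / (n - 1)) * (r / s); 0 when r = 0.
scaled_closeness <- function(edges_ij, gene_names) {
  n <- length(gene_names)
  cl <- numeric(n)
  if (!nrow(edges_ij)) return(cl)
  g <- igraph::graph_from_edgelist(
    cbind(gene_names[edges_ij[, 1]], gene_names[edges_ij[, 2]]),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(gene_names, igraph::V(g)$name))
  D <- igraph::distances(g, mode = "all")
  D <- D[gene_names, gene_names]
  for (u in seq_len(n)) {
    d <- D[u, -u]
    reach <- is.finite(d) & d > 0
    r <- sum(reach)
    if (r > 0) cl[u] <- (r / (n - 1)) * (r / sum(d[reach]))
  }
  cl
}

#' Expression module score with binned control genes
#'
#' Per-cell score of a gene set: mean (pre-scaling, log-CPM) expression of
#' the set's genes minus the mean expression of control genes sampled from
#' matching average-expression bins - the binned-control module score
#' popularized by the Seurat `AddModuleScore` procedure.
#'
#' @param features a [feature_matrix] whose `logcpm` slot is used.
#' @param cluster_genes the gene set to score.
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100; capped at
#'   the bin size).
#' @param seed RNG seed for control sampling.
#' @return Named numeric vector, one score per cell.
#' @export
module_score <- function(features, cluster_genes, n_bins = 24, n_ctrl = 100,
                         seed = 0) {
  expr <- features$logcpm
  if (is.null(expr)) expr <- features$values
  cluster_genes <- intersect(unique(cluster_genes), rownames(expr))
  if (!length(cluster_genes)) stop("no cluster genes present in the features")
  avg <- rowMeans(expr)
  n_bins <- min(n_bins, length(avg))
  # equal-frequency bins on average expression (rank-based)
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- rownames(expr)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ctrl <- character(0)
  for (g in cluster_genes) {
    pool <- names(bins)[bins == bins[[g]]]
    pool <- setdiff(pool, g)
    if (!length(pool)) next
    ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
  }
  ctrl <- unique(ctrl)
  if (!length(ctrl)) stop("no control genes could be sampled")
  score <- colMeans(expr[cluster_genes, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
  score
}
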