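#' Project a latent embedding to two dimensions with t-SNE
#'
#' @param Z latent matrix (n x d) or a `latent_embedding`.
#' @param perplexity t-SNE perplexity (default 30); requires
#'   `n > 3 * perplexity`.
#' @param seed RNG seed; the projection is deterministic given seed.
#' @param exact use the exact (theta = 0) gradient instead of Barnes-Hut?
#'   Default `TRUE`; exact is robust for the gene-set sizes this package
#'   targets.
#' @return Numeric n x 2 matrix of coordinates, rownames preserved.
#' @export
reduce_2d <- function(Z, perplexity = 30, seed = 0, exact = TRUE) {
  if (inherits(Z, "latent_embedding")) Z <- Z$Z
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n <= 3 * perplexity) {
    stop("too few points for perplexity ", perplexity,
         " (need n > 3 * perplexity, got n = ", n, ")")
  }
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  res <- Rtsne::Rtsne(Z, dims = 2, perplexity = perplexity,
                      theta = if (exact) 0 else 0.5,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  coords <- res$Y
  rownames(coords) <- rownames(Z)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

#' Gene cluster catalog
#'
#' Container for a hard gene clustering in the 2-D embedding: per-gene
#' labels (`NA` = unassigned after small-cluster dissolution), the selected
#' number of clusters and its quality indices.
#'
#' @param labels integer cluster id per gene (`NA` allowed).
#' @param coords2d the coordinates the clustering was computed on.
#' @param silhouette,dbi quality indices of the retained assignment.
#' @param min_size dissolution threshold used.
#' @return A `cluster_catalog`.
#' @export
cluster_catalog <- function(labels, coords2d, silhouette, dbi, min_size) {
  keep <- !is.na(labels)
  structure(list(labels = labels, k = length(unique(labels[keep])),
                 silhouette = silhouette, dbi = dbi,
                 coords2d = coords2d, min_size = min_size,
                 linkage = "ward"),
            class = "cluster_catalog")
}

#' @export
print.cluster_catalog <- function(x, ...) {
  cat(sprintf("cluster_catalog: %d clusters over %d genes (%d unassigned), silhouette %.3f, DBI %.3f\n",
              x$k, length(x$labels), sum(is.na(x$labels)), x$silhouette,
              x$dbi))
  invisible(x)
}

#' Cluster genes per catalog as a named list of gene sets
#' @param catalog a `cluster_catalog`.
#' @param gene_names gene symbols in catalog order (default: rownames of the
#'   catalog coordinates).
#' @return Named list, one character vector of genes per retained cluster.
#' @export
catalog_gene_sets <- function(catalog, gene_names = rownames(catalog$coords2d)) {
  keep <- !is.na(catalog$labels)
  split(gene_names[keep], catalog$labels[keep])
}

default_k_range <- function(n) {
  if (n >= 1000) seq(20, 200, by = 5) else seq(2L, max(3L, min(30L, n %/% 8L)))
}

#' Hierarchical gene clustering with silhouette-selected k
#'
#' Builds a Ward-linkage tree on the 2-D coordinates, cuts it at every `k`
#' in `k_range`, and keeps the cut with the maximal mean silhouette width.
#' Clusters with `min_size` or fewer genes are then dissolved (their genes
#' marked unassigned) and the quality indices recomputed on the retained
#' assignment.
#'
#' @param coords2d n x 2 coordinate matrix from [reduce_2d()].
#' @param k_range candidate cluster counts; default 20..200 step 5, scaled
#'   down automatically for n < 1000.
#' @param min_size retained clusters must have more than this many genes
#'   (default 10).
#' @return A [cluster_catalog()] carrying `k_scan`, a data.frame of the
#'   silhouette at every scanned k.
#' @export
hierarchical_clusters <- function(coords2d, k_range = NULL, min_size = 10) {
  coords2d <- as.matrix(coords2d)
  n <- nrow(coords2d)
  if (is.null(k_range)) k_range <- default_k_range(n)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range empty after bounding to [2, n-1]")
  d <- stats::dist(coords2d)
  tree <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    mean(cluster::silhouette(stats::cutree(tree, k), d)[, 3])
  }, numeric(1))
  best_k <- k_range[which.max(sil)]
  labels <- stats::cutree(tree, best_k)

  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes <= min_size])
  labels[labels %in% small] <- NA
  if (all(is.na(labels))) {
    stop("all clusters dissolved by the min_size filter (min_size = ",
         min_size, ")")
  }
  keep <- !is.na(labels)
  retained <- labels[keep]
  if (length(unique(retained)) >= 2) {
    qm <- clustering_metrics(coords2d[keep, , drop = FALSE], retained)
  } else {
    qm <- list(silhouette = NA_real_, dbi = NA_real_)
  }
  out <- cluster_catalog(labels, coords2d, qm$silhouette, qm$dbi, min_size)
  out$k_scan <- data.frame(k = k_range, silhouette = sil)
  out$selected_k <- best_k
  out
}

#' Internal clustering quality indices
#'
#' Mean silhouette width and the Davies-Bouldin index under the Euclidean
#' metric.
#'
#' @param coords2d coordinate matrix.
#' @param labels cluster label per row (at least two clusters, each of
#'   size >= 2; no NA).
#' @return List with `silhouette` and `dbi`.
#' @export
clustering_metrics <- function(coords2d, labels) {
  coords2d <- as.matrix(coords2d)
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stop("need at least two clusters")
  if (min(table(labels)) < 2) stop("every cluster must have size >= 2")
  sil <- mean(cluster::silhouette(labels, stats::dist(coords2d))[, 3])
  # Davies-Bouldin: mean over clusters of max_j (s_i + s_j) / d(c_i, c_j),
  # with s_i the mean distance of members to their centroid
  ks <- sort(unique(labels))
  centroids <- t(vapply(ks, function(k) {
    colMeans(coords2d[labels == k, , drop = FALSE])
  }, numeric(ncol(coords2d))))
  scatter <- vapply(seq_along(ks), function(ki) {
    pts <- coords2d[labels == ks[ki], , drop = FALSE]
    mean(sqrt(rowSums((pts - rep(centroids[ki, ], each = nrow(pts)))^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  db <- vapply(seq_along(ks), function(i) {
    r <- (scatter[i] + scatter[-i]) / cd[i, -i]
    max(r)
  }, numeric(1))
  list(silhouette = sil, dbi = mean(db))
}

#' Hopkins statistic of spatial clustering tendency
#'
#' Compares nearest-neighbour distances of uniform reference points (drawn
#' in the bounding box) with those of sampled data points; values near 1
#' indicate strong aggregation, near 0.5 spatial randomness.
#'
#' @param coords point matrix.
#' @param m number of probes per resample
#'   (default `min(floor(n/10), 100)`, at least 2).
#' @param n_resamples number of seeded resamples averaged (default 20).
#' @param seed RNG seed.
#' @return Numeric scalar in `[0, 1]`.
#' @export
hopkins_statistic <- function(coords, m = NULL, n_resamples = 20, seed = 0) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(m)) m <- max(2L, min(n %/% 10L, 100L))
  m <- min(m, n - 1L)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  vals <- vapply(seq_len(n_resamples), function(r) {
    probes <- sample.int(n, m)
    u_pts <- sapply(seq_along(lo), function(dmn) stats::runif(m, lo[dmn], hi[dmn]))
    u_pts <- matrix(u_pts, nrow = m)
    # NN distance of each uniform point to the data
    u <- apply(u_pts, 1, function(p) {
      min(sqrt(colSums((t(coords) - p)^2)))
    })
    # NN distance of each probe to the remaining data
    w <- vapply(probes, function(ix) {
      dd <- sqrt(colSums((t(coords[-ix, , drop = FALSE]) - coords[ix, ])^2))
      min(dd)
    }, numeric(1))
    sum(u) / (sum(u) + sum(w))
  }, numeric(1))
  mean(vals)
}

#' Degree-stratified hub aggregation diagnostic
#'
#' Ranks genes by network degree, splits them into `n_degree_groups`
#' equal-size strata (highest degrees first; ties broken by gene name),
#' takes the `top_per_group` highest-degree genes of each stratum as hubs,
#' forms each hub's point set (hub + its network neighbours) and reports
#' the Hopkins statistic of the hub-set centroids in the 2-D embedding,
#' per stratum.
#'
#' @param graph a [gene_graph].
#' @param coords2d 2-D coordinates aligned to the graph's gene order.
#' @param n_degree_groups number of degree strata (default 20).
#' @param top_per_group hubs per stratum (default 100).
#' @param seed seed for the Hopkins resamples.
#' @return data.frame with columns `group`, `min_degree`, `max_degree`,
#'   `n_hubs`, `hopkins`; the per-group hub gene sets are attached as
#'   `attr(, "hubs")`.
#' @export
hub_aggregation_diagnostic <- function(graph, coords2d, n_degree_groups = 20,
                                       top_per_group = 100, seed = 0) {
  n <- n_genes(graph)
  if (n < n_degree_groups) stop("need at least as many genes as degree groups")
  coords2d <- as.matrix(coords2d)
  ord <- order(-graph$degrees, graph$gene_names)
  group_of <- rep(seq_len(n_degree_groups),
                  each = ceiling(n / n_degree_groups))[seq_len(n)]
  adj <- graph$adjacency
  hub_sets <- vector("list", n_degree_groups)
  rows <- lapply(seq_len(n_degree_groups), function(g) {
    members <- ord[group_of == g]
    hubs <- members[seq_len(min(top_per_group, length(members)))]
    hub_sets[[g]] <<- graph$gene_names[hubs]
    centroids <- t(vapply(hubs, function(h) {
      pts <- c(h, which(adj[h, ] != 0))
      colMeans(coords2d[pts, , drop = FALSE])
    }, numeric(2)))
    hop <- if (nrow(centroids) >= 5) {
      hopkins_statistic(centroids, seed = seed)
    } else NA_real_
    data.frame(group = g,
               min_degree = min(graph$degrees[members]),
               max_degree = max(graph$degrees[members]),
               n_hubs = length(hubs), hopkins = hop)
  })
  out <- do.call(rbind, rows)
  attr(out, "hubs") <- hub_sets
  out
}

#' Write a cluster catalog as TSV (gene, cluster_id, coord_x, coord_y)
#' @param catalog a `cluster_catalog`.
#' @param path output path.
#' @param gene_names gene symbols (default rownames of the coords).
#' @export
write_cluster_catalog <- function(catalog, path,
                                  gene_names = rownames(catalog$coords2d)) {
  utils::write.table(
    data.frame(gene = gene_names,
               cluster_id = ifelse(is.na(catalog$labels), "NA",
                                   as.character(catalog$labels)),
               coord_x = catalog$coords2d[, 1],
               coord_y = catalog$coords2d[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
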