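# shared fixture builders (all seeded, generated at test time)

# Erdos-Renyi gene graph over n nodes, edge prob p
random_gene_graph <- function(n, p, seed) {
  set.seed(seed)
  ut <- which(upper.tri(matrix(0, n, n)))
  ii <- ((ut - 1) %% n) + 1
  jj <- ((ut - 1) %/% n) + 1
  draw <- runif(length(ut)) < p
  gn <- sprintf("g%03d", seq_len(n))
  gene_graph(cbind(gn[ii[draw]], gn[jj[draw]]), gene_names = gn)
}

# Newman modularity of a hard partition, brute-force double loop
newman_modularity <- function(graph, labels) {
  A <- as.matrix(graph$adjacency)
  d <- graph$degrees
  two_m <- 2 * graph$m
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) q <- q + A[i, j] - d[i] * d[j] / two_m
    }
  }
  q / two_m
}

# gene x cell random count matrix
random_counts <- function(n_genes, n_cells, seed, lambda = 2) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  m
}

# small trained fit on the tiny synthetic bundle (shared by several tests)
tiny_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- fixture_bundle("tiny", seed = 0, out_dir = tempfile("tinyfit"))
    graph <- load_edge_list(fx$edges)
    counts <- read_counts_mtx(fx$counts, fx$genes, fx$cells)
    feats <- align_genes(graph, preprocess_features(counts,
                                                    min_genes_expressed = 5))
    cfg <- train_config(learning_rate = 1e-2, epochs = 40,
                        encoder = encoder_config(c(16, 4)), seed = 1)
    cache <<- list(fit = genevec(graph, feats, cfg), graph = graph,
                   feats = feats, fx = fx)
    cache
  }
})

# independent oracle for neighbourhood expansion: connected component of the
# seed in the radius graph, gated on the initial ball size, then filtered to
# direct interactors of the seed
expansion_oracle <- function(coords, gene_names, seed_gene, graph, config) {
  si <- match(seed_gene, gene_names)
  D <- as.matrix(stats::dist(coords))
  ball <- which(D[si, ] <= config$radius)
  if (length(ball) <= config$min_cluster) return(character(0))
  adj <- D <= config$radius
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  members <- setdiff(which(comp == comp[si]), si)
  if (config$require_direct_interactor) {
    members <- members[graph$adjacency[si, members] != 0]
  }
  sort(gene_names[members])
}

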