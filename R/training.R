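#' Training configuration
#'
#' Bundles the model and optimizer hyperparameters. Defaults are the
#' selected settings from the hyperparameter sweep that the method was
#' tuned with: `lambda = 1`, `beta = 10`, `gamma = 0.1`, `s = 10`, a
#' 256-64-16 encoder, Adam with learning rate 1e-4, 600 epochs and 10
#' replicate runs.
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs number of full-batch epochs (default 600).
#' @param beta weight of the soft-modularity term (default 10).
#' @param gamma Gaussian-kernel bandwidth of the soft-modularity term
#'   (default 0.1).
#' @param lambda_weight weight of community links in the enhanced adjacency
#'   (default 1).
#' @param sparsity_s community-link sparsity (representatives per node,
#'   default 10).
#' @param encoder an [encoder_config()].
#' @param seed base RNG seed (default 0).
#' @param replicates replicate runs for [replicate_and_select()]
#'   (default 10).
#' @param resolution Louvain resolution (default 1).
#' @param fractions train/validation/test edge fractions
#'   (default `c(0.90, 0.05, 0.05)`).
#' @param reconstruct_an reconstruct the enhanced adjacency's support
#'   instead of the plain training adjacency? (default `FALSE`)
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 600, beta = 10,
                         gamma = 0.1, lambda_weight = 1, sparsity_s = 10,
                         encoder = encoder_config(), seed = 0,
                         replicates = 10, resolution = 1,
                         fractions = c(0.90, 0.05, 0.05),
                         reconstruct_an = FALSE) {
  stopifnot(learning_rate > 0, epochs >= 0, beta > 0, gamma > 0,
            lambda_weight > 0, sparsity_s >= 1, replicates >= 1,
            inherits(encoder, "encoder_config"))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 beta = beta, gamma = gamma, lambda_weight = lambda_weight,
                 sparsity_s = as.integer(sparsity_s), encoder = encoder,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 resolution = resolution, fractions = fractions,
                 reconstruct_an = isTRUE(reconstruct_an)),
            class = "train_config")
}

#' Split edges into train/validation/test sets with matched negatives
#'
#' Positive edges are shuffled (seeded) and split 90/5/5 by default;
#' an equal number of negative (non-adjacent, unordered) gene pairs is
#' sampled uniformly without replacement and partitioned into sets of the
#' same sizes. Negative sets contain no true edges and no duplicates.
#'
#' @param graph a [gene_graph].
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed.
#' @return An `edge_split`: integer matrices `train_pos`, `val_pos`,
#'   `test_pos`, `train_neg`, `val_neg`, `test_neg` (columns `i`, `j` with
#'   i < j), plus `fractions`, `seed` and `n_genes`.
#' @export
split_edges <- function(graph, fractions = c(0.90, 0.05, 0.05), seed = 0) {
  stopifnot(inherits(graph, "gene_graph"), length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  E <- edge_index(graph)
  ne <- nrow(E)
  n <- n_genes(graph)
  n_val <- floor(ne * fractions[2])
  n_test <- floor(ne * fractions[3])
  if (n_val < 1L || n_test < 1L) {
    stop("graph too small: validation/test splits would be empty")
  }
  n_nonedges <- n * (n - 1) / 2 - ne
  if (ne > n_nonedges) stop("graph too dense to sample matched negatives")

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(ne)
  val_idx <- perm[seq_len(n_val)]
  test_idx <- perm[n_val + seq_len(n_test)]
  train_idx <- perm[-seq_len(n_val + n_test)]

  edge_key <- E[, 1] + (E[, 2] - 1) * n
  neg <- sample_negative_pairs(n, ne, edge_key)

  structure(list(
    train_pos = E[train_idx, , drop = FALSE],
    val_pos = E[val_idx, , drop = FALSE],
    test_pos = E[test_idx, , drop = FALSE],
    train_neg = neg[seq_along(train_idx), , drop = FALSE],
    val_neg = neg[length(train_idx) + seq_len(n_val), , drop = FALSE],
    test_neg = neg[length(train_idx) + n_val + seq_len(n_test), , drop = FALSE],
    fractions = fractions, seed = as.integer(seed), n_genes = n
  ), class = "edge_split")
}

# uniform sample of `count` unordered non-adjacent pairs, no duplicates
sample_negative_pairs <- function(n, count, edge_key) {
  if (n <= 1500) {
    # enumerate all unordered pairs, drop edges, sample directly
    ut <- which(upper.tri(matrix(0, n, n)))
    ii <- ((ut - 1) %% n) + 1
    jj <- ((ut - 1) %/% n) + 1
    keys <- ii + (jj - 1) * n
    pool <- which(!(keys %in% edge_key))
    sel <- pool[sample.int(length(pool), count)]
    return(cbind(i = ii[sel], j = jj[sel]))
  }
  found <- integer(0)
  while (length(found) < count) {
    need <- count - length(found)
    a <- sample.int(n, 3 * need + 16, replace = TRUE)
    b <- sample.int(n, 3 * need + 16, replace = TRUE)
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- lo + (hi - 1) * n
    ok <- lo != hi & !(key %in% edge_key) & !(key %in% found) & !duplicated(key)
    found <- c(found, key[ok][seq_len(min(need, sum(ok)))])
  }
  lo <- ((found - 1) %% n) + 1
  hi <- ((found - 1) %/% n) + 1
  cbind(i = lo, j = hi)
}

#' @export
print.edge_split <- function(x, ...) {
  cat(sprintf("edge_split: %d/%d/%d positive edges (train/val/test), matched negatives, seed %d\n",
              nrow(x$train_pos), nrow(x$val_pos), nrow(x$test_pos), x$seed))
  invisible(x)
}

# area under the ROC curve for scores of positive/negative pairs
link_auroc <- function(pos_scores, neg_scores) {
  as.numeric(pROC::auc(
    response = c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores))),
    predictor = c(pos_scores, neg_scores),
    quiet = TRUE, direction = "<", levels = c(0L, 1L)))
}

# average precision (area under precision-recall via step interpolation)
link_ap <- function(pos_scores, neg_scores) {
  y <- c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores)))
  s <- c(pos_scores, neg_scores)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  sum(precision[y == 1L]) / sum(y)
}

pair_logits <- function(Z, pairs) {
  rowSums(Z[pairs[, 1], , drop = FALSE] * Z[pairs[, 2], , drop = FALSE])
}

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else array(0, dim(p))
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^state$t)
    vhat <- v / (1 - b2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      for (l in seq_along(params[[nm]])) {
        r <- upd(params[[nm]][[l]], grads[[nm]][[l]],
                 state$m[[nm]][[l]], state$v[[nm]][[l]])
        params[[nm]][[l]] <- r$p
        state$m[[nm]][[l]] <- r$m
        state$v[[nm]][[l]] <- r$v
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
      params[[nm]] <- r$p
      state$m[[nm]] <- r$m
      state$v[[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

#' Fit the community-augmented variational graph autoencoder
#'
#' The main fitting function. Splits the network's edges 90/5/5 with matched
#' negatives, detects Louvain communities on the training graph only,
#' builds the enhanced adjacency `A_n = A_train + lambda * A_c(s)`, and
#' trains the variational GCN encoder with full-batch Adam to minimize
#' `recon + KL - soft-modularity`. Held-out edges never enter the
#' propagation graph, the reconstruction target or the modularity term.
#'
#' @param graph a [gene_graph].
#' @param features a [feature_matrix]; aligned to the graph automatically if
#'   the gene order differs.
#' @param config a [train_config()].
#' @param project also compute the 2-D t-SNE projection and the
#'   silhouette-selected hierarchical gene clusters? (default `FALSE`)
#' @param perplexity t-SNE perplexity when `project = TRUE` (default 30,
#'   reduced automatically for small gene sets).
#' @param min_size minimum retained cluster size when `project = TRUE`
#'   (default 10).
#' @param verbose print a progress line every 50 epochs?
#' @return An object of class `genevec` with elements `embedding`
#'   (`latent_embedding`), `history` (per-epoch data.frame: epoch, recon,
#'   kl — the KL contribution to the objective, i.e. the per-node-mean KL
#'   scaled by 1/n — modularity, total, val_auc, val_ap), `metrics` (val/test AUROC and
#'   average precision), `split`, `communities`, `enhanced`, `params`,
#'   `config`, `gene_names`, and (when `project = TRUE`) `catalog`.
#' @seealso [replicate_and_select()], [reduce_2d()],
#'   [hierarchical_clusters()], [predict.genevec()], [plot.genevec()]
#' @export
genevec <- function(graph, features, config = train_config(),
                    project = FALSE, perplexity = 30, min_size = 10,
                    verbose = FALSE) {
  stopifnot(inherits(graph, "gene_graph"), inherits(config, "train_config"))
  if (!identical(features$gene_names, graph$gene_names)) {
    features <- align_genes(graph, features)
  }
  n <- n_genes(graph)
  split <- split_edges(graph, config$fractions, config$seed)
  train_graph <- graph_from_edge_index(split$train_pos, graph$gene_names)
  communities <- detect_primary_communities(train_graph, config$resolution,
                                            config$seed)
  A_c <- community_matrix(communities)
  A_cs <- sparsify_community(A_c, communities, train_graph, config$sparsity_s)
  enhanced <- enhance_adjacency(train_graph, A_cs, config$lambda_weight,
                                config$sparsity_s)
  S <- gcn_propagation_matrix(enhanced)
  X <- features$values

  target <- as.matrix(train_graph$adjacency)
  if (config$reconstruct_an) target <- (as.matrix(enhanced$matrix) > 0) * 1
  n_pos <- sum(target)
  if (n_pos == 0) stop("empty reconstruction target")
  pos_weight <- (n^2 - n_pos) / n_pos
  norm <- n^2 / (2 * (n^2 - n_pos))
  # reference-VGAE convention: the loss target carries self-loops (A + I),
  # while pos_weight/norm are computed from the plain adjacency; the
  # diagonal positives anchor ||z_i|| away from the collapsed origin
  diag(target) <- 1
  two_m <- 2 * train_graph$m
  B <- as.matrix(train_graph$adjacency) -
    outer(train_graph$degrees, train_graph$degrees) / two_m
  c_mod <- config$beta / two_m
  kl_weight <- 1 / n  # reference-VGAE scaling of the KL term

  params <- init_params(config$encoder, ncol(X), config$seed)
  state <- adam_init(params)
  history <- vector("list", config$epochs)

  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  latent <- config$encoder$latent_dim
  n_hidden <- length(config$encoder$layer_dims) - 1L
  dims_hidden <- config$encoder$layer_dims[seq_len(n_hidden)]
  dropout <- config$encoder$dropout

  for (epoch in seq_len(config$epochs)) {
    eps <- matrix(stats::rnorm(n * latent), n, latent)
    masks <- NULL
    if (dropout > 0) {
      masks <- lapply(dims_hidden, function(d) {
        matrix(stats::rbinom(n * d, 1, 1 - dropout) / (1 - dropout), n, d)
      })
    }
    emb <- gcn_encode(enhanced, X, config$encoder, params, sample = TRUE,
                      eps = eps, propagation = S, keep_cache = TRUE,
                      masks = masks)
    logits <- tcrossprod(emb$Z)
    el <- elbo_loss(logits, target, emb$mu, emb$logvar, pos_weight, norm)
    mod <- modularity_loss(emb$Z, train_graph, config$beta, config$gamma)
    kl_contrib <- kl_weight * el$kl
    tot <- tryCatch(
      total_loss(el$recon, el$kl, mod, kl_weight = kl_weight),
      error = function(e) {
        stop("training diverged (non-finite loss) at epoch ", epoch)
      })
    g <- loss_gradients(emb$Z, emb$mu, emb$logvar, eps, target, pos_weight,
                        norm, B, c_mod, config$gamma, n,
                        kl_weight = kl_weight)
    grads <- encoder_gradients(emb, params, g$dmu, g$dlogvar)
    names(grads) <- c("W", "W_mu", "W_logvar")
    st <- adam_step(params, grads, state, config$learning_rate)
    params <- st$params
    state <- st$state

    val_scores_p <- pair_logits(emb$mu, split$val_pos)
    val_scores_n <- pair_logits(emb$mu, split$val_neg)
    history[[epoch]] <- data.frame(
      epoch = epoch, recon = el$recon, kl = kl_contrib, modularity = mod,
      total = tot,
      val_auc = link_auroc(val_scores_p, val_scores_n),
      val_ap = link_ap(val_scores_p, val_scores_n))
    if (verbose && epoch %% 50 == 0) {
      message(sprintf("epoch %4d  total %.4f  recon %.4f  kl %.4f  mod %.4f  val_auc %.3f",
                      epoch, tot, el$recon, el$kl, mod,
                      history[[epoch]]$val_auc))
    }
  }
  history <- if (config$epochs > 0) do.call(rbind, history) else
    data.frame(epoch = integer(), recon = numeric(), kl = numeric(),
               modularity = numeric(), total = numeric(),
               val_auc = numeric(), val_ap = numeric())

  embedding <- gcn_encode(enhanced, X, config$encoder, params,
                          sample = FALSE, propagation = S)
  embedding$cache <- NULL; embedding$S <- NULL; embedding$head_input <- NULL
  Z <- embedding$mu
  metrics <- list(
    val_auroc = link_auroc(pair_logits(Z, split$val_pos),
                           pair_logits(Z, split$val_neg)),
    val_ap = link_ap(pair_logits(Z, split$val_pos),
                     pair_logits(Z, split$val_neg)),
    test_auroc = link_auroc(pair_logits(Z, split$test_pos),
                            pair_logits(Z, split$test_neg)),
    test_ap = link_ap(pair_logits(Z, split$test_pos),
                      pair_logits(Z, split$test_neg)))

  fit <- structure(list(
    embedding = embedding, history = history, metrics = metrics,
    split = split, communities = communities, enhanced = enhanced,
    params = params, config = config, gene_names = graph$gene_names,
    graph = graph, catalog = NULL
  ), class = "genevec")

  if (project) {
    perp <- min(perplexity, floor((n - 2) / 3))
    fit$embedding$coords2d <- reduce_2d(Z, perplexity = perp,
                                        seed = config$seed)
    fit$catalog <- hierarchical_clusters(fit$embedding$coords2d,
                                         min_size = min_size)
  }
  fit
}

#' Fit replicate models and keep the best-clustering run
#'
#' Runs [genevec()] `n_runs` times with seeds `seed + 0 ... seed + n_runs-1`,
#' clusters each run's embedding, and returns the run whose (post-dissolution)
#' silhouette coefficient is maximal. Failing runs are skipped; an error is
#' raised only if every run fails.
#'
#' @param graph a [gene_graph].
#' @param features a [feature_matrix].
#' @param config a [train_config()]; `config$replicates` is the default
#'   number of runs.
#' @param n_runs number of replicate fits (default `config$replicates`).
#' @param perplexity,min_size forwarded to the projection/clustering step.
#' @return List with `best` (the selected `genevec` fit, including its
#'   cluster catalog), `runs` (a data.frame of seed, silhouette, k,
#'   test_auroc per run) and `errors` (messages of failed runs).
#' @export
replicate_and_select <- function(graph, features, config = train_config(),
                                 n_runs = config$replicates,
                                 perplexity = 30, min_size = 10) {
  stopifnot(n_runs >= 1)
  fits <- vector("list", n_runs)
  rows <- vector("list", n_runs)
  errors <- character()
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    res <- tryCatch(
      genevec(graph, features, cfg, project = TRUE,
              perplexity = perplexity, min_size = min_size),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("seed %d: %s", cfg$seed, conditionMessage(res)))
      next
    }
    fits[[r]] <- res
    rows[[r]] <- data.frame(seed = cfg$seed,
                            silhouette = res$catalog$silhouette,
                            k = res$catalog$k,
                            test_auroc = res$metrics$test_auroc)
  }
  runs <- do.call(rbind, rows)
  if (is.null(runs) || !nrow(runs)) {
    stop("all replicate runs failed:\n", paste(errors, collapse = "\n"))
  }
  ok <- which(!vapply(fits, is.null, TRUE))
  best <- ok[which.max(vapply(fits[ok], function(f) f$catalog$silhouette, 0))]
  list(best = fits[[best]], runs = runs, errors = errors)
}
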