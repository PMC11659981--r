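#' Encoder configuration
#'
#' Layer widths for the graph-convolutional encoder. The final entry is the
#' latent dimension; the last layer branches into two heads producing the
#' posterior mean and log-variance.
#'
#' @param layer_dims integer vector of layer widths, at least 2 entries
#'   (default `c(256, 64, 16)`).
#' @param dropout dropout rate in `[0, 1)` applied to hidden activations
#'   during training (default 0).
#' @return An `encoder_config`.
#' @export
encoder_config <- function(layer_dims = c(256, 64, 16), dropout = 0) {
  layer_dims <- as.integer(layer_dims)
  if (length(layer_dims) < 2L) stop("encoder needs at least 2 layers")
  if (any(layer_dims <= 0L)) stop("all layer dims must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(layer_dims = layer_dims,
                 latent_dim = layer_dims[length(layer_dims)],
                 activation = "relu", dropout = dropout),
            class = "encoder_config")
}

glorot_uniform <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

#' Initialize encoder parameters (Glorot uniform)
#'
#' @param config an [encoder_config()].
#' @param in_dim number of input features (columns of X).
#' @param seed RNG seed.
#' @return List with hidden-layer weights `W` (list) and the two variational
#'   heads `W_mu`, `W_logvar`.
#' @export
init_params <- function(config, in_dim, seed = 0) {
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dims <- c(in_dim, config$layer_dims)
  L <- length(config$layer_dims)
  W <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) W[[l]] <- glorot_uniform(dims[l], dims[l + 1L])
  list(W = W,
       W_mu = glorot_uniform(dims[L], dims[L + 1L]),
       W_logvar = glorot_uniform(dims[L], dims[L + 1L]))
}

#' Symmetric degree-normalized propagation matrix
#'
#' Adds self-loops to the (possibly weighted) adjacency and returns
#' `D^{-1/2} (A + I) D^{-1/2}`, the standard GCN propagation operator.
#'
#' @param A_n an `enhanced_adjacency`, or any symmetric nonnegative matrix.
#' @return Dense numeric matrix.
#' @export
gcn_propagation_matrix <- function(A_n) {
  A <- if (inherits(A_n, "enhanced_adjacency")) A_n$matrix else A_n
  A <- as.matrix(A)
  diag(A) <- diag(A) + 1
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

relu <- function(x) (x > 0) * x

#' Encode genes into latent space with the variational GCN
#'
#' Forward pass `Z = GCN(A_n, X)`: hidden layers are shared ReLU graph
#' convolutions over the normalized enhanced adjacency; the final layer has
#' separate linear heads for the posterior mean `mu` and log-variance.
#' With `sample = TRUE`, `Z = mu + exp(logvar / 2) * eps` with standard
#' normal `eps`; otherwise `Z = mu`.
#'
#' @param A_n an `enhanced_adjacency` (or precomputed propagation matrix via
#'   `propagation`).
#' @param X a [feature_matrix] or numeric matrix aligned to the graph.
#' @param config an [encoder_config()].
#' @param params parameters from [init_params()].
#' @param sample draw a reparameterized latent sample? (default `FALSE`)
#' @param seed RNG seed for `eps` when sampling.
#' @param eps optional fixed noise matrix (overrides `seed`; used for
#'   gradient checking).
#' @param propagation optional precomputed dense propagation matrix.
#' @param keep_cache keep forward activations for backprop? (internal)
#' @param masks optional list of per-hidden-layer dropout masks (internal;
#'   applied multiplicatively after the ReLU).
#' @return A `latent_embedding`: list with `mu`, `logvar`, `Z` (n x latent),
#'   and optionally `coords2d` (filled later by [reduce_2d()]).
#' @export
gcn_encode <- function(A_n, X, config, params, sample = FALSE, seed = 0,
                       eps = NULL, propagation = NULL, keep_cache = FALSE,
                       masks = NULL) {
  S <- if (is.null(propagation)) gcn_propagation_matrix(A_n) else propagation
  Xm <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  gene_names <- rownames(Xm)
  if (nrow(Xm) != nrow(S)) stop("X rows must match adjacency dimension")
  L <- length(config$layer_dims)
  H <- Xm
  cache <- if (keep_cache) list(H = vector("list", L - 1L),
                                SH = vector("list", L - 1L),
                                pre = vector("list", L - 1L)) else NULL
  for (l in seq_len(L - 1L)) {
    SH <- S %*% (H %*% params$W[[l]])
    if (any(!is.finite(SH))) stop("NaN in forward pass at hidden layer ", l)
    if (keep_cache) { cache$H[[l]] <- H; cache$pre[[l]] <- SH }
    H <- relu(SH)
    if (!is.null(masks)) H <- H * masks[[l]]
  }
  if (keep_cache) cache$masks <- masks
  SHfin <- H  # input to the heads
  mu <- as.matrix(S %*% (SHfin %*% params$W_mu))
  logvar <- as.matrix(S %*% (SHfin %*% params$W_logvar))
  if (any(!is.finite(mu)) || any(!is.finite(logvar))) {
    stop("NaN in forward pass at variational heads")
  }
  if (sample) {
    if (is.null(eps)) {
      old <- .Random.seed_store()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    }
    Z <- mu + exp(logvar / 2) * eps
  } else {
    eps <- NULL
    Z <- mu
  }
  rownames(mu) <- rownames(logvar) <- rownames(Z) <- gene_names
  structure(list(mu = mu, logvar = logvar, Z = Z, eps = eps,
                 coords2d = NULL, cache = cache, S = if (keep_cache) S else NULL,
                 head_input = if (keep_cache) SHfin else NULL),
            class = "latent_embedding")
}

#' @export
print.latent_embedding <- function(x, ...) {
  cat("latent_embedding:", nrow(x$Z), "genes x", ncol(x$Z), "latent dims",
      if (!is.null(x$coords2d)) "(+ 2-D projection)" else "", "\n")
  invisible(x)
}

#' Inner-product decoder
#'
#' Reconstructed edge probabilities `sigmoid(Z Z^T)`.
#'
#' @param Z latent matrix (n x d) or a `latent_embedding`.
#' @return Dense symmetric matrix of probabilities in (0, 1).
#' @export
decode <- function(Z) {
  if (inherits(Z, "latent_embedding")) Z <- Z$Z
  stopifnot(all(is.finite(Z)))
  stats::plogis(tcrossprod(Z))
}

# numerically stable softplus log(1 + exp(x))
softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

#' Evidence-lower-bound loss components
#'
#' Reconstruction term: `norm`-scaled, positive-class-weighted binary
#' cross-entropy (mean over all ordered node pairs) between decoder logits
#' and the target adjacency. KL term: mean over nodes of the closed-form KL
#' between `N(mu, diag(exp(logvar)))` and `N(0, I)`.
#'
#' @param logits dense n x n matrix of decoder logits (`Z Z^T`).
#' @param target binary adjacency matrix of the same shape.
#' @param mu,logvar variational posterior parameters (n x d).
#' @param pos_weight weight multiplying the positive-class term; the
#'   reference convention is `(n^2 - 2m) / (2m)`.
#' @param norm overall scale; reference convention `n^2 / (2 (n^2 - 2m))`.
#' @return List with numeric scalars `recon` and `kl`.
#' @export
elbo_loss <- function(logits, target, mu, logvar, pos_weight, norm) {
  if (pos_weight <= 0) stop("pos_weight must be positive")
  target <- as.matrix(target)
  stopifnot(identical(dim(logits), dim(target)))
  bce <- pos_weight * target * softplus(-logits) +
    (1 - target) * softplus(logits)
  recon <- norm * mean(bce)
  kl <- 0.5 * sum(exp(logvar) + mu^2 - 1 - logvar) / nrow(mu)
  list(recon = recon, kl = kl)
}

#' Soft-modularity score of an embedding
#'
#' Kernel-relaxed modularity
#' `(beta / 2m) * sum_{i,j} (A_ij - d_i d_j / 2m) * exp(-gamma * ||z_i - z_j||^2)`,
#' where the Gaussian kernel on embedding distances replaces the hard
#' same-community indicator of Newman modularity. Larger is better; the
#' training objective subtracts this score so that gradient descent
#' maximizes it. The exact double sum is used when `n <= max_exact_n`;
#' beyond that the null-model part is estimated from a seeded uniform
#' sample of `pair_sample` node pairs (the edge part stays exact).
#'
#' @param Z latent matrix (n x d) or `latent_embedding`.
#' @param graph the [gene_graph] providing `A`, degrees and `m`.
#' @param beta weight of the community-structure term (default 10).
#' @param gamma kernel bandwidth on squared distances (default 0.1).
#' @param max_exact_n exact computation threshold (default 2000).
#' @param pair_sample number of sampled pairs in the approximate regime.
#' @param seed seed for pair sampling.
#' @return Numeric scalar score.
#' @export
modularity_loss <- function(Z, graph, beta = 10, gamma = 0.1,
                            max_exact_n = 2000, pair_sample = 2e6, seed = 0) {
  if (inherits(Z, "latent_embedding")) Z <- Z$Z
  stopifnot(beta > 0, gamma > 0)
  if (graph$m == 0L) stop("graph has no edges (m = 0)")
  n <- nrow(Z)
  two_m <- 2 * graph$m
  d <- graph$degrees
  if (n <= max_exact_n) {
    K <- exp(-gamma * sqdist_matrix(Z))
    B <- as.matrix(graph$adjacency) - outer(d, d) / two_m
    return(beta / two_m * sum(B * K))
  }
  # large-n estimate: exact over edges, sampled over the degree-null term
  e <- edge_index(graph)
  kr <- exp(-gamma * rowSums((Z[e[, 1], , drop = FALSE] -
                                Z[e[, 2], , drop = FALSE])^2))
  edge_part <- 2 * sum(kr)
  old <- .Random.seed_store(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  si <- sample.int(n, pair_sample, replace = TRUE)
  sj <- sample.int(n, pair_sample, replace = TRUE)
  w <- d[si] * d[sj] / two_m
  kk <- exp(-gamma * rowSums((Z[si, , drop = FALSE] - Z[sj, , drop = FALSE])^2))
  null_part <- mean(w * kk) * as.numeric(n)^2
  beta / two_m * (edge_part - null_part)
}

sqdist_matrix <- function(Z) {
  sq <- rowSums(Z^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  D[D < 0] <- 0
  D
}

#' Combine loss components into the minimized objective
#'
#' The optimizer minimizes `recon + kl - modularity`, so that descent
#' simultaneously maximizes the reconstruction ELBO and the soft-modularity
#' score.
#'
#' @param recon,kl,modularity numeric scalars (see [elbo_loss()],
#'   [modularity_loss()]).
#' @param kl_weight weight of the KL term in the objective (default 1).
#'   Training uses `1/n`, the reference-VGAE scaling, under which the KL of
#'   [elbo_loss()] (a per-node mean) enters the objective as
#'   `0.5 / n^2 * sum(...)`.
#' @return Numeric scalar total loss.
#' @export
total_loss <- function(recon, kl, modularity, kl_weight = 1) {
  total <- recon + kl_weight * kl - modularity
  if (!is.finite(total)) stop("non-finite total loss")
  total
}

# ---- gradients (internal) --------------------------------------------------

# gradient of the minimized objective w.r.t. Z, mu, logvar given the forward
# quantities; target is the dense binary adjacency, B the modularity null
# matrix (A - d d^T / 2m), c_mod = beta / 2m.
loss_gradients <- function(Z, mu, logvar, eps, target, pos_weight, norm,
                           B, c_mod, gamma, n_nodes, kl_weight = 1) {
  n2 <- length(target)
  logits <- tcrossprod(Z)
  sig <- stats::plogis(logits)
  G <- (pos_weight * target * (sig - 1) + (1 - target) * sig) * (norm / n2)
  dZ <- (G + t(G)) %*% Z
  # modularity: minimized term is -score
  K <- exp(-gamma * sqdist_matrix(Z))
  Wk <- B * K
  r <- rowSums(Wk)
  dZ <- dZ + 4 * gamma * c_mod * (r * Z - Wk %*% Z)
  dmu <- dZ
  dlogvar <- matrix(0, nrow(mu), ncol(mu))
  if (!is.null(eps)) dlogvar <- dZ * (Z - mu) * 0.5
  dmu <- dmu + kl_weight * mu / n_nodes
  dlogvar <- dlogvar + kl_weight * 0.5 * (exp(logvar) - 1) / n_nodes
  list(dmu = dmu, dlogvar = dlogvar)
}

# backprop through the GCN given a forward pass with keep_cache = TRUE
encoder_gradients <- function(emb, params, dmu, dlogvar) {
  S <- emb$S
  Hfin <- emb$head_input
  SHfin <- S %*% Hfin
  gW_mu <- crossprod(SHfin, dmu)
  gW_logvar <- crossprod(SHfin, dlogvar)
  dH <- (S %*% dmu) %*% t(params$W_mu) +
    (S %*% dlogvar) %*% t(params$W_logvar)
  L1 <- length(params$W)
  gW <- vector("list", L1)
  for (l in rev(seq_len(L1))) {
    dpre <- dH * (emb$cache$pre[[l]] > 0)
    if (!is.null(emb$cache$masks)) dpre <- dpre * emb$cache$masks[[l]]
    SH <- S %*% emb$cache$H[[l]]
    gW[[l]] <- crossprod(SH, dpre)
    if (l > 1L) dH <- (S %*% dpre) %*% t(params$W[[l]])
  }
  list(W = gW, W_mu = as.matrix(gW_mu), W_logvar = as.matrix(gW_logvar))
}
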