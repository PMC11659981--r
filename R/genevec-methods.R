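#' @export
print.genevec <- function(x, ...) {
  cfg <- x$config
  cat("genevec fit:", length(x$gene_names), "genes,",
      nrow(x$split$train_pos), "training edges\n")
  cat(sprintf("  encoder %s -> latent %d | lambda %g, beta %g, gamma %g, s %d\n",
              paste(cfg$encoder$layer_dims, collapse = "-"),
              cfg$encoder$latent_dim, cfg$lambda_weight, cfg$beta, cfg$gamma,
              cfg$sparsity_s))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  %d epochs (lr %g): total loss %.4f, soft modularity %.4f\n",
                cfg$epochs, cfg$learning_rate, last$total, last$modularity))
  }
  cat(sprintf("  link prediction: val AUROC %.3f / AP %.3f, test AUROC %.3f / AP %.3f\n",
              x$metrics$val_auroc, x$metrics$val_ap,
              x$metrics$test_auroc, x$metrics$test_ap))
  if (!is.null(x$catalog)) {
    cat(sprintf("  clusters: k = %d, silhouette %.3f, DBI %.3f\n",
                x$catalog$k, x$catalog$silhouette, x$catalog$dbi))
  }
  invisible(x)
}

#' @export
summary.genevec <- function(object, ...) {
  out <- list(
    n_genes = length(object$gene_names),
    n_communities = length(object$communities$community_sizes),
    config = object$config,
    metrics = object$metrics,
    final_loss = if (nrow(object$history))
      object$history[nrow(object$history), ] else NULL,
    catalog = object$catalog
  )
  class(out) <- "summary.genevec"
  out
}

#' @export
print.summary.genevec <- function(x, ...) {
  cat("Community-augmented VGAE gene embedding\n")
  cat(sprintf("  genes: %d | primary communities: %d\n",
              x$n_genes, x$n_communities))
  if (!is.null(x$final_loss)) {
    cat(sprintf("  final losses: recon %.4f, KL %.4f, soft modularity %.4f (total %.4f)\n",
                x$final_loss$recon, x$final_loss$kl, x$final_loss$modularity,
                x$final_loss$total))
  }
  cat(sprintf("  held-out link prediction: AUROC %.3f (val), %.3f (test)\n",
              x$metrics$val_auroc, x$metrics$test_auroc))
  if (!is.null(x$catalog)) print(x$catalog)
  invisible(x)
}

#' Extract the latent gene embedding
#'
#' @param object a fitted `genevec` model.
#' @param ... unused.
#' @return Numeric matrix (genes x latent dims), the posterior mean.
#' @export
coef.genevec <- function(object, ...) object$embedding$mu

#' Predict edge probabilities from a fitted model
#'
#' @param object a fitted `genevec` model.
#' @param pairs gene pairs to score: a two-column matrix/data.frame of gene
#'   symbols or integer indices. `NULL` scores the held-out test pairs.
#' @param type `"prob"` (sigmoid) or `"link"` (raw inner-product logits).
#' @param ... unused.
#' @return Numeric vector of scores, one per pair.
#' @export
predict.genevec <- function(object, pairs = NULL, type = c("prob", "link"),
                            ...) {
  type <- match.arg(type)
  Z <- object$embedding$mu
  if (is.null(pairs)) {
    pairs <- rbind(object$split$test_pos, object$split$test_neg)
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      idx <- matrix(match(pairs, object$gene_names), ncol = 2)
      if (any(is.na(idx))) stop("unknown gene symbols in `pairs`")
      pairs <- idx
    }
  }
  logits <- pair_logits(Z, pairs)
  if (type == "prob") stats::plogis(logits) else logits
}

#' @export
fitted.genevec <- function(object, ...) {
  P <- decode(object$embedding$mu)
  dimnames(P) <- list(object$gene_names, object$gene_names)
  P
}

#' @export
residuals.genevec <- function(object, ...) {
  as.matrix(object$graph$adjacency) - fitted(object)
}

#' Sample reconstructed networks from a fitted model
#'
#' Draws binary symmetric adjacency matrices whose edges are independent
#' Bernoulli draws with the decoded probabilities.
#'
#' @param object a fitted `genevec` model.
#' @param nsim number of sampled networks.
#' @param seed RNG seed.
#' @param ... unused.
#' @return List of `nsim` sparse binary adjacency matrices.
#' @export
simulate.genevec <- function(object, nsim = 1, seed = NULL, ...) {
  P <- fitted(object)
  n <- nrow(P)
  old <- .Random.seed_store()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(P)
  p_ut <- P[ut]
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    draw <- stats::rbinom(length(p_ut), 1, p_ut)
    A <- matrix(0, n, n, dimnames = dimnames(P))
    A[ut] <- draw
    A <- A + t(A)
    out[[k]] <- methods::as(Matrix::Matrix(A, sparse = TRUE), "CsparseMatrix")
  }
  out
}

#' Plot the 2-D embedding of a fitted model
#'
#' Scatter plot of the t-SNE projection, coloured by gene cluster when a
#' catalog is attached (unassigned genes in grey). Computes the projection
#' on the fly if the model was fitted with `project = FALSE`.
#'
#' @param x a fitted `genevec` model.
#' @param perplexity t-SNE perplexity if the projection must be computed.
#' @param ... passed to [graphics::plot()].
#' @return The 2-D coordinates, invisibly.
#' @export
plot.genevec <- function(x, perplexity = 30, ...) {
  coords <- x$embedding$coords2d
  if (is.null(coords)) {
    perp <- min(perplexity, floor((nrow(x$embedding$mu) - 2) / 3))
    coords <- reduce_2d(x$embedding$mu, perplexity = perp,
                        seed = x$config$seed)
  }
  cols <- "grey40"
  if (!is.null(x$catalog)) {
    lab <- x$catalog$labels
    pal <- grDevices::hcl.colors(max(1L, x$catalog$k), "Dark 3")
    cols <- ifelse(is.na(lab), "grey80", pal[as.integer(factor(lab))])
  }
  graphics::plot(coords, col = cols, pch = 16, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(coords)
}
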