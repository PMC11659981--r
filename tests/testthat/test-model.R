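toy_setup <- function(n = 6, in_dim = 5, dims = c(4, 3), seed = 21,
                      p = 0.5) {
  g <- random_gene_graph(n, p, seed = seed)
  X <- matrix(rnorm(n * in_dim), n, in_dim,
              dimnames = list(g$gene_names, paste0("c", seq_len(in_dim))))
  comm <- detect_primary_communities(g, seed = seed)
  An <- enhance_adjacency(g, community_matrix(comm), 1)
  cfg <- encoder_config(dims)
  params <- init_params(cfg, in_dim, seed = seed)
  list(g = g, X = X, An = An, cfg = cfg, params = params)
}

test_that("encoder forward pass matches dense propagation algebra", {
  s <- toy_setup(n = 4, in_dim = 3, dims = c(3, 2), seed = 31, p = 0.8)
  # propagation matrix oracle
  A <- as.matrix(s$An$matrix)
  At <- A + diag(nrow(A))
  dinv <- diag(1 / sqrt(rowSums(At)))
  S_oracle <- dinv %*% At %*% dinv
  expect_equal(gcn_propagation_matrix(s$An), S_oracle, ignore_attr = TRUE)

  # full forward oracle for the 2-layer encoder
  emb <- gcn_encode(s$An, s$X, s$cfg, s$params)
  H1 <- pmax(S_oracle %*% (s$X %*% s$params$W[[1]]), 0)
  mu_oracle <- S_oracle %*% (H1 %*% s$params$W_mu)
  lv_oracle <- S_oracle %*% (H1 %*% s$params$W_logvar)
  expect_equal(emb$mu, mu_oracle, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(emb$logvar, lv_oracle, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(emb$Z, emb$mu)  # sample = FALSE means Z = mu
})

test_that("zero parameters give a zero embedding; shapes follow the config", {
  s <- toy_setup(seed = 32)
  zp <- lapply(s$params, function(p) {
    if (is.list(p)) lapply(p, function(w) w * 0) else p * 0
  })
  emb <- gcn_encode(s$An, s$X, s$cfg, zp)
  expect_true(all(emb$Z == 0))

  cfg3 <- encoder_config(c(256, 64, 16))
  p3 <- init_params(cfg3, ncol(s$X), seed = 1)
  emb3 <- gcn_encode(s$An, s$X, cfg3, p3)
  expect_equal(dim(emb3$Z), c(6L, 16L))
})

test_that("reparameterized sampling uses Z = mu + exp(logvar/2) * eps", {
  s <- toy_setup(seed = 33)
  eps <- matrix(rnorm(6 * 3), 6, 3)
  emb <- gcn_encode(s$An, s$X, s$cfg, s$params, sample = TRUE, eps = eps)
  expect_equal(emb$Z, emb$mu + exp(emb$logvar / 2) * eps,
               ignore_attr = TRUE)
  # seeded sampling is reproducible
  e1 <- gcn_encode(s$An, s$X, s$cfg, s$params, sample = TRUE, seed = 5)
  e2 <- gcn_encode(s$An, s$X, s$cfg, s$params, sample = TRUE, seed = 5)
  expect_equal(e1$Z, e2$Z)
})

test_that("encoder config validates its invariants", {
  expect_error(encoder_config(16), "at least 2")
  expect_error(encoder_config(c(16, 0)), "positive")
  expect_error(encoder_config(c(16, 8), dropout = 1), "dropout")
  expect_equal(encoder_config(c(64, 16))$latent_dim, 16L)
})

test_that("decoder is the sigmoid inner product", {
  expect_true(all(decode(matrix(0, 3, 2)) == 0.5))
  Zs <- rbind(c(10, 0), c(10, 0))
  expect_gt(decode(Zs)[1, 2], 1 - 1e-8)
  set.seed(34)
  Z <- matrix(rnorm(15), 5, 3)
  oracle <- 1 / (1 + exp(-Z %*% t(Z)))
  expect_equal(decode(Z), oracle, tolerance = 1e-12)
  expect_equal(decode(Z), t(decode(Z)))
  expect_true(all(decode(Z) > 0 & decode(Z) < 1))
})

test_that("ELBO components match a scalar-loop oracle", {
  # prior equals posterior: KL = 0
  el0 <- elbo_loss(matrix(0, 3, 3), diag(0, 3), matrix(0, 3, 2),
                   matrix(0, 3, 2), pos_weight = 1, norm = 1)
  expect_equal(el0$kl, 0)

  # perfect reconstruction limit
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  big <- 50 * (2 * A - 1)
  elp <- elbo_loss(big, A, matrix(0, 3, 2), matrix(0, 3, 2),
                   pos_weight = 2, norm = 1)
  expect_lt(elp$recon, 1e-8)

  # hand-set 3-node toy vs scalar loops
  set.seed(35)
  logits <- matrix(rnorm(9), 3, 3); logits <- (logits + t(logits)) / 2
  mu <- matrix(rnorm(6), 3, 2); lv <- matrix(rnorm(6), 3, 2)
  pw <- 2.5; nrm <- 0.8
  el <- elbo_loss(logits, A, mu, lv, pw, nrm)
  recon_o <- 0
  for (i in 1:3) for (j in 1:3) {
    p <- 1 / (1 + exp(-logits[i, j]))
    recon_o <- recon_o - (pw * A[i, j] * log(p) + (1 - A[i, j]) * log(1 - p))
  }
  recon_o <- nrm * recon_o / 9
  kl_o <- 0
  for (i in 1:3) for (d in 1:2) {
    kl_o <- kl_o + 0.5 * (exp(lv[i, d]) + mu[i, d]^2 - 1 - lv[i, d])
  }
  kl_o <- kl_o / 3
  expect_equal(el$recon, recon_o, tolerance = 1e-10)
  expect_equal(el$kl, kl_o, tolerance = 1e-10)
  expect_error(elbo_loss(logits, A, mu, lv, 0, nrm), "pos_weight")
})

test_that("KL is nonnegative and zero only at the prior", {
  set.seed(36)
  for (r in 1:20) {
    mu <- matrix(rnorm(8), 4, 2)
    lv <- matrix(rnorm(8, sd = 0.7), 4, 2)
    kl <- elbo_loss(matrix(0, 4, 4), diag(0, 4), mu, lv, 1, 1)$kl
    expect_gte(kl, 0)
  }
})

test_that("soft modularity matches a brute-force double loop and its identities", {
  g <- random_gene_graph(12, 0.3, seed = 37)
  # identical embeddings: exact zero (sum of B is zero)
  Zc <- matrix(1.7, 12, 3)
  expect_lt(abs(modularity_loss(Zc, g, beta = 10, gamma = 0.1)), 1e-10)

  # large gamma with distinct points: kernel vanishes except diagonal
  set.seed(38)
  Zr <- matrix(rnorm(36), 12, 3)
  v_big <- modularity_loss(Zr, g, beta = 10, gamma = 1e6)
  # remaining mass is the constant diagonal -sum(d^2)/2m term
  diag_term <- 10 / (2 * g$m) * sum(-g$degrees^2 / (2 * g$m))
  expect_equal(v_big, diag_term, tolerance = 1e-6)

  # path graph on 3 nodes, z = 0,1,2: brute-force double loop oracle
  pg <- gene_graph(cbind(c("n0", "n1"), c("n1", "n2")))
  Z <- matrix(c(0, 1, 2), 3, 1)
  beta <- 10; gam <- 0.1
  o <- 0
  A <- as.matrix(pg$adjacency); d <- pg$degrees; two_m <- 2 * pg$m
  for (i in 1:3) for (j in 1:3) {
    o <- o + (A[i, j] - d[i] * d[j] / two_m) * exp(-gam * (Z[i] - Z[j])^2)
  }
  o <- beta / two_m * o
  expect_equal(modularity_loss(Z, pg, beta, gam), o, tolerance = 1e-12)

  expect_error(modularity_loss(Z, gene_graph(matrix(c("A", "A"), 1, 2),
                                             gene_names = c("A", "B"))),
               "no edges")
})

test_that("soft modularity is invariant to rigid translation", {
  g <- random_gene_graph(10, 0.4, seed = 39)
  set.seed(40)
  Z <- matrix(rnorm(30), 10, 3)
  shift <- matrix(rep(c(3.2, -1.5, 0.7), each = 10), 10, 3)
  expect_equal(modularity_loss(Z, g), modularity_loss(Z + shift, g),
               tolerance = 1e-10)
})

test_that("total loss composes the terms with the stated signs", {
  expect_equal(total_loss(1.5, 0.3, 0), 1.8)
  expect_equal(total_loss(1.25, 0.5, 0.75), 1.0, tolerance = 1e-12)
  expect_equal(total_loss(1, 2, 0.5, kl_weight = 0.25), 1.0)
  expect_error(total_loss(Inf, 0, 0), "non-finite")

  # end-to-end composition on a 4-node toy equals the two oracles combined
  s <- toy_setup(n = 4, in_dim = 3, dims = c(3, 2), seed = 41, p = 0.9)
  emb <- gcn_encode(s$An, s$X, s$cfg, s$params)
  A <- as.matrix(s$g$adjacency)
  el <- elbo_loss(tcrossprod(emb$Z), A, emb$mu, emb$logvar, 2, 0.6)
  mod <- modularity_loss(emb$Z, s$g, 10, 0.1)
  expect_equal(total_loss(el$recon, el$kl, mod), el$recon + el$kl - mod)
})

test_that("analytic gradients match central finite differences", {
  s <- toy_setup(n = 7, in_dim = 4, dims = c(4, 3), seed = 42, p = 0.5)
  n <- 7
  target <- as.matrix(s$g$adjacency); diag(target) <- 1
  npos <- sum(as.matrix(s$g$adjacency))
  pw <- (n^2 - npos) / npos
  nrm <- n^2 / (2 * (n^2 - npos))
  two_m <- 2 * s$g$m
  B <- as.matrix(s$g$adjacency) - outer(s$g$degrees, s$g$degrees) / two_m
  set.seed(43)
  eps <- matrix(rnorm(n * 3), n, 3)
  klw <- 1 / n
  S <- gcn_propagation_matrix(s$An)

  lossfun <- function(p) {
    emb <- gcn_encode(s$An, s$X, s$cfg, p, sample = TRUE, eps = eps,
                      propagation = S)
    el <- elbo_loss(tcrossprod(emb$Z), target, emb$mu, emb$logvar, pw, nrm)
    total_loss(el$recon, el$kl, modularity_loss(emb$Z, s$g, 10, 0.1),
               kl_weight = klw)
  }
  emb <- gcn_encode(s$An, s$X, s$cfg, s$params, sample = TRUE, eps = eps,
                    propagation = S, keep_cache = TRUE)
  gr <- genevec:::loss_gradients(emb$Z, emb$mu, emb$logvar, eps, target,
                                 pw, nrm, B, 10 / two_m, 0.1, n,
                                 kl_weight = klw)
  ag <- genevec:::encoder_gradients(emb, s$params, gr$dmu, gr$dlogvar)

  h <- 1e-6
  numgrad <- function(get, set) {
    P <- get(s$params)
    num <- array(0, dim(P))
    for (k in seq_along(P)) {
      P1 <- P; P1[k] <- P1[k] + h
      P2 <- P; P2[k] <- P2[k] - h
      num[k] <- (lossfun(set(s$params, P1)) - lossfun(set(s$params, P2))) /
        (2 * h)
    }
    num
  }
  nw <- numgrad(function(p) p$W[[1]], function(p, v) { p$W[[1]] <- v; p })
  expect_equal(unname(ag$W[[1]]), nw, tolerance = 1e-5)
  nmu <- numgrad(function(p) p$W_mu, function(p, v) { p$W_mu <- v; p })
  expect_equal(unname(ag$W_mu), nmu, tolerance = 1e-5)
  nlv <- numgrad(function(p) p$W_logvar, function(p, v) { p$W_logvar <- v; p })
  expect_equal(unname(ag$W_logvar), nlv, tolerance = 1e-5)
})

test_that("one small gradient step decreases the total loss (5 seeds)", {
  for (seed in 1:5) {
    s <- toy_setup(n = 10, in_dim = 4, dims = c(4, 2), seed = 50 + seed,
                   p = 0.5)
    n <- 10
    target <- as.matrix(s$g$adjacency); diag(target) <- 1
    npos <- sum(as.matrix(s$g$adjacency))
    pw <- (n^2 - npos) / npos
    nrm <- n^2 / (2 * (n^2 - npos))
    two_m <- 2 * s$g$m
    B <- as.matrix(s$g$adjacency) - outer(s$g$degrees, s$g$degrees) / two_m
    set.seed(seed)
    eps <- matrix(rnorm(n * 2), n, 2)
    S <- gcn_propagation_matrix(s$An)
    lossfun <- function(p) {
      emb <- gcn_encode(s$An, s$X, s$cfg, p, sample = TRUE, eps = eps,
                        propagation = S)
      el <- elbo_loss(tcrossprod(emb$Z), target, emb$mu, emb$logvar, pw, nrm)
      total_loss(el$recon, el$kl, modularity_loss(emb$Z, s$g, 10, 0.1),
                 kl_weight = 1 / n)
    }
    emb <- gcn_encode(s$An, s$X, s$cfg, s$params, sample = TRUE, eps = eps,
                      propagation = S, keep_cache = TRUE)
    gr <- genevec:::loss_gradients(emb$Z, emb$mu, emb$logvar, eps, target,
                                   pw, nrm, B, 10 / two_m, 0.1, n,
                                   kl_weight = 1 / n)
    ag <- genevec:::encoder_gradients(emb, s$params, gr$dmu, gr$dlogvar)
    lr <- 1e-3
    p1 <- s$params
    p1$W[[1]] <- p1$W[[1]] - lr * ag$W[[1]]
    p1$W_mu <- p1$W_mu - lr * ag$W_mu
    p1$W_logvar <- p1$W_logvar - lr * ag$W_logvar
    expect_lt(lossfun(p1), lossfun(s$params))
  }
})
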