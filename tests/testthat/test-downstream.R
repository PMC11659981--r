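test_that("seeds with sparse neighbourhoods yield no candidate cluster", {
  gn <- sprintf("g%02d", 1:12)
  co <- matrix(0, 12, 2)
  co[2:5, 1] <- c(0.1, -0.1, 0.2, -0.2)   # only 4 genes within 0.5
  co[6:12, ] <- 50
  g <- random_gene_graph(12, 0.9, seed = 90)
  res <- neighbor_gene_clusters(co, gn, "g01", g,
                                neighbor_config(radius = 0.5, min_cluster = 6))
  expect_length(res, 0)
})

test_that("expansion walks a chain and equals its connected component", {
  # 10 points spaced 0.4 apart along a line; seed at one end
  gn <- sprintf("g%02d", 1:10)
  co <- cbind(seq(0, by = 0.4, length.out = 10), 0)
  # make all genes adjacent to the seed so the interactor filter keeps them
  g <- gene_graph(cbind(rep("g01", 9), gn[2:10]))
  # initial ball holds only the seed and its 0.4-neighbour, so the size gate
  # must sit below 2 for the expansion walk to start
  cfg <- neighbor_config(radius = 0.5, min_cluster = 1)
  res <- neighbor_gene_clusters(co, gn, "g01", g, cfg)
  expect_setequal(res$g01$candidate, gn[2:10])
  expect_equal(sort(res$g01$candidate),
               expansion_oracle(co, gn, "g01", g, cfg))
  # distances reported are to the seed
  expect_equal(res$g01$distance_to_seed[order(res$g01$candidate)],
               seq(0.4, by = 0.4, length.out = 9), tolerance = 1e-12)
})

test_that("expansion is idempotent and monotone in the radius", {
  set.seed(91)
  gn <- sprintf("g%03d", 1:60)
  co <- matrix(rnorm(120, sd = 0.5), 60, 2)
  g <- random_gene_graph(60, 0.5, seed = 92)
  cfg <- neighbor_config(radius = 0.6, min_cluster = 2,
                         require_direct_interactor = FALSE)
  res <- neighbor_gene_clusters(co, gn, gn[1], g, cfg)
  expect_gt(length(res), 0)
  # idempotent: the member set is closed under another expansion pass
  members <- c(gn[1], res[[1]]$candidate)
  idx <- match(members, gn)
  D <- as.matrix(dist(co))
  reachable <- apply(D[idx, -idx, drop = FALSE] <= 0.6, 2, any)
  expect_false(any(reachable))
  # monotone: smaller radius yields a subset
  cfg_small <- neighbor_config(radius = 0.35, min_cluster = 2,
                               require_direct_interactor = FALSE)
  res_small <- neighbor_gene_clusters(co, gn, gn[1], g, cfg_small)
  if (length(res_small)) {
    expect_true(all(res_small[[1]]$candidate %in%
                      c(res[[1]]$candidate, gn[1])))
  }
})

test_that("absent seeds are reported and skipped", {
  gn <- c("A", "B", "C")
  co <- matrix(0, 3, 2)
  g <- gene_graph(cbind("A", c("B", "C")))
  expect_warning(res <- neighbor_gene_clusters(co, gn, c("A", "ZZZ"), g,
                                               neighbor_config(min_cluster = 1)),
                 "ZZZ")
})

test_that("the direct-interactor filter prunes non-neighbours of the seed", {
  gn <- sprintf("g%02d", 1:8)
  co <- cbind(seq(0, by = 0.3, length.out = 8), 0)
  g <- gene_graph(cbind(rep("g01", 3), c("g02", "g03", "g04")),
                  gene_names = gn)
  cfg <- neighbor_config(radius = 0.5, min_cluster = 1)
  res <- neighbor_gene_clusters(co, gn, "g01", g, cfg)
  expect_setequal(res$g01$candidate, c("g02", "g03", "g04"))
  cfg_off <- neighbor_config(radius = 0.5, min_cluster = 1,
                             require_direct_interactor = FALSE)
  res_off <- neighbor_gene_clusters(co, gn, "g01", g, cfg_off)
  expect_setequal(res_off$g01$candidate, gn[-1])
  expect_equal(sum(res_off$g01$is_direct_interactor), 3)
})

test_that("neighbourhood config defaults match the published rules", {
  cfg <- neighbor_config()
  expect_equal(cfg$radius, 0.5)
  expect_equal(cfg$min_cluster, 6L)
  expect_true(cfg$require_direct_interactor)
  melanoma <- neighbor_config(radius = 0.8, min_cluster = 6)
  expect_equal(melanoma$radius, 0.8)
})

test_that("tissue specificity follows the <5% significant-overlap rule", {
  universe <- sprintf("u%03d", 1:300)
  # tissue A: one private cluster, one shared cluster
  shared <- universe[1:40]
  catalogs <- list(
    A = list(c1 = universe[101:140], c2 = shared),
    B = c(list(s = shared),
          setNames(lapply(0:9, function(i) universe[141 + i]), # 10 singletons
                   paste0("b", 1:10))),
    C = c(list(s = shared),
          setNames(lapply(0:9, function(i) universe[201 + i]),
                   paste0("c", 1:10)))
  )
  res <- tissue_specific_clusters(catalogs, universe)
  a1 <- res[res$tissue == "A" & res$cluster_id == "c1", ]
  a2 <- res[res$tissue == "A" & res$cluster_id == "c2", ]
  expect_equal(a1$n_sig_overlaps, 0)
  expect_true(a1$is_specific)
  # c2 overlaps the shared cluster in both other tissues: 2 of 22 > 5%
  expect_equal(a2$n_sig_overlaps, 2)
  expect_false(a2$is_specific)
  expect_error(tissue_specific_clusters(catalogs["A"], universe),
               "two tissues")
  expect_error(tissue_specific_clusters(catalogs, character(0)), "universe")

  # invariance to tissue ordering
  res2 <- tissue_specific_clusters(rev(catalogs), universe)
  m <- merge(res, res2, by = c("tissue", "cluster_id"))
  expect_equal(m$is_specific.x, m$is_specific.y)
})

test_that("enrichment p-values equal the closed-form hypergeometric tail", {
  universe <- sprintf("u%02d", 1:40)
  cluster <- universe[1:20]
  annotated <- universe[11:30]
  et <- enrichment_test(cluster, annotated, universe)
  # exhaustive tail sum with binomial coefficients
  a <- length(intersect(cluster, annotated))
  K <- length(annotated); nC <- length(cluster); N <- length(universe)
  tail_sum <- sum(sapply(a:min(K, nC), function(x) {
    choose(K, x) * choose(N - K, nC - x) / choose(N, nC)
  }))
  expect_equal(et$p, tail_sum, tolerance = 1e-12)
  expect_equal(et$overlap, a)

  # zero overlap with large expected overlap: p ~ 1
  et0 <- enrichment_test(universe[1:15], universe[16:40], universe)
  expect_gt(et0$p, 0.999)

  # bonferroni family adjustment (e.g. 50 hallmark sets)
  et50 <- enrichment_test(cluster, annotated, universe, n_families = 50)
  expect_equal(et50$p_adjusted, min(1, et50$p * 50))
  expect_equal(adjust_family(c(0.001, 0.04), "bonferroni"),
               c(0.002, 0.08))
})

test_that("closeness split separates intra- from extra-cluster structure", {
  # two 4-cliques with a single bridge; clusters = the cliques
  gn <- c(paste0("a", 1:4), paste0("b", 1:4))
  edges <- rbind(t(combn(gn[1:4], 2)), t(combn(gn[5:8], 2)))
  g_noext <- gene_graph(edges, gene_names = gn)
  cat0 <- cluster_catalog(rep(1:2, each = 4), matrix(0, 8, 2), 0.5, 0.5, 1)
  cs <- closeness_split(g_noext, cat0)
  expect_equal(cs$per_cluster$external_closeness, c(0, 0))
  expect_gt(cs$per_cluster$internal_closeness[1], 0)
  # identical internal samples vs identical external: wilcoxon p = 1
  expect_equal(suppressWarnings(
    stats::wilcox.test(c(1, 2), c(1, 2), exact = FALSE,
                       correct = FALSE)$p.value), 1)

  # 6-node path: hand-computed scaled closeness
  pn <- sprintf("p%d", 1:6)
  pg <- gene_graph(cbind(pn[1:5], pn[2:6]))
  cat1 <- cluster_catalog(rep(1, 6), matrix(0, 6, 2), 0, 0, 1)
  cs2 <- closeness_split(pg, cat1)
  d_tot <- c(15, 11, 9, 9, 11, 15)  # path distances sums
  oracle <- mean((5 / 5) * (5 / d_tot))
  expect_equal(cs2$per_cluster$internal_closeness, oracle, tolerance = 1e-12)
  expect_equal(cs2$per_cluster$external_closeness, 0)
})

test_that("module scores recover a planted expression shift", {
  set.seed(93)
  n_genes <- 400; n_cells <- 30
  expr <- matrix(rnorm(n_genes * n_cells, mean = 3, sd = 0.01),
                 n_genes, n_cells,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("c%03d", 1:n_cells)))
  # lift 5 genes by +2 in every cell; with 200-gene bins the control pool is
  # barely contaminated by the lifted genes themselves
  lifted <- sprintf("g%03d", 1:5)
  expr[lifted, ] <- expr[lifted, ] + 2
  fm <- feature_matrix(expr, rownames(expr), colnames(expr), logcpm = expr)
  sc <- module_score(fm, lifted, n_bins = 2, n_ctrl = 100, seed = 1)
  expect_equal(length(sc), n_cells)
  expect_true(all(abs(sc - 2) < 0.2))

  # a null gene set scores ~0 against its bin-matched controls
  nullset <- sprintf("g%03d", 101:110)
  sc0 <- module_score(fm, nullset, n_bins = 2, n_ctrl = 100, seed = 1)
  expect_true(all(abs(sc0) < 0.05))

  # scalar reimplementation with the same seed reproduces the exact scores
  avg <- rowMeans(expr)
  bins <- cut(rank(avg, ties.method = "first"), breaks = 2, labels = FALSE)
  names(bins) <- rownames(expr)
  set.seed(1)
  ctrl <- character(0)
  for (g in lifted) {
    pool <- setdiff(names(bins)[bins == bins[[g]]], g)
    ctrl <- c(ctrl, sample(pool, min(100, length(pool))))
  }
  ctrl <- unique(ctrl)
  oracle <- colMeans(expr[lifted, ]) - colMeans(expr[ctrl, ])
  expect_equal(sc, oracle)

  expect_error(module_score(fm, "absent_gene"), "no cluster genes")
})

test_that("jaccard index handles the edge conventions", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(character(0), character(0)), 0)
})

test_that("seed lists and neighbour tables round-trip through files", {
  f <- tempfile()
  writeLines(c("# GWAS hits", "TP53", "", "BRCA1"), f)
  expect_equal(read_seed_genes(f), c("TP53", "BRCA1"))

  nb <- list(TP53 = data.frame(candidate = "MDM2", distance_to_seed = 0.2,
                               is_direct_interactor = TRUE))
  out <- tempfile()
  write_neighbor_clusters(nb, out)
  back <- read.delim(out)
  expect_equal(back$seed, "TP53")
  expect_equal(back$candidate, "MDM2")
})
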