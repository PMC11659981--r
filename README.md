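# genevec

Gene embeddings from interaction networks and single-cell expression, via a
community-augmented variational graph autoencoder (VGAE).

## The problem

Gene–gene interaction networks (BioGRID-style physical interactions,
pathways, regulons) and single-cell expression profiles describe the same
genes from two different angles. `genevec` fuses the two into a
low-dimensional embedding per gene, in which distances are meaningful for
three downstream tasks:

1. **gene-cluster identification** — groups of genes that are both densely
   interconnected and co-expressed;
2. **tissue/state-specific cluster calling** — which clusters are private to
   one tissue's embedding;
3. **candidate-gene discovery** — expanding outward from *seed* genes
   (GWAS hits, known drivers, perturbed regulators) to embedding-space
   neighbours that directly interact with them.

It is aimed at computational biologists who have an edge list and a count
matrix and want interpretable gene modules plus ranked candidate genes,
entirely offline.

## The model

Let `A` be the binary adjacency of the interaction network over `n` genes
and `X` the preprocessed gene × cell feature matrix. A Louvain partition of
the network gives a membership matrix `M`, from which a community matrix

    A_c = M M' − I

marks same-community gene pairs. Each gene keeps community links to at most
`s` high-degree representatives of its community, and the encoder
propagates over the **enhanced adjacency**

    A_n = A + λ A_c(s),    λ > 0.

A multilayer graph-convolutional encoder (default widths 256-64-16) maps
`(A_n, X)` to a Gaussian posterior `N(mu_i, diag(exp(logvar_i)))` per gene;
the inner-product decoder reconstructs edge probabilities
`sigmoid(z_i · z_j)`. Training minimizes

    L = recon + KL/n − L_M,

where `recon` is the positive-class-weighted cross-entropy of the decoder
against the training adjacency (reference-VGAE conventions, self-loops in
the target), `KL` is the divergence from the standard-normal prior, and

    L_M = (β / 2m) Σ_ij (A_ij − d_i d_j / 2m) · exp(−γ ‖z_i − z_j‖²)

is a *soft modularity* score: Newman modularity with the hard
same-community indicator relaxed to a Gaussian kernel on embedding
distances. Descent on `−L_M` pulls connected, community-consistent genes
together. Defaults (λ = 1, β = 10, γ = 0.1, s = 10, Adam, lr 1e-4,
600 epochs, 10 replicate runs with max-silhouette selection) follow the
published hyperparameter sweep for tissue-scale networks.

Edges are split 90/5/5 (train/validation/test) with equal numbers of
sampled non-edges; communities and the enhanced adjacency are built from
training edges only, so held-out link-prediction metrics are leak-free.

## Worked example

The package ships a seeded generator for benchmark data: a
stochastic-block-model network (4 planted blocks of 50 genes) paired with a
400-cell count matrix whose blocks are over-expressed in coupled cell
types, with dropout.

```r
library(genevec)

fx       <- fixture_bundle("sbm_recovery", seed = 0, out_dir = tempfile())
graph    <- load_edge_list(fx$edges)
counts   <- read_counts_mtx(fx$counts, fx$genes, fx$cells)
features <- align_genes(graph, preprocess_features(counts, min_genes_expressed = 10))

cfg <- train_config(learning_rate = 1e-2, epochs = 300, seed = 0)
fit <- genevec(graph, features, cfg, project = TRUE)
fit
#> genevec fit: 200 genes, 1388 training edges
#>   encoder 256-64-16 -> latent 16 | lambda 1, beta 10, gamma 0.1, s 10
#>   300 epochs (lr 0.01): total loss -3.6069, soft modularity 4.9748
#>   link prediction: val AUROC 0.817 / AP 0.816, test AUROC 0.800 / AP 0.755
#>   clusters: k = 4, silhouette 0.935, DBI 0.095
```

The fit reports the three quantities that matter: the training objective
(its soft-modularity component rises as communities tighten), held-out link
prediction (AUROC/average precision on edges the model never saw — on this
block-model benchmark ~0.80 is the information ceiling, see the vignette),
and the gene clustering of the 2-D projection (4 clusters recovered,
silhouette 0.935 — exactly the planted blocks; adjusted Rand index vs truth
is 1.0 on all three seeds of the acceptance run).

`coef(fit)` returns the n × 16 embedding; `predict(fit, pairs)` scores gene
pairs; `plot(fit)` draws the t-SNE map coloured by cluster;
`simulate(fit)` samples reconstructed networks. Downstream:

```r
catalog <- fit$catalog                               # silhouette-selected clusters
neighbor_gene_clusters(fit$embedding$coords2d, fit$gene_names,
                       seeds = c("G0001"), graph,
                       neighbor_config(radius = 0.5, min_cluster = 6))
```

A command-line wrapper is provided for shell pipelines:

```sh
Rscript inst/cli/embed.R --edges net.tsv --counts X.mtx --genes genes.txt \
    --cells cells.txt --lambda 1 --beta 10 --gamma 0.1 --s 10 \
    --layers 256,64,16 --lr 1e-4 --epochs 600 --seed 0 --out run/
```

writing `embedding.tsv`, `coords2d.tsv`, `clusters.tsv`, `history.tsv`,
`split.json` and `metrics.json`.

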