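# gcnforge

Construction and multivariate comparison of gene co-expression networks
(GCNs) in R.

A GCN is an undirected graph whose nodes are genes and whose edges join
genes with similar expression profiles across samples. `gcnforge` covers the
four steps of this kind of analysis for preprocessed (normalized, log2)
expression matrices, as used in studies of plant immune responses and other
stress transcriptomics:

1. **Expression matrices** — probe-to-gene collapsing (ambiguous probes
   dropped, per-sample maximum over a gene's probes), a fixed-order
   missingness filter (samples covering < 50% of the common genes, then
   genes observed in < 75% of the remaining samples), and multi-experiment
   merging on a common gene list.
2. **Similarity** — three measures in `[0, 1]`: the absolute Pearson
   correlation (APCC), a non-linear correlation coefficient based on mutual
   information (NCMI, `lambda = sqrt(1 - exp(-2 I))` with a bias-corrected
   2-D histogram MI estimate), and the normalized mean residue similarity
   (NMRS, shift- and scale-invariant). NCMI detects quadratic and other
   non-monotone co-expression that APCC misses.
3. **Threshold selection** — edges are created where similarity reaches a
   hard threshold `tau*`, chosen by scanning `tau = 0.01 ... 0.99` and
   comparing the network's observed clustering coefficient
   `C = mean(2 D_i / (k_i (k_i - 1)))` (over nodes with `k_i > 1`) against
   its degree-matched random expectation
   `Cr = (kd_bar - k_bar)^2 / (k_bar^3 N)`; `tau*` is the first local
   maximum of `|C - Cr|`. The absolute difference keeps the criterion
   defined for hub-dominated networks where `Cr > C`.
4. **Comparison** — each network is reduced to eight graph variables
   (clustering coefficient CC, betweenness centralization Cen, degree
   heterogeneity Het, density Den, GO/PFAM label assortativity AsG/AsP,
   hub-attack tolerance Tol, and the degree–immunity-domain correlation
   KI); the networks-by-variables table is summarized by standardized PCA
   and clustered with seeded K-means under a BIC curve
   (`BIC(k) = n log(W_k / n) + k log(n)`, elbow rule by default).

Seeded generators (`simulate_network`, `embed_similarity`,
`simulate_expression`, `simulate_annotations`) produce power-law networks
with target degree heterogeneity and clustering, similarity matrices with a
planted true threshold, and expression matrices with planted linear,
inverted, quadratic and shifted co-expression; `recovery_experiment`
validates threshold selection against them.

## Worked example

Build and compare three networks from synthetic expression data with a
planted linear and a planted quadratic module:

```r
library(gcnforge)

mods <- list(list(size = 10, relation = "linear"),
             list(size = 8, relation = "quadratic"))
mats <- setNames(lapply(1:3, function(i) {
  simulate_expression(30, 24, modules = mods, noise_sd = 0.1, seed = 100 + i)
}), paste0("exp", 1:3))

cfg <- pipeline_config(matrices = mats, measure = "ncmi", seed = 5,
                       n_starts = 10, out_dir = "demo_run")
res <- run_pipeline(cfg, mode = "single")
res$networks$exp1
#> Gene co-expression network: 18 nodes, 57 edges, tau* = 0.73
round(res$characterization[, c("CC", "Het", "Den", "Tol")], 2)
#>        CC  Het  Den  Tol
#> exp1 1.00 0.47 0.37 1.00
#> exp2 0.92 0.39 0.35 0.99
#> exp3 0.79 0.36 0.30 0.68
```

Each network retains roughly the 18 planted module genes out of 30 (the 12
background genes are independent noise and fall below the selected
threshold), with the high clustering expected of two planted co-expression
modules. The run directory `demo_run/` contains per-network
threshold curves, SIF and edge-list exports, the characterization CSV, PCA
and clustering JSON, and a `manifest.json` with parameters and input
hashes; reruns with the same seed are byte-identical.

The same steps are available piecemeal: `similarity_matrix()`,
`threshold_curve()`, `select_threshold()`, `build_gcn()`,
`characterize()`, `gcn_pca()`, `kmeans_bic()`.

A command-line wrapper with subcommands `filter`, `similarity`,
`threshold`, `network`, `characterize`, `compare`, `simulate` and `run` is
installed under `exec/gcnforge`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "gcnforge", package = "gcnforge"))')" --help
```

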