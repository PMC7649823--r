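# diffge

Differential analysis of single-cell RNA-seq data at the level of **gene
groups**, scored by a PPI-weighted **network entropy**.

Single-gene differential tests ignore that genes in the same pathway are
co-expressed and shift together. `diffge` instead asks which *groups* of
co-expressed genes change activity across cells or cell types. Genes are
partitioned into K clusters by EM mixture clustering of their expression
profiles; each cluster is intersected with a protein–protein interaction
(PPI) network; and the cluster's activity in every cell is summarized into
an entropy that ranks the clusters. The top 10% of clusters are reported
as highly differential gene groups.

## The score

With `e_si` the normalized expression of gene *i* in cell *s* (each
cell's expression vector divided by its sum), a PPI edge (*i*, *j*)
carries weight

    W_ijs = e_si · e_sj

read as the probability that the two proteins interact in that cell. The
activity of cluster *k* (gene set `C_k`, size `n_k`) in cell *s* sums
the weights of its within-cluster PPI edges:

    W_ks = Σ_{i,j ∈ C_k} W_ijs / n_k

Activities are converted to shares `P_ks` and the network entropy of the
cluster is

    E_k = − Σ_s P_ks ln P_ks

Two share normalizations are provided: `per_cell` (shares across clusters
within each cell; the default) and `per_cluster` (shares across cells
within each cluster — a proper probability distribution, with
`E_k ≤ ln S`). Clusters are ranked by `E_k`, descending; broadly and
coherently active groups score high, sporadically bursting background
groups score low.

Also included: the logTPM transform with zero/rare/ubiquitous gene
filters (`v = 10`%), a STRING-dialect PPI reader, a subsampling
precision/recall stability protocol with ROC/AUC, and a fully seeded
synthetic-data generator (co-expression blocks, cell populations,
dropout, block-enriched PPI graphs).

## Worked example

```r
library(diffge)

sim <- simulate_diffge(simulation_config(seed = 1))   # 200 genes, 120 cells
res <- diffge_run(sim$expr, sim$ppi, K = 5, entropy_mode = "per_cluster")
res
#> <diffge_result> 5 clusters, 40 differential genes detected
#>  cluster n_genes n_edges total_activity  entropy rank selected
#>        1      40     255     0.01839266 3.843361    5    FALSE
#>        2      40     242     0.01924874 4.078785    3    FALSE
#>        3      40     231     0.02272660 4.090948    2    FALSE
#>        4      40     261     0.07131406 4.262612    1     TRUE
#>        5      40     260     0.02577867 3.927529    4    FALSE
```

The generator planted one differential block (block 1: elevated by 3
log-TPM units in the second cell type) among four bursty background
blocks. Cluster 4 recovers that block exactly (40 genes, 261 matched PPI
edges) and carries the top entropy 4.26 — its activity spreads coherently
over the 60 cells of the active type plus baseline elsewhere, while
background clusters concentrate on sporadic bursts — so it is selected
and its genes are reported:

```r
head(detected_genes(res$genes), 3)
#> [1] "G0001" "G0002" "G0003"
```

Stability of the detection under cell subsampling, and accuracy against
the planted truth:

```r
ev <- subset_experiment(sim$expr, sim$ppi, labels = sim$labels, seed = 1,
                        params = list(K = 5, entropy_mode = "per_cluster"))
ev$summary[, c("fraction", "mean_precision", "mean_recall")]
#>  fraction mean_precision mean_recall
#>        10      0.5071786        0.51
#>        30      1.0000000        1.00
#>        50      1.0000000        1.00
#>        70      1.0000000        1.00
#>        90      1.0000000        1.00

truth <- names(sim$truth$blocks)[sim$truth$blocks == 1]
roc_auc(setNames(res$genes$score, res$genes$gene), truth)$auc
#> [1] 1
```

Detections on 10% subsets (12 cells) only half-match the full-data gold
standard; from 30% on they are essentially stable — the qualitative
behavior expected of the protocol.

A thin CLI wrapper over the same functions ships in `inst/cli/diffge.R`
(`run`, `simulate`, `evaluate` subcommands).

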