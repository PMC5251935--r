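# scnmf

Unsupervised detection of cell subpopulations in single-cell RNA-Seq, and
of the genes and interaction-network modules that separate them.

Single-cell experiments routinely contain transcriptomic subpopulations
that bulk analyses average away. `scnmf` is an R toolkit for finding them
without labels, built around consensus non-negative matrix factorization
(NMF): the filtered, normalized gene × cell matrix `A` is factorized as
`A ≈ WH` (`W ≥ 0`: genes × k meta-genes, `H ≥ 0`: k × cells) by the
multiplicative Kullback–Leibler updates

    H_au ← H_au · [Σ_i W_ia A_iu / (WH)_iu] / Σ_k W_ka
    W_ia ← W_ia · [Σ_u H_au A_iu / (WH)_iu] / Σ_v H_av

Cells are assigned to their dominant meta-gene; 30 random restarts give a
consensus co-clustering matrix, and the factorization rank k (number of
subpopulations, scanned over 2–5) is chosen by the cophenetic correlation
coefficient of that consensus. For two subpopulations, genes are ranked by
the D-score

    D_i = | λ·W_i1 − (1 − λ)·W_i2 |,

with λ calibrated so that a uniformly expressed gene scores exactly 0.
The package also provides: FPKM conversion from exon-union gene lengths,
housekeeping-gene cell filters and zero-fraction gene filters,
median-of-ratios size factors, the pair-counting Rand measure and a
five-method clustering benchmark (K-means, three hierarchical variants,
optional correlation t-SNE preprocessing, Welch tests), seeded greedy
module detection on a PPI network with Monte Carlo permutation p-values,
and a synthetic-data generator with planted ground truth for all of the
above. Intended users are computational biologists analyzing counts, UMI
or FPKM matrices from scRNA-Seq experiments.

## Worked example

```r
library(scnmf)

# a synthetic two-subpopulation experiment with known ground truth:
# 2,000 genes x 100 cells, 100 marker genes at 4-fold effect, dropout
sim <- simulate_populations(seed = 1)
pre <- preprocess_counts(sim$counts, housekeeping = sim$housekeeping_genes)
pre$log
#> # A tibble: 4 × 3
#>   stage         n_genes n_samples
#>   <chr>           <int>     <int>
#> 1 input            2000       100
#> 2 sample_filter    2000       100
#> 3 gene_filter      1756       100
#> 4 normalized       1756       100

# how many subpopulations? scan ranks 2..5, 30 restarts each
sel <- select_rank(pre$values, k_range = 2:5, n_runs = 30, base_seed = 1)
tidy(sel)
#> # A tibble: 4 × 2
#>       k cophenetic
#>   <int>      <dbl>
#> 1     2      1
#> 2     3      0.998
#> 3     4      0.990
#> 4     5      0.981

cc <- sel$results[["2"]]
rand_index(cc$labels, sim$true_labels[names(cc$labels)])$rand
#> [1] 1
```

The cophenetic coefficient is maximal at k = 2 — the consensus over 30
restarts is perfectly block-structured there — and the recovered labels
match the planted subpopulations exactly (Rand measure 1). Ranking genes
from a rank-2 fit:

```r
fit <- nmf_fit(pre$values, k = 2, seed = 1)
genes <- rank_genes(fit, top_n = 500)
head(genes, 3)
#> # A tibble: 3 × 7
#>   gene_id loading_1 loading_2 d_score  rank is_feature lambda
#>   <chr>       <dbl>     <dbl>   <dbl> <int> <lgl>       <dbl>
#> 1 g1922        402.  6.58e+ 0    192.     1 TRUE        0.486
#> 2 g0824        355.  1.29e- 5    172.     2 TRUE        0.486
#> 3 g1811        354.  9.93e-11    172.     3 TRUE        0.486

mean(genes$gene_id[genes$rank <= 100] %in% sim$marker_genes)
#> [1] 0.57
```

The top-ranked genes load one meta-gene almost exclusively. Planted
markers make up 57% of the first 100 ranks against a background rate of
under 6% — a tenfold enrichment (hypergeometric p < 1e-50 over the top
500). D-scores are on the loading scale (proportional to absolute
expression), and λ ≈ 0.49 says the two meta-genes carry the uniform
profile nearly symmetrically.

Module detection takes the feature genes as seeds on a PPI graph:

```r
ppi <- simulate_ppi(n_nodes = 150, planted_module_size = 10, seed = 2)
stats <- node_statistics(pre$values, sim$true_labels[colnames(pre$values)])
# (with a real PPI graph: read_ppi("interactions.tsv"))
```

Every result is a tibble or has `tidy()`/`glance()` methods, and
`autoplot()` draws the consensus heatmap and the rank-selection curve.
The same workflow is scriptable end to end via `run_pipeline()` (which
writes a JSON manifest that `replay_manifest()` reproduces bitwise) or
from a shell through the thin wrapper:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/scnmf.R", package="scnmf"))') \
    cluster --matrix norm.tsv --k-range 2:5 --runs 30 --seed 1 -o out/
```

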