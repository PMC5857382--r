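# sporegcn

Staged gene co-expression network (GCN) analysis for sporulating bacteria.

Sporulation runs through morphological phases (P0–P6: vegetative growth,
asymmetric division, engulfment, forespore maturation, phase-bright spores),
and genes acting together in that program share expression profiles across
staged transcriptome samples. `sporegcn` reconstructs the co-expression
network behind such data and mines it: genes become nodes, an edge links
genes whose association survives conditioning on all other genes, modules
of co-expressed genes emerge from random-walk community detection, and
unannotated genes wired into a regulon's neighbourhood become sporulation
candidates by guilt-by-association.

The package is aimed at microbial systems-biology analysts with a genes ×
samples expression matrix (RPKM-like or logged), a sample→phase design, and
optionally curated gene sets (regulons, GO classes) in GMT format.

## The model

Edges carry partial correlations. For genes *i*, *j* the weight is

    rho_ij = -omega_ij / sqrt(omega_ii * omega_jj)

with Omega the inverse covariance of the standardized log-expression
profiles. Two estimators are provided: exact covariance inversion (with
optional ridge), and a sparse joint regression that minimises

    1/2 * sum_i w_i || x_i - sum_{j!=i} beta_ij x_j ||^2 + lambda * sum_{i<j} |rho_ij|,
    beta_ij = rho_ij * sqrt(sigma_jj / sigma_ii)

by active-shooting coordinate descent (compiled kernel), with the penalty
chosen by BIC over a log grid and a relaxed refit on the selected support.
The estimate is pruned at |rho| >= 0.35 into an undirected weighted network.
Downstream: walktrap modules cut at maximal modularity
`Q = sum_c [ e_c/m - (d_c/2m)^2 ]`, curation of detached fragments, hubs
(degree >= 5), truncated power-law degree fits
`P(eta) = beta * eta^-gamma * exp(-alpha*eta)`, phase-contrast DEG calling
(fold change + Welch test, BH-corrected), regulon sub-networks with
first-degree expansion, hypergeometric module enrichment, k-means
concordance, and exact two-network intersection for conserved modules.

A synthetic-data generator plants all of this structure (block
partial-correlation modules, cumulative staged DEGs, regulon sets, decoys)
so every stage is testable against known truth.

## Worked example

```r
library(sporegcn)

# a synthetic staged study: 25 planted 3-gene modules + 25 background genes,
# phases P1-P6 x 42 samples, 10% new DEGs per phase at |log2FC| = 2
ds   <- make_staged_expression(synthetic_config(seed = 1))
sets <- make_gene_sets(ds$truth, n_decoys = 5, decoy_size = 10, seed = 2)

res <- run_analyze(ds$expression, ds$design, sets, pipeline_config(seed = 1))
res
#> GCN analysis: 63 nodes, 41 edges; 24 modules (Q = 0.953); 0 hubs

res$updown_counts
#>   contrast up down total
#> 1 P2_vs_P1  5    5    10
#> 2 P3_vs_P1 10   10    20
#> 3 P4_vs_P1 16   14    30
#> 4 P5_vs_P1 19   21    40
#> 5 P6_vs_P1 21   29    50

head(res$enrichment[res$enrichment$fdr < 0.05, c("module", "set", "fdr")], 3)
#>   module        set         fdr
#> 1      1 regulon_01 0.001168442
#> 2     10 regulon_20 0.001168442
#> 3     11 regulon_21 0.001168442
```

Reading the output: 63 of 100 genes survive pruning at rho = 0.35 (the rest
carry no retained association, as expected for the planted background); the
41 edges reassemble the planted modules (adjusted Rand index 0.97 against
truth; modularity 0.953 versus 0.734 for a size-matched random graph); DEG
counts grow 10 → 50 across P2–P6 exactly as planted, and each detected
module's top enrichment is its own planted regulon, never a decoy.

The same analysis as a narrated workflow lives under `analysis/`
(`01_simulate.R` … `07_compare.R`, run in order from the repository root);
each stage prints what it found and writes its tables under `results/`.

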