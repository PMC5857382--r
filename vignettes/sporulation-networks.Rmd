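---
title: "Staged sporulation co-expression networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged sporulation co-expression networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporegcn)
```

## The problem

Sporulating bacilli pass through morphologically defined phases — from
vegetative growth (P0, P1) through asymmetric division (P2), engulfment
(P3), and forespore maturation (P4, P5) to phase-bright spores (P6). Genes
acting together in this program tend to share expression profiles, so an
undirected gene co-expression network (GCN) built from staged transcriptome
data groups functionally related genes into modules and exposes candidate
sporulation genes by guilt-by-association: an unannotated gene wired into a
regulon's neighbourhood is a candidate member of that regulon.

`sporegcn` implements that analysis end to end: partial-correlation network
inference, module detection and curation, topology characterisation,
differential expression over the phase contrasts, regulon sub-network
extraction, gene-set enrichment, and cross-strain network comparison — plus
a synthetic-data generator that plants all of the structure the pipeline is
supposed to find, so every stage is testable against known truth.

## Network inference model

The network is a Gaussian graphical model estimate. For genes $i \ne j$ the
edge weight is the partial correlation
$$\rho^{ij} = -\,\omega_{ij} / \sqrt{\omega_{ii}\,\omega_{jj}},$$
where $\Omega = (\omega_{ij})$ is the inverse covariance of the (log-scale,
per-gene standardized) expression profiles. Unlike marginal correlation,
$\rho^{ij}$ measures association after removing the linear effect of all
other genes, which suppresses the dense indirect correlations that staged
designs induce.

Two estimators are provided:

* **Exact** (`partial_correlations_exact`): invert the sample covariance,
  optionally ridge-regularized (default $10^{-3}\,\mathrm{tr}(S)/p$ when
  $n \le p$). This is the oracle when samples outnumber genes.
* **Sparse joint regression** (`space_fit`, `space_fit_bic`): minimise
  $$\tfrac12 \sum_i w_i \bigl\| x_i - \sum_{j \ne i} \beta_{ij} x_j \bigr\|^2
    + \lambda \sum_{i<j} |\rho^{ij}|,
    \qquad \beta_{ij} = \rho^{ij} \sqrt{\sigma^{jj}/\sigma^{ii}},$$
  which estimates all partial correlations simultaneously under a
  symmetry-respecting lasso penalty. The solver is coordinate descent with
  an active-shooting schedule (full sweeps alternating with cheap sweeps
  over the nonzero pairs; compiled kernel), alternating with re-estimation
  of the precision diagonal $\sigma^{ii}$ from residual variances.
  Regression weights $w_i$ default to uniform; degree-based reweighting can
  be passed explicitly.

**Penalty selection and the relaxed refit.** The analysis fixes only the
post-hoc pruning threshold ($\rho = 0.35$), not the penalty. We
treat $\lambda$ as a nuisance parameter: scan a log-spaced grid (default 8
points over $[0.01, 1] \cdot \lambda_{\max}$, warm starts from sparse to
dense, early stop once BIC has passed its minimum), pick the BIC minimiser,
then re-solve at $\lambda = 0$ restricted to the selected support. The
refit matters: the soft threshold shrinks every retained coefficient by
roughly $\lambda$, and a fixed pruning threshold applied to shrunken values
would systematically under-select; after the refit, 0.35 acts on unshrunk
partial-correlation magnitudes, as it does for the exact estimator. The
grid scan runs at a loosened tolerance (`scan_tol = 1e-4`) since it only
has to rank penalties; the returned estimate is solved at `tol = 1e-6`.

**Pruning.** `prune_to_network` keeps edges with $|\hat\rho^{ij}| \ge 0.35$
by default (ties at the threshold kept). Genes left without any edge drop
out of the network — in real sporulation GCNs this filters out roughly a
third of the genome. A marginal-correlation
(Pearson/Spearman) network is available as the guilt-by-association
baseline.

## Modules, hubs, topology

Modules are detected by the walktrap algorithm (random-walk length $t = 4$,
the algorithm's usual setting; the paper is silent on $t$), with the
dendrogram cut at maximum modularity
$$Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right],$$
computed unweighted by default since pruned edges are treated as
presence/absence (a weighted variant uses $|\hat\rho|$). Vertices are taken
in lexicographic order, making detection deterministic and label-invariant.
Curation then merges each small detached component (default size $\le 5$)
into a single module: raw walktrap output routinely splits an isolated gene
pair into two singletons; merging such detached fragments back into single
modules matches how curated module lists treat them. Curation never drops genes and never splits a module.

Hubs are genes with degree $\ge 5$. The degree distribution is summarised
by a truncated power law
$$P(\eta) = \beta\, \eta^{-\gamma} e^{-\alpha \eta},$$
fitted by least squares on $\log P(\eta)$ over the observed degrees with
positive mass — matching the log–log presentation such distributions are
judged by — with $\alpha \ge 0$ enforced (a negative cutoff estimate is
refit as a pure power law). Maximum-likelihood fitting would weight the
abundant low-degree nodes differently; the least-squares choice is
deliberate and documented. Local clustering coefficients use the
triangles-over-wedges definition with degree-$<2$ nodes assigned 0 (the
mean is reported both with and without them). A uniform $G(n, m)$ random
graph with matching node and edge counts serves as the topology baseline.

## Differential expression over phases

Phases P2–P6 are contrasted against P1 (P0, pre-sporulation, is carried in
the design but never contrasted). Per gene and contrast,
$$\log_2 \mathrm{FC} = \log_2 \frac{\bar x_{\mathrm{target}} + c}
                                   {\bar x_{\mathrm{ref}} + c}$$
with pseudocount $c = 1$ on the RPKM-like scale. With $\ge 2$ replicates a
Welch $t$-test on $\log_2(x + c)$ supplies p-values, BH-adjusted within
contrast; a call requires $|\log_2 \mathrm{FC}| \ge 1$ **and** FDR < 0.05.
With a single replicate (e.g. replicate-averaged input) the pipeline drops
to fold-change-only mode with a logged caveat. This transparent statistic
deliberately replaces webserver-based DEG calling; it reproduces the
contrast structure, not any specific external tool's totals.

Downstream summaries: up/down counts per contrast, the Venn partition of
the per-contrast DEG sets (every union gene in exactly one sector), the top
10% of genes by minimum phase-mean expression, and a network overlay
classifying nodes as consistently up, consistently down, mixed, or
unaffected.

## Sub-networks, enrichment, comparison

Regulon gene sets are mapped onto the network and expanded by first-degree
neighbours; the expansion returns the induced subgraph (neighbour–neighbour
edges included — the induced-subgraph semantics is the documented choice, with a
seeds-incident-only mode available). Neighbour-only genes are the
guilt-by-association candidates. Expression of a sub-network can be ordered
for heatmaps by agglomerative hierarchical clustering of rows and columns
(Euclidean distance throughout; average linkage as the documented default).

Enrichment is a hypergeometric over-representation test per module × set
with BH correction across all tests jointly. The universe defaults to the
network's gene set rather than the genome: modules are partitions of the
network, and a genome universe would inflate significance from genes
already filtered out at inference (a genome-universe mode exists). Only
over-representation is tested, and BH is the default correction; both
choices are logged.

k-means clustering of standardized expression profiles (best of 10 starts)
provides the module-independent grouping; `concordance` reports the
adjusted Rand index and contingency table between clusters and modules, and
`silhouette_scan` substitutes for external tools' choice of $k$. Because
profiles are row-standardized, clusters reflect profile shape; on data
where staged mean shifts dominate the profiles, k-means clusters track DEG
onset groups rather than network modules, and the concordance is
correspondingly lower — visible on the synthetic data with planted DEGs.

Two networks are compared by exact intersection: nodes matched by an
explicit one-to-one ID map (default: identity on shared gene names,
appropriate when both strains' reads are mapped to the same reference
genome), edges kept when present in both, both weights retained. Walktrap
on the intersection yields conserved modules, which are then
enrichment-tested.

## The synthetic-data generator

The generator (`synthetic_config`, `make_staged_expression`) plants exactly
the structure each stage must recover:

* **Modules**: a block precision matrix with $\omega_{ii} = 1$ and
  $\omega_{ij} = -\rho_w$ inside each module, so every within-module pair
  has partial correlation exactly $\rho_w$ and background genes are
  independent. The block is positive definite only when
  $\rho_w (m - 1) < 1$; infeasible configurations are rejected with a
  diagnostic naming the block (no silent diagonal inflation, which would
  change the planted correlations).
* **Staging**: planted DEGs receive a mean shift of $\pm 2$ log2 units from
  their onset phase onward (cumulative by default — once differential,
  always differential — so DEG counts are non-decreasing over phases, with
  a transient mode for stress tests). Signs are random per gene.
* **Scale**: the correlated Gaussian draw is rescaled to unit per-gene
  variance (diagonal rescaling leaves partial correlations untouched) and
  multiplied by `noise_sd`, then exported as $100 \cdot 2^{\mathrm{signal}}$
  — non-negative, RPKM-like, with export-scale fold changes equal to
  $2^{\mathrm{effect}}$.
* **Regulons**: one gene set per planted module, plus uniformly random
  decoy sets for calibrating enrichment specificity.

**Default study conditions.** 25 modules of 3 genes with $\rho_w = 0.45$,
25 background genes, 6 phases × 42 samples (252 conditions, the scale of
a tiling-array compendium),
`noise_sd` 0.3, 10% new DEGs per phase at 2 log2 units. Module size 3 is
forced by arithmetic, not convenience: the PD constraint caps
$\rho_w < 1/(m-1)$, so modules whose partial correlations clear the 0.35
pruning threshold cannot be larger — consistent with real sporulation
GCNs, where thousands of genes fall into hundreds of small modules. A consequence
worth noting when interpreting tests: with ~10 genes sharing each planted
DEG onset profile, the staged shifts themselves induce genuine partial
correlations between co-onset genes; these are real features of the
generated data, kept small at the default scale but dominant if the
generator is pushed to few genes per onset group with tiny noise.

**What the generator does not emulate**: read-count noise, library-size
effects, batch structure, transcription-factor cascades, or two genomes
with true ortholog divergence (the "second strain" of the comparison
analyses is a gene-subset twin). Passing tests demonstrate the machinery
recovers planted linear-Gaussian structure; they do not certify performance
on count data or on regulatory networks with nonlinear effects.

## Numerical choices and degenerate inputs

* Zero-variance genes are dropped (with IDs logged) before standardization.
* Coordinate-descent convergence: largest single-parameter change below
  `tol` (default $10^{-6}$); non-convergence is an error, not a warning.
* Ties at the pruning threshold are kept ($\ge$).
* `venn_partition` accepts at most 6 sets (2^k sectors become unreadable).
* Degenerate all-identical input to `bicluster_order` returns the input
  order with a warning.
* Module labels are dense integers ordered by decreasing module size, ties
  by smallest member ID, so runs are comparable.
* Every random step (sampling, k-means starts, random baselines, decoys)
  takes an explicit seed; a single pipeline seed is fanned out in fixed
  offsets to the stages, and rerunning any stage alone reproduces its
  output byte for byte.

## Problem sizes used by the checks

The packaged checks run the pipeline at the default 100-gene × 252-sample
scale and verify: oracle equivalence of the exact estimator ($p \le 20$,
exact to $10^{-8}$), agreement of the unpenalized joint regression with the
exact estimator ($10^{-4}$ at $p = 10$, $n = 5000$), support recovery on a
planted GGM ($p = 100$, $n = 300$, F1 at the best grid penalty), modularity
against a literal-formula oracle on all graphs up to 8 nodes, walktrap
recovery on planted-partition graphs, truncated power-law parameter
recovery (noiseless to $10^{-6}$; sampled within ±0.3), hypergeometric
agreement with exhaustive enumeration ($N \le 12$) and decoy calibration
over 200 null simulations, DEG sensitivity/FPR on replicated staged data,
and end-to-end module/regulon/conservation recovery on synthetic twins.

## Known limitations

* The generator's equicorrelated blocks cannot represent large
  strong-partial-correlation modules (PD constraint above); hub-dominated
  topologies are exercised with explicit toy graphs instead.
* BIC-based penalty selection is conservative under the collinearity that
  staged mean shifts induce; the relaxed refit mitigates, but edge recall
  on heavily staged data trails the exact estimator when $n > p$. The
  pipeline exposes `method = "exact"` for exactly that regime.
* The DEG statistic is a transparent substitute, not a reimplementation of
  any external tool; absolute DEG totals are not comparable to
  webserver-derived counts.
* Cross-strain comparison assumes shared gene identifiers; ortholog
  inference is out of scope.
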