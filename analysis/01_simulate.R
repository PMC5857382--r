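#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-strain sporulation study.
#
# Strain A carries 25 planted co-expression modules (3 genes each, within-
# module partial correlation 0.45) plus 25 background genes, sampled over
# phases P1-P6 with 42 samples per phase. Ten percent of genes newly become
# differentially expressed at each phase after P1 (|log2FC| = 2, cumulative).
# Strain B is a reduced genome sharing modules 1-15 and the background,
# standing in for a related isolate whose reads map to the same reference.

suppressMessages(library(sporegcn))

seed <- 1L
cfg <- synthetic_config(seed = seed)
ds <- run_simulate(cfg, out_dir = "results/data/strain_a")

truth <- ds$truth$planted_partition
shared_genes <- names(truth)[truth %in% 0:15]
ds_b <- list(expression = ds$expression[shared_genes, ],
             design = ds$design,
             truth = list(
               planted_partition = truth[shared_genes],
               planted_regulons = ds$truth$planted_regulons,
               planted_degs = lapply(ds$truth$planted_degs, function(d)
                 d[d$gene %in% shared_genes, ]),
               precision = ds$truth$precision[shared_genes, shared_genes],
               config = cfg))
class(ds_b) <- "synthetic_dataset"
write_synthetic_dataset(ds_b, "results/data/strain_b")

sets <- make_gene_sets(ds$truth, n_decoys = 5, decoy_size = 10,
                       seed = seed + 1L)
write_gmt(sets, "results/data/gene_sets.gmt")

cat(sprintf(
  "strain A: %d genes x %d samples; %d planted modules; %d planted DEGs by P6\n",
  nrow(ds$expression), ncol(ds$expression), max(truth),
  nrow(ds$truth$planted_degs[["P6_vs_P1"]])))
cat(sprintf("strain B: %d genes (modules 1-15 + background)\n",
            nrow(ds_b$expression)))
cat(sprintf("gene sets: %d (planted regulons + 5 decoys)\n",
            length(sets$sets)))
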