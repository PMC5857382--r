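#!/usr/bin/env Rscript
# Stage 7: two-strain comparison.
#
# Reconstructs the strain B network with the same settings, intersects it
# with strain A (identity mapping on shared gene names), detects conserved
# modules on the intersection and tests their regulon enrichment.

suppressMessages(library(sporegcn))

expr_b <- read_expression_tsv("results/data/strain_b/expression.tsv")
net_a <- read_edge_list("results/network_a/edges.tsv")
sets <- read_gmt("results/data/gene_sets.gmt")
dir.create("results/comparison", showWarnings = FALSE)

fit_b <- space_fit_bic(log_transform(expr_b))
net_b <- prune_to_network(fit_b, rho_threshold = 0.35)
write_edge_list(net_b, "results/comparison/network_b_edges.tsv")
cat(sprintf("strain B network: %d nodes, %d edges\n",
            igraph::vcount(net_b), igraph::ecount(net_b)))

cmp <- run_compare(net_a, net_b, sets, out_dir = "results/comparison")
cat(sprintf("intersection: %d shared nodes, %d shared edges\n",
            cmp$summary$shared_nodes, cmp$summary$shared_edges))

if (!is.null(cmp$conserved)) {
  cons <- cmp$conserved
  cat(sprintf("conserved modules: %d (Q = %.3f)\n",
              length(unique(cons$partition$assignment)), cons$partition$q))
  sig <- cons$enrichment[cons$enrichment$fdr < 0.05, ]
  cat(sprintf("%d conserved modules with a significant regulon (BH < 0.05)\n",
              length(unique(sig$module))))
  truth <- utils::read.delim("results/data/strain_a/truth_partition.tsv")
  planted <- stats::setNames(truth$module_id, truth$gene_id)
  strain_specific <- names(planted)[planted > 15]
  cat(sprintf("strain-A-specific module genes in the intersection: %d (expect 0)\n",
              length(intersect(igraph::V(cmp$intersection)$name,
                               strain_specific))))
}
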