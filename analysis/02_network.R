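#!/usr/bin/env Rscript
# Stage 2: reconstruct the strain A co-expression network.
#
# Sparse partial correlations by joint regression (BIC-selected penalty,
# relaxed refit), pruned at |rho| >= 0.35; genes left without an edge are
# filtered out of the network, as they would be for real data.

suppressMessages(library(sporegcn))

expr <- read_expression_tsv("results/data/strain_a/expression.tsv")
lx <- log_transform(expr)

fit <- space_fit_bic(lx)
cat(sprintf("selected penalty %.3g (BIC path over %d points)\n",
            attr(fit, "lambda"), nrow(attr(fit, "path"))))

net <- prune_to_network(fit, rho_threshold = 0.35)
dir.create("results/network_a", recursive = TRUE, showWarnings = FALSE)
write_edge_list(net, "results/network_a/edges.tsv")
write_graphml(net, "results/network_a/network.graphml")

cat(sprintf("network: %d nodes, %d edges (%.0f%% of genes retained)\n",
            igraph::vcount(net), igraph::ecount(net),
            100 * igraph::vcount(net) / nrow(expr)))

# how many planted within-module edges survive pruning
truth <- utils::read.delim("results/data/strain_a/truth_partition.tsv")
mods <- truth$module_id[match(igraph::as_edgelist(net)[, 1], truth$gene_id)] ==
        truth$module_id[match(igraph::as_edgelist(net)[, 2], truth$gene_id)]
cat(sprintf("%d of %d edges connect genes of the same planted module\n",
            sum(mods), igraph::ecount(net)))
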