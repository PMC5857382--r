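#!/usr/bin/env Rscript
# Stage 3: modules, hubs and topology of the strain A network.
#
# Walktrap modules cut at maximal modularity, curation of small detached
# components, hub census (degree >= 5), degree distribution with a truncated
# power-law fit, clustering coefficients, and a size-matched random baseline.

suppressMessages(library(sporegcn))

net <- read_edge_list("results/network_a/edges.tsv")
truth <- utils::read.delim("results/data/strain_a/truth_partition.tsv")

part <- curate_modules(walktrap_modules(net), net, max_detached_size = 5)
write_partition_tsv(part, "results/network_a/modules.tsv")
cat(sprintf("%d modules, Q = %.3f\n",
            length(unique(part$assignment)), part$q))

planted <- stats::setNames(truth$module_id, truth$gene_id)
sh <- intersect(names(part$assignment), names(planted))
cat(sprintf("adjusted Rand index vs planted modules: %.3f (%d genes)\n",
            mclust::adjustedRandIndex(part$assignment[sh], planted[sh]),
            length(sh)))

hubs <- extract_hubs(net)
cat(sprintf("%d hubs at degree >= 5; max degree %d\n",
            nrow(hubs), max(igraph::degree(net))))
utils::write.table(hubs, "results/network_a/hubs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cen <- component_census(net)
utils::write.table(cen, "results/network_a/component_census.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("components: %s\n",
            paste(sprintf("%dx size-%d", cen$n_components, cen$size),
                  collapse = ", ")))

dd <- degree_distribution(net)
fit <- tryCatch(fit_truncated_power_law(dd), error = function(e) NULL)
if (!is.null(fit)) {
  print(fit)
  utils::write.table(
    data.frame(parameter = c("beta", "gamma", "alpha", "rss"),
               value = c(fit$beta, fit$gamma, fit$alpha, fit$rss)),
    "results/network_a/powerlaw.tsv", sep = "\t", quote = FALSE,
    row.names = FALSE)
}

cc <- clustering_coefficients(net)
cat(sprintf("mean clustering coefficient %.3f (%.3f over degree >= 2)\n",
            cc$mean_all, cc$mean_deg2plus))

base <- random_baseline(igraph::vcount(net), igraph::ecount(net), seed = 1001L)
qb <- walktrap_modules(base)$q
cat(sprintf("modularity %.3f vs %.3f for a size-matched random graph\n",
            part$q, qb))
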