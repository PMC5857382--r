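#!/usr/bin/env Rscript
# Stage 4: differential expression over the sporulation time course.
#
# Phases P2-P6 are each contrasted against P1 (|log2FC| >= 1, BH FDR < 0.05);
# up/down counts, the Venn partition of the per-contrast DEG sets, the top
# 10% consistently expressed genes, and the DEG overlay on the network.

suppressMessages(library(sporegcn))

expr <- read_expression_tsv("results/data/strain_a/expression.tsv")
design <- read_design_tsv("results/data/strain_a/design.tsv")
net <- read_edge_list("results/network_a/edges.tsv")
dir.create("results/degs_a", showWarnings = FALSE)

degs <- call_degs(expr, design)
utils::write.table(degs, "results/degs_a/degs.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cnt <- updown_counts(degs)
utils::write.table(cnt, "results/degs_a/updown_counts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("DEG counts per contrast (up/down):\n")
print(cnt, row.names = FALSE)

truth_degs <- utils::read.delim("results/data/strain_a/truth_degs.tsv")
called <- deg_sets(degs)
sens <- mean(unlist(lapply(names(called), function(ct)
  truth_degs$gene[truth_degs$contrast == ct] %in% called[[ct]])))
cat(sprintf("sensitivity vs planted DEGs: %.3f\n", sens))

venn <- venn_partition(called)
utils::write.table(venn, "results/degs_a/venn.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("venn: %d genes in the union, %d in every contrast, %d unique to P6\n",
            sum(venn$count),
            venn$count[venn$pattern == "11111"],
            ifelse(any(venn$pattern == "00001"),
                   venn$count[venn$pattern == "00001"], 0L)))

top <- rank_top_expressed(expr, design, fraction = 0.10)
utils::write.table(top, "results/degs_a/top_expressed.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("top 10%% most expressed: %d genes, min phase-mean score %.1f\n",
            nrow(top), min(top$score)))

ov <- overlay_on_network(net, degs)
utils::write.table(data.frame(gene_id = names(ov), status = unname(ov)),
                   "results/degs_a/network_overlay.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("network overlay:", paste(names(table(ov)), table(ov), collapse = ", "),
    "\n")
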