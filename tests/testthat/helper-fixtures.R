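# Shared fixtures, built in code at test time.

ari <- mclust::adjustedRandIndex

# small, fast synthetic dataset used across module tests
small_config <- function(seed = 11, samples_per_phase = 6,
                         deg_fraction_per_phase = 0.1, ...) {
  synthetic_config(n_genes = 30, module_sizes = rep(3L, 6),
                   within_pcor = 0.45,
                   samples_per_phase = samples_per_phase,
                   deg_fraction_per_phase = deg_fraction_per_phase,
                   effect_log2fc = 2, noise_sd = 0.1, seed = seed, ...)
}

# igraph from an edge list given as c(a,b, c,d, ...) with unit weights
toy_graph <- function(pairs, weights = NULL, isolated = character()) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  df <- data.frame(gene_a = m[, 1], gene_b = m[, 2],
                   weight = if (is.null(weights)) rep(1, nrow(m)) else weights,
                   stringsAsFactors = FALSE)
  nodes <- sort(unique(c(m[, 1], m[, 2], isolated)))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

clique_graph <- function(ids) {
  prs <- t(utils::combn(ids, 2))
  toy_graph(as.vector(t(prs)))
}

# named assignment vector helper
assign_of <- function(genes, labels) stats::setNames(as.integer(labels), genes)

# expression matrix with given rows
expr_of <- function(values, genes = NULL, samples = NULL,
                    log_transformed = TRUE) {
  m <- as.matrix(values)
  rownames(m) <- if (is.null(genes)) sprintf("g%02d", seq_len(nrow(m))) else genes
  colnames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(ncol(m))) else samples
  expression_matrix(m, log_transformed = log_transformed)
}
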