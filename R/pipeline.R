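#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis with its default. All
#' thresholds are validated here, never silently replaced.
#'
#' @param method network inference: `"space"` (sparse joint regression with
#'   BIC-selected penalty; default), `"exact"` (covariance inversion) or
#'   `"marginal"` (thresholded Pearson correlation).
#' @param rho_threshold pruning threshold on |partial correlation|
#'   (default 0.35, the conventional cutoff for sporulation GCNs).
#' @param lambda_grid optional penalty grid for the sparse estimator.
#' @param walktrap_steps random-walk length for module detection.
#' @param curation_max_size largest detached component merged into a single
#'   module during curation.
#' @param hub_min_degree minimum degree of a hub (default 5).
#' @param lfc_threshold,alpha,pseudocount DEG-calling settings.
#' @param min_module_size smallest module tested for enrichment. Default 2:
#'   the planted modules of the synthetic data are necessarily small (see
#'   [synthetic_config()]), and the network universe already guards against
#'   spurious tiny-module hits.
#' @param kmeans_k number of k-means clusters; `NULL` = number of detected
#'   modules of at least `min_module_size` genes.
#' @param subnetwork_sets names of the gene sets used as sub-network seeds;
#'   `NULL` = the first two sets of the collection (mirroring the
#'   two-regulon sub-network analysis; name the regulons of interest
#'   explicitly for real data).
#' @param seed global seed, fanned out deterministically to the stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("space", "exact", "marginal"),
                            rho_threshold = 0.35,
                            lambda_grid = NULL,
                            walktrap_steps = 4,
                            curation_max_size = 5,
                            hub_min_degree = 5,
                            lfc_threshold = 1,
                            alpha = 0.05,
                            pseudocount = 1,
                            min_module_size = 2,
                            kmeans_k = NULL,
                            subnetwork_sets = NULL,
                            seed = 1L) {
  method <- match.arg(method)
  if (rho_threshold <= 0 || rho_threshold >= 1)
    stop("rho_threshold must lie in (0, 1)")
  stopifnot(walktrap_steps >= 1, curation_max_size >= 1, hub_min_degree >= 1,
            lfc_threshold >= 0, alpha > 0, alpha <= 1, pseudocount > 0,
            min_module_size >= 1)
  structure(list(method = method, rho_threshold = rho_threshold,
                 lambda_grid = lambda_grid, walktrap_steps = walktrap_steps,
                 curation_max_size = curation_max_size,
                 hub_min_degree = hub_min_degree,
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 pseudocount = pseudocount,
                 min_module_size = min_module_size, kmeans_k = kmeans_k,
                 subnetwork_sets = subnetwork_sets, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Generate and write the synthetic dataset
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory.
#' @return invisibly, the `synthetic_dataset`; files (expression, design,
#'   regulon GMT, truth sidecars, manifest) are written under `out_dir`.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir) {
  dataset <- make_staged_expression(config)
  paths <- write_synthetic_dataset(dataset, out_dir)
  write_manifest(file.path(out_dir, "manifest.txt"),
                 unclass(config), files = paths)
  invisible(dataset)
}

#' Full single-strain analysis
#'
#' Chains the stages: log-transform, network inference
#' (partial-correlation estimation and pruning), walktrap module detection
#' and curation, hubs and component census, topology (degree distribution,
#' truncated power-law fit, clustering coefficients, matched random
#' baseline), DEG calling with up/down counts and Venn partition,
#' top-expressed ranking, DEG overlay, regulon sub-network extraction with
#' bicluster ordering, module gene-set enrichment, and k-means concordance.
#'
#' @param expr expression matrix (non-negative scale unless flagged logged).
#' @param design phase design.
#' @param sets optional [gene_set_collection()] of regulons / GO classes.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage output is
#'   written (TSV / GMT / GraphML) together with a manifest.
#' @return list of class `gcn_analysis` with the per-stage results.
#' @export
run_analyze <- function(expr, design, sets = NULL,
                        config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  logx <- log_transform(expr, config$pseudocount)

  message("inference method: ", config$method,
          "; pruning at |rho| >= ", config$rho_threshold)
  net <- switch(config$method,
    exact = prune_to_network(partial_correlations_exact(logx),
                             config$rho_threshold),
    space = {
      fit <- space_fit_bic(logx, lambda_grid = config$lambda_grid)
      message("BIC-selected lambda: ", signif(attr(fit, "lambda"), 4))
      prune_to_network(fit, config$rho_threshold)
    },
    marginal = marginal_correlation_network(logx,
                                            threshold = config$rho_threshold))

  partition_raw <- walktrap_modules(net, steps = config$walktrap_steps)
  partition <- curate_modules(partition_raw, net,
                              max_detached_size = config$curation_max_size)
  hubs <- extract_hubs(net, min_degree = config$hub_min_degree)
  census <- component_census(net)

  dd <- degree_distribution(net)
  plaw <- tryCatch(fit_truncated_power_law(dd), error = function(e) {
    message("power-law fit skipped: ", conditionMessage(e)); NULL
  })
  cc <- clustering_coefficients(net)
  baseline <- random_baseline(igraph::vcount(net), igraph::ecount(net),
                              seed = config$seed + 1000L)
  baseline_q <- walktrap_modules(baseline, steps = config$walktrap_steps)$q

  degs <- call_degs(expr, design, lfc_threshold = config$lfc_threshold,
                    alpha = config$alpha, pseudocount = config$pseudocount)
  counts <- updown_counts(degs)
  venn <- venn_partition(deg_sets(degs))
  top <- rank_top_expressed(expr, design)
  overlay <- overlay_on_network(net, degs)

  subnet <- NULL
  mapping <- NULL
  enrichment <- NULL
  if (!is.null(sets)) {
    mapping <- map_gene_sets(net, sets)
    seed_sets <- config$subnetwork_sets
    if (is.null(seed_sets))
      seed_sets <- names(sets$sets)[seq_len(min(2, length(sets$sets)))]
    seeds <- unique(unlist(sets$sets[seed_sets]))
    subnet <- tryCatch(first_degree_expansion(net, seeds),
                       error = function(e) {
                         message("sub-network skipped: ", conditionMessage(e))
                         NULL
                       })
    if (!is.null(subnet) && igraph::vcount(subnet) >= 2)
      attr(subnet, "bicluster") <- bicluster_order(
        logx[intersect(rownames(logx), igraph::V(subnet)$name), ,
             drop = FALSE])
    enrichment <- enrich_partition(partition, sets,
                                   min_module_size = config$min_module_size)
  }

  k <- config$kmeans_k
  if (is.null(k))
    k <- max(1L, sum(table(partition$assignment) >= config$min_module_size))
  clustering <- kmeans_clusters(logx, k = min(k, nrow(logx)),
                                seed = config$seed + 2000L)
  conc <- concordance(partition, clustering)

  res <- structure(list(network = net, partition = partition,
                        partition_raw = partition_raw, hubs = hubs,
                        component_census = census,
                        degree_distribution = dd, power_law = plaw,
                        clustering_coefficients = cc,
                        baseline_q = baseline_q, degs = degs,
                        updown_counts = counts, venn = venn,
                        top_expressed = top, overlay = overlay,
                        gene_set_mapping = mapping, subnetwork = subnet,
                        enrichment = enrichment, clustering = clustering,
                        concordance = conc, config = config),
                   class = "gcn_analysis")
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

write_analysis <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  files <- c(p("network_edges.tsv"), p("network.graphml"), p("modules.tsv"),
             p("hubs.tsv"), p("component_census.tsv"), p("degs.tsv"),
             p("updown_counts.tsv"), p("venn.tsv"), p("top_expressed.tsv"),
             p("deg_overlay.tsv"), p("topology.tsv"))
  write_edge_list(res$network, files[1])
  write_graphml(res$network, files[2])
  write_partition_tsv(res$partition, files[3])
  utils::write.table(res$hubs, files[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$component_census, files[5], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$degs, files[6], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$updown_counts, files[7], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$venn, files[8], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$top_expressed, files[9], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(res$overlay),
                                status = unname(res$overlay)),
                     files[10], sep = "\t", quote = FALSE, row.names = FALSE)
  topo <- data.frame(
    key = c("n_nodes", "n_edges", "modularity_q", "baseline_q", "n_hubs",
            "mean_clustering_all", "mean_clustering_deg2plus",
            "powerlaw_beta", "powerlaw_gamma", "powerlaw_alpha"),
    value = c(igraph::vcount(res$network), igraph::ecount(res$network),
              res$partition$q, res$baseline_q, nrow(res$hubs),
              res$clustering_coefficients$mean_all,
              res$clustering_coefficients$mean_deg2plus,
              if (is.null(res$power_law)) rep(NA_real_, 3) else
                c(res$power_law$beta, res$power_law$gamma,
                  res$power_law$alpha)))
  utils::write.table(topo, files[11], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(res$enrichment)) {
    f <- p("enrichment.tsv")
    utils::write.table(res$enrichment, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  write_manifest(p("manifest.txt"), unclass(res$config), files = files)
  invisible(out_dir)
}

#' @export
print.gcn_analysis <- function(x, ...) {
  cat("GCN analysis: ", igraph::vcount(x$network), " nodes, ",
      igraph::ecount(x$network), " edges; ",
      length(unique(x$partition$assignment)), " modules (Q = ",
      round(x$partition$q, 3), "); ", nrow(x$hubs), " hubs\n", sep = "")
  invisible(x)
}

#' Compare two strains' networks
#'
#' Intersects the two inferred networks (identity mapping on shared gene
#' names unless `idmap` is given), detects conserved modules on the
#' intersection and tests their gene-set enrichment. An empty intersection
#' is reported, not an error.
#'
#' @param res_a,res_b `gcn_analysis` results (or bare igraph networks).
#' @param sets optional [gene_set_collection()] for conserved-module
#'   enrichment.
#' @param idmap optional data.frame (`id_a`, `id_b`) mapping strain B gene
#'   IDs onto strain A.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `gcn_comparison`: `intersection`, `conserved`
#'   (partition + enrichment, or `NULL`), `summary` (shared node/edge
#'   counts, `no_shared_structure` flag).
#' @export
run_compare <- function(res_a, res_b, sets = NULL, idmap = NULL,
                        config = pipeline_config(), out_dir = NULL) {
  net_a <- if (inherits(res_a, "gcn_analysis")) res_a$network else res_a
  net_b <- if (inherits(res_b, "gcn_analysis")) res_b$network else res_b
  inter <- network_intersection(net_a, net_b, idmap = idmap)
  conserved <- NULL
  if (igraph::ecount(inter) > 0 && !is.null(sets)) {
    conserved <- conserved_modules(inter, sets,
                                   min_module_size = config$min_module_size,
                                   steps = config$walktrap_steps)
  } else if (igraph::ecount(inter) == 0) {
    message("no shared structure: intersection has ",
            igraph::vcount(inter), " nodes and 0 edges")
  }
  out <- structure(list(
    intersection = inter, conserved = conserved,
    summary = list(shared_nodes = igraph::vcount(inter),
                   shared_edges = igraph::ecount(inter),
                   no_shared_structure = igraph::ecount(inter) == 0)),
    class = "gcn_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(out_dir, c("intersection_edges.tsv",
                                  "intersection.graphml"))
    write_edge_list(inter, files[1])
    write_graphml(inter, files[2])
    if (!is.null(conserved)) {
      f2 <- file.path(out_dir, c("conserved_modules.tsv",
                                 "conserved_enrichment.tsv"))
      write_partition_tsv(conserved$partition, f2[1])
      utils::write.table(conserved$enrichment, f2[2], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f2)
    }
    write_manifest(file.path(out_dir, "manifest.txt"), unclass(config),
                   files = files)
  }
  out
}
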