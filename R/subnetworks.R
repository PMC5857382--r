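#' Map gene sets onto a network
#'
#' Annotates every node with the (possibly empty) list of sets containing
#' it, and reports per-set coverage: how many members are present in the
#' network versus absent (filtered out during reconstruction).
#'
#' @param net igraph network.
#' @param sets a [gene_set_collection()].
#' @return list: `annotation` (named list node -> character vector of set
#'   names) and `coverage` (data.frame set, size, present, absent).
#' @export
map_gene_sets <- function(net, sets) {
  stopifnot(inherits(sets, "gene_set_collection"))
  nodes <- igraph::V(net)$name
  annotation <- stats::setNames(
    lapply(nodes, function(g)
      names(sets$sets)[vapply(sets$sets, function(s) g %in% s, logical(1))]),
    nodes)
  coverage <- data.frame(
    set = names(sets$sets),
    size = lengths(sets$sets),
    present = vapply(sets$sets, function(s) sum(s %in% nodes), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  coverage$absent <- coverage$size - coverage$present
  list(annotation = annotation, coverage = coverage)
}

#' First-degree expansion of seed genes
#'
#' Extracts the sub-network spanned by the seed genes present in the network
#' together with every gene directly connected to them. By default the
#' induced subgraph is returned, i.e. neighbour-neighbour edges are
#' included; `seeds_incident_only = TRUE` restricts edges to those touching
#' a seed. Neighbour-only genes are the guilt-by-association candidates:
#' linked to the seed sets without belonging to them.
#'
#' @param net igraph network.
#' @param seeds character vector of seed gene IDs; at least one must be in
#'   the network.
#' @param seeds_incident_only drop neighbour-neighbour edges.
#' @return igraph sub-network with vertex attribute `role` (`"seed"` /
#'   `"neighbor"`); every edge exists in the parent network.
#' @export
first_degree_expansion <- function(net, seeds, seeds_incident_only = FALSE) {
  seeds_in <- intersect(seeds, igraph::V(net)$name)
  if (!length(seeds_in))
    stop("no seed gene is present in the network; missing: ",
         paste(utils::head(seeds, 10), collapse = ", "))
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(net, seeds_in),
                             function(v) v$name)))
  nodes <- sort(union(seeds_in, nb))
  sub <- igraph::induced_subgraph(net, nodes)
  if (seeds_incident_only) {
    el <- igraph::as_edgelist(sub)
    drop <- !(el[, 1] %in% seeds_in | el[, 2] %in% seeds_in)
    sub <- igraph::delete_edges(sub, which(drop))
  }
  igraph::V(sub)$role <- ifelse(igraph::V(sub)$name %in% seeds_in,
                                "seed", "neighbor")
  sub <- igraph::set_graph_attr(sub, "n_seeds", length(seeds_in))
  canonical_order(sub)
}

#' Bi-directional hierarchical ordering for heatmaps
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) on both gene rows and sample columns; returns the leaf orders
#' and, optionally, a flat cut of the gene dendrogram.
#'
#' @param expr expression matrix restricted to the genes of interest
#'   (>= 2 genes and >= 2 samples).
#' @param k optional number of flat row clusters.
#' @return list: `row_order`, `col_order` (integer permutations),
#'   `row_hclust`, `col_hclust`, and `row_clusters` (named, when `k` given).
#' @export
bicluster_order <- function(expr, k = NULL) {
  if (nrow(expr) < 2 || ncol(expr) < 2)
    stop("need at least 2 genes and 2 samples")
  d_row <- stats::dist(expr)
  d_col <- stats::dist(t(expr))
  if (max(d_row) < .Machine$double.eps * 100) {
    warning("all gene profiles identical; returning input order")
    return(list(row_order = seq_len(nrow(expr)),
                col_order = seq_len(ncol(expr)),
                row_hclust = NULL, col_hclust = NULL,
                row_clusters = if (!is.null(k))
                  stats::setNames(rep(1L, nrow(expr)), rownames(expr))))
  }
  hr <- stats::hclust(d_row, method = "average")
  hc <- stats::hclust(d_col, method = "average")
  list(row_order = hr$order, col_order = hc$order,
       row_hclust = hr, col_hclust = hc,
       row_clusters = if (!is.null(k))
         stats::cutree(hr, k = k))
}

#' Intersect two networks
#'
#' Nodes are matched through `idmap` (one-to-one; identity on shared gene
#' names by default, appropriate when both strains' reads are mapped to the
#' same reference genome). The intersection keeps the node pairs present in
#' both networks and the edges present (after mapping) in both; the two
#' original weights are retained as edge attributes `weight_a` / `weight_b`
#' (and `weight` = mean absolute weight for downstream weighted operations).
#' Node names in the result are those of network A.
#'
#' @param net_a,net_b igraph networks.
#' @param idmap `NULL` (identity) or data.frame with columns `id_a`, `id_b`.
#' @return igraph network.
#' @export
network_intersection <- function(net_a, net_b, idmap = NULL) {
  if (is.null(idmap)) {
    shared <- intersect(igraph::V(net_a)$name, igraph::V(net_b)$name)
    idmap <- data.frame(id_a = shared, id_b = shared,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id_a", "id_b") %in% names(idmap)))
  if (anyDuplicated(idmap$id_a) || anyDuplicated(idmap$id_b))
    stop("idmap must be one-to-one (duplicated IDs found)")
  map <- stats::setNames(idmap$id_a, idmap$id_b)
  nodes <- intersect(intersect(igraph::V(net_a)$name, idmap$id_a),
                     map[intersect(igraph::V(net_b)$name, idmap$id_b)])
  edge_key <- function(el) {
    swap <- el[, 1] > el[, 2]
    paste(ifelse(swap, el[, 2], el[, 1]), ifelse(swap, el[, 1], el[, 2]),
          sep = "\t")
  }
  el_a <- igraph::as_edgelist(net_a)
  el_b <- igraph::as_edgelist(net_b)
  if (nrow(el_b)) el_b[] <- ifelse(el_b %in% names(map), map[el_b], NA)
  key_a <- if (nrow(el_a)) edge_key(el_a) else character()
  key_b <- if (nrow(el_b)) edge_key(el_b[stats::complete.cases(el_b), ,
                                         drop = FALSE]) else character()
  w_a <- stats::setNames(if (nrow(el_a)) igraph::E(net_a)$weight else numeric(),
                         key_a)
  w_b_all <- if (nrow(igraph::as_edgelist(net_b)))
    igraph::E(net_b)$weight else numeric()
  keep_b <- if (length(w_b_all)) stats::complete.cases(el_b) else logical()
  w_b <- stats::setNames(w_b_all[keep_b], key_b)
  common <- intersect(key_a, key_b)
  common <- common[vapply(strsplit(common, "\t"), function(pr)
    all(pr %in% nodes), logical(1))]
  prs <- do.call(rbind, strsplit(common, "\t"))
  edges <- if (length(common))
    data.frame(gene_a = prs[, 1], gene_b = prs[, 2],
               weight_a = unname(w_a[common]), weight_b = unname(w_b[common]),
               stringsAsFactors = FALSE)
  else data.frame(gene_a = character(), gene_b = character(),
                  weight_a = numeric(), weight_b = numeric())
  edges$weight <- (abs(edges$weight_a) + abs(edges$weight_b)) / 2
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = sort(nodes)))
  igraph::set_graph_attr(g, "method", "intersection")
}

#' Conserved modules of an intersection network
#'
#' Walktrap modules on the intersection of two networks, followed by
#' hypergeometric gene-set enrichment of each module.
#'
#' @param intersection network from [network_intersection()] (>= 1 edge).
#' @param sets a [gene_set_collection()].
#' @param min_module_size smallest module tested for enrichment.
#' @param steps walktrap random-walk length.
#' @return list: `partition` ([module_partition()]) and `enrichment`
#'   (data.frame from [enrich_partition()]).
#' @export
conserved_modules <- function(intersection, sets, min_module_size = 2,
                              steps = 4) {
  if (igraph::ecount(intersection) == 0)
    stop("no conserved structure: the intersection network has no edges")
  part <- walktrap_modules(intersection, steps = steps)
  enr <- enrich_partition(part, sets, min_module_size = min_module_size)
  list(partition = part, enrichment = enr)
}
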