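#' Module partition object
#'
#' @param assignment named integer vector, gene -> module label.
#' @param net the network the partition lives on (used to compute Q).
#' @param method short tag recording how the partition was obtained.
#' @return object of class `module_partition` with fields `assignment`
#'   (labels are dense integers, numbered by decreasing module size, ties
#'   broken by smallest member ID), `q` (modularity) and `method`.
#' @export
module_partition <- function(assignment, net, method = "manual") {
  assignment <- relabel_dense(assignment)
  structure(list(assignment = assignment,
                 q = modularity_q(net, assignment),
                 method = method),
            class = "module_partition")
}

# dense integer labels ordered by decreasing module size, ties by smallest
# member gene ID
relabel_dense <- function(assignment) {
  members <- split(names(assignment), assignment)
  ord <- order(-lengths(members),
               vapply(members, function(g) min(g), character(1)))
  new_lab <- stats::setNames(seq_along(members), names(members)[ord])
  stats::setNames(as.integer(new_lab[as.character(assignment)]),
                  names(assignment))
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Module partition (", x$method, "): ", length(unique(x$assignment)),
      " modules over ", length(x$assignment), " genes, Q = ",
      round(x$q, 4), "\n", sep = "")
  invisible(x)
}

#' Random-walk (walktrap) module detection
#'
#' Agglomerative merging driven by t-step random-walk distances; the
#' dendrogram is cut at the level of maximum modularity. Vertices are taken
#' in canonical (lexicographic) order, making the result deterministic and
#' invariant to input node relabelling.
#'
#' @param net igraph network with >= 1 edge.
#' @param steps random-walk length t (default 4, the algorithm's usual
#'   setting).
#' @param weighted use |edge weight| to bias the walk; default `FALSE`
#'   (edges are presence/absence after pruning).
#' @return a [module_partition()].
#' @export
walktrap_modules <- function(net, steps = 4, weighted = FALSE) {
  if (igraph::ecount(net) == 0)
    stop("network has no edges; module detection is undefined - ",
         "check the pruning threshold")
  net <- canonical_order(net)
  w <- if (weighted) abs(igraph::E(net)$weight) else rep(1, igraph::ecount(net))
  wt <- igraph::cluster_walktrap(net, weights = w, steps = steps)
  assignment <- stats::setNames(igraph::membership(wt),
                                igraph::V(net)$name)
  module_partition(assignment, net, method = sprintf("walktrap_t%d", steps))
}

canonical_order <- function(net) {
  igraph::permute(net, match(igraph::V(net)$name,
                             sort(igraph::V(net)$name)))
}

#' Modularity Q of a partition
#'
#' \deqn{Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]} with \eqn{e_c} the
#' number of edges inside module c, \eqn{d_c} the total degree of its nodes
#' and m the number of edges: the fraction of edges falling within modules
#' minus the expectation under random edge placement. Unweighted by default;
#' the weighted variant replaces counts by |weight| sums.
#'
#' @param net igraph network.
#' @param assignment named module labels covering every network node (a
#'   `module_partition` is also accepted).
#' @param weighted logical.
#' @return Q in \[-1, 1\].
#' @export
modularity_q <- function(net, assignment, weighted = FALSE) {
  if (inherits(assignment, "module_partition"))
    assignment <- assignment$assignment
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(assignment))
  if (length(missing))
    stop("node(s) missing from partition: ",
         paste(utils::head(missing, 5), collapse = ", "))
  el <- igraph::as_edgelist(net)
  w <- if (weighted) abs(igraph::E(net)$weight) else rep(1, nrow(el))
  m <- sum(w)
  if (m == 0) return(0)
  mod_a <- assignment[el[, 1L]]
  mod_b <- assignment[el[, 2L]]
  e_c <- tapply(w[mod_a == mod_b], mod_a[mod_a == mod_b], sum)
  # (weighted) degree summed per module: each edge contributes its weight
  # to the module of both endpoints
  d_c <- tapply(c(w, w), c(mod_a, mod_b), sum)
  all_mods <- unique(assignment[nodes])
  d_c <- stats::setNames(ifelse(is.na(d_c[as.character(all_mods)]), 0,
                                d_c[as.character(all_mods)]),
                         all_mods)
  q_by_mod <- -(d_c / (2 * m))^2
  q_by_mod[names(e_c)] <- q_by_mod[names(e_c)] + e_c / m
  sum(q_by_mod)
}

#' Merge small detached components into single modules
#'
#' The raw walktrap partition can split a small connected component that is
#' completely detached from the rest of the network (e.g. an isolated gene
#' pair) into several modules. Within every detached component of at most
#' `max_detached_size` nodes, all genes are merged into one module; larger
#' components are untouched. Q is recomputed. Curation never removes genes
#' and never splits an existing module.
#'
#' @param partition a [module_partition()].
#' @param net the network the partition was detected on.
#' @param max_detached_size largest component size eligible for merging.
#' @return a curated [module_partition()].
#' @export
curate_modules <- function(partition, net, max_detached_size = 5) {
  stopifnot(inherits(partition, "module_partition"))
  assignment <- partition$assignment
  comp <- igraph::components(net)
  small <- which(comp$csize <= max_detached_size)
  if (comp$no > 1) {                # small components detached from a rest
    nxt <- max(assignment) + 1L
    for (cid in small) {
      genes <- igraph::V(net)$name[comp$membership == cid]
      assignment[genes] <- nxt
      nxt <- nxt + 1L
    }
  }
  module_partition(assignment, net,
                   method = paste0(partition$method, "+curated"))
}

#' Extract hub genes
#'
#' Hubs are genes connected to at least `min_degree` other genes in the same
#' network (default 5).
#'
#' @param net igraph network.
#' @param min_degree degree cutoff.
#' @return data.frame (gene, degree) sorted by decreasing degree, ties by
#'   gene ID.
#' @export
extract_hubs <- function(net, min_degree = 5) {
  deg <- igraph::degree(net)
  keep <- deg >= min_degree
  out <- data.frame(gene = names(deg)[keep], degree = unname(deg[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$gene), , drop = FALSE]
}

#' Census of connected components by size
#'
#' @param net igraph network.
#' @return data.frame (size, n_components, node_fraction); `node_fraction`
#'   is the share of all network nodes held by components of that size.
#' @export
component_census <- function(net) {
  if (igraph::vcount(net) == 0)
    return(data.frame(size = integer(), n_components = integer(),
                      node_fraction = numeric()))
  comp <- igraph::components(net)
  tab <- table(comp$csize)
  size <- as.integer(names(tab))
  data.frame(size = size, n_components = as.integer(tab),
             node_fraction = size * as.integer(tab) / igraph::vcount(net))
}
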