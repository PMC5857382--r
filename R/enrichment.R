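#' Gene set collection
#'
#' Named gene sets (regulons, GO classes, ...) over a stated gene universe.
#'
#' @param sets named list of character vectors; every set must lie within
#'   the universe and names must be unique.
#' @param universe character vector of all gene IDs under consideration;
#'   defaults to the union of the sets.
#' @param descriptions optional named character vector of set descriptions.
#' @return object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, descriptions = NULL) {
  if (!length(sets)) stop("empty gene-set collection")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == ""))
    stop("sets must have unique, non-empty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  outside <- setdiff(unlist(sets), universe)
  if (length(outside))
    stop("set member(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(universe = universe, sets = sets,
                 descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene set collection: ", length(x$sets), " sets over ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P(X \ge k)} for X hypergeometric: drawing a
#' module of size n from a universe of N genes of which K belong to the set,
#' and observing an overlap of k.
#'
#' @param k observed overlap.
#' @param n module (or gene-list) size.
#' @param K set size within the universe.
#' @param N universe size.
#' @return p-value in (0, 1\]. Vectorized over its arguments.
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  if (any(k < 0) || any(k > pmin(n, K)) || any(n > N) || any(K > N))
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: monotone, capped at 1, order-preserving with the
#' input indexing.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene-set enrichment of a module partition
#'
#' One hypergeometric test per (module of at least `min_module_size` genes)
#' x (set with members in the universe), BH-corrected across all tests
#' jointly. The universe defaults to the partitioned genes themselves (the
#' network's gene set) rather than the whole genome, so genes filtered out
#' during network reconstruction do not inflate significance; pass
#' `universe` explicitly for genome-wide testing.
#'
#' @param partition a [module_partition()], or a named vector of cluster
#'   labels.
#' @param sets a [gene_set_collection()].
#' @param min_module_size smallest module tested (default 5).
#' @param universe optional explicit gene universe.
#' @return data.frame (module, set, overlap, module_size, set_size,
#'   universe_size, p, fdr), sorted by fdr then p.
#' @export
enrich_partition <- function(partition, sets, min_module_size = 5,
                             universe = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"))
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (!length(assignment)) stop("empty partition")
  if (is.null(universe)) universe <- names(assignment)
  assignment <- assignment[names(assignment) %in% universe]
  N <- length(universe)
  modules <- split(names(assignment), assignment)
  modules <- modules[lengths(modules) >= min_module_size]
  set_in_univ <- lapply(sets$sets, intersect, universe)
  set_in_univ <- set_in_univ[lengths(set_in_univ) > 0]
  if (!length(modules) || !length(set_in_univ))
    return(data.frame(module = character(), set = character(),
                      overlap = integer(), module_size = integer(),
                      set_size = integer(), universe_size = integer(),
                      p = numeric(), fdr = numeric()))
  rows <- expand.grid(module = names(modules), set = names(set_in_univ),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$overlap <- mapply(function(m, s)
    length(intersect(modules[[m]], set_in_univ[[s]])),
    rows$module, rows$set)
  rows$module_size <- lengths(modules)[rows$module]
  rows$set_size <- lengths(set_in_univ)[rows$set]
  rows$universe_size <- N
  rows$p <- hypergeom_pvalue(rows$overlap, rows$module_size,
                             rows$set_size, N)
  rows$fdr <- bh_adjust(rows$p)
  rows <- rows[order(rows$fdr, rows$p, rows$module, rows$set), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' k-means clustering of gene expression profiles
#'
#' Rows are standardized first so that clusters reflect profile shape, not
#' absolute expression level. Best of `n_init` random starts by total
#' within-cluster sum of squares; reproducible for a fixed seed.
#'
#' @param expr expression matrix.
#' @param k number of clusters (1 <= k <= number of genes).
#' @param seed integer seed.
#' @param n_init number of random starts (default 10).
#' @return list of class `kmeans_clustering`: `assignment` (named integer
#'   vector), `tot_withinss`, `k`.
#' @export
kmeans_clusters <- function(expr, k, seed = 1L, n_init = 10) {
  if (k < 1) stop("k must be >= 1")
  x <- standardize(expr)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  km <- withr::with_seed(seed,
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100))
  structure(list(assignment = stats::setNames(km$cluster, rownames(x)),
                 tot_withinss = km$tot.withinss, k = k),
            class = "kmeans_clustering")
}

#' Mean silhouette scan over a k grid
#'
#' A simple substitute for external tools' cluster-number choice: runs
#' [kmeans_clusters()] for each candidate k and reports the mean silhouette
#' width (Euclidean distance on standardized profiles).
#'
#' @param expr expression matrix.
#' @param ks integer vector of candidate k (>= 2).
#' @param seed integer seed.
#' @return data.frame (k, mean_silhouette); attribute `best` = argmax k.
#' @export
silhouette_scan <- function(expr, ks = 2:10, seed = 1L) {
  stopifnot(all(ks >= 2))
  x <- standardize(expr)
  d <- as.matrix(stats::dist(x))
  msil <- vapply(ks, function(k) {
    cl <- kmeans_clusters(x, k, seed = seed)$assignment
    sil <- vapply(seq_len(nrow(x)), function(i) {
      own <- cl[i]
      a <- mean(d[i, cl == own & seq_len(nrow(x)) != i])
      if (is.nan(a)) return(0)                  # singleton cluster
      b <- min(vapply(setdiff(unique(cl), own), function(g)
        mean(d[i, cl == g]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
  }, numeric(1))
  out <- data.frame(k = ks, mean_silhouette = msil)
  attr(out, "best") <- ks[which.max(msil)]
  out
}

#' Concordance between a module partition and a clustering
#'
#' Adjusted Rand index plus the full module x cluster contingency table,
#' over the genes present in both labelings (genes missing from either side
#' are excluded and counted in the output).
#'
#' @param partition a [module_partition()] or named label vector.
#' @param clustering a `kmeans_clustering` or named label vector.
#' @return list: `ari`, `table` (contingency), `n_shared`, `n_only_partition`,
#'   `n_only_clustering`.
#' @export
concordance <- function(partition, clustering) {
  a <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  b <- if (inherits(clustering, "kmeans_clustering"))
    clustering$assignment else clustering
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("the two labelings share no genes")
  list(ari = mclust::adjustedRandIndex(a[shared], b[shared]),
       table = table(module = a[shared], cluster = b[shared]),
       n_shared = length(shared),
       n_only_partition = length(setdiff(names(a), shared)),
       n_only_clustering = length(setdiff(names(b), shared)))
}
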