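#' Write / read an expression matrix as TSV
#'
#' Rows = genes, columns = samples; header row of sample IDs, first column
#' `gene_id`.
#'
#' @param expr expression matrix.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param log_transformed flag recorded on the returned matrix.
#' @export
read_expression_tsv <- function(path, log_transformed = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, log_transformed = log_transformed)
}

#' Read a phase design TSV
#'
#' Expects columns `sample_id`, `phase` and optionally `replicate`.
#'
#' @param path file path.
#' @param phase_levels optional ordered phase labels.
#' @return a [phase_design()] data.frame.
#' @export
read_design_tsv <- function(path, phase_levels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(phase_levels)) phase_levels <- unique(df$phase)
  phase_design(df$sample_id, df$phase,
               replicate = df$replicate, phase_levels = phase_levels)
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, tab-separated gene IDs.
#'
#' @param sets a [gene_set_collection()].
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm)
    paste(c(nm, sets$descriptions[[nm]], sets$sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @param universe optional explicit universe for the returned collection
#'   (defaults to the union of the sets).
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  # recover descriptions (gmtPathways drops them)
  desc <- vapply(strsplit(readLines(path), "\t"), function(f)
    if (length(f) >= 2) f[2] else "", character(1))
  names(desc) <- names(sets)
  gene_set_collection(sets, universe = universe, descriptions = desc)
}

#' Write a network as a weighted edge-list TSV
#'
#' Three columns `gene_a`, `gene_b`, `weight` with `gene_a < gene_b`
#' lexicographically.
#'
#' @param net igraph network.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  w <- if (igraph::ecount(net) && "weight" %in% igraph::edge_attr_names(net))
    igraph::E(net)$weight else rep(1, nrow(el))
  swap <- nrow(el) > 0 & el[, 1] > el[, 2]
  df <- data.frame(gene_a = ifelse(swap, el[, 2], el[, 1]),
                   gene_b = ifelse(swap, el[, 1], el[, 2]),
                   weight = w, stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- sort(unique(c(df$gene_a, df$gene_b)))
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Write a partial-correlation matrix as TSV
#'
#' Square matrix with a leading `gene_id` column.
#'
#' @param pcm a `pcor_matrix` (or plain matrix).
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_pcor_tsv <- function(pcm, path) {
  rho <- if (inherits(pcm, "pcor_matrix")) pcm$rho_hat else pcm
  df <- data.frame(gene_id = rownames(rho), rho, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML (weight attribute included)
#'
#' @param net igraph network.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a module partition as a two-column TSV
#'
#' @param partition a [module_partition()] or named label vector.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
write_partition_tsv <- function(partition, path) {
  a <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  utils::write.table(data.frame(gene_id = names(a), module_id = unname(a)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Flat key-value text file: configuration snapshot, package version, seed,
#' and an md5 hash per written output file. Re-running with an identical
#' manifest reproduces byte-identical stage outputs.
#'
#' @param path manifest path.
#' @param config named list of configuration values.
#' @param files character vector of output file paths to hash.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(path, config, files = character()) {
  flat <- unlist(lapply(config, function(v) paste(v, collapse = ",")))
  lines <- c(paste0("package_version\t", as.character(utils::packageVersion("sporegcn"))),
             paste0(names(flat), "\t", flat))
  files <- files[file.exists(files)]
  if (length(files)) {
    h <- tools::md5sum(files)
    lines <- c(lines, paste0("md5\t", basename(files), "\t", h))
  }
  writeLines(lines, path)
  invisible(path)
}
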