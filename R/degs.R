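#' Call differentially expressed genes per phase contrast
#'
#' Each post-reference phase is contrasted against the reference (P1 by
#' default; P0, the state prior to the onset of sporulation, is carried in
#' the design but never contrasted). Per gene and contrast,
#' \code{log2FC = log2((mean target + pseudocount) / (mean reference +
#' pseudocount))} on the expression scale. With >= 2 replicates on both
#' sides a Welch two-sample t-test on `log2(value + pseudocount)` yields a
#' p-value, BH-adjusted within contrast; a gene is called `up`/`down` when
#' both `|log2FC| >= lfc_threshold` and adjusted p < `alpha`. With a single
#' replicate on either side (e.g. replicate-averaged input) only the
#' fold-change criterion applies and p is set to 1 with a message.
#'
#' @param expr expression matrix on the non-negative (RPKM-like) scale.
#' @param design phase design ([phase_design()]).
#' @param lfc_threshold minimum |log2 fold change| (default 1).
#' @param alpha FDR level (default 0.05).
#' @param pseudocount positive offset guarding zero expression (default 1).
#' @param reference reference phase (default `"P1"`).
#' @param exclude_phases phases never contrasted (default `"P0"`).
#' @return data.frame of class `deg_table`: columns `contrast` (e.g.
#'   `"P2_vs_P1"`, ordered factor), `gene`, `log2fc`, `p`, `fdr`, `call`
#'   (`up`, `down`, `ns`).
#' @export
call_degs <- function(expr, design, lfc_threshold = 1, alpha = 0.05,
                      pseudocount = 1, reference = "P1",
                      exclude_phases = "P0") {
  stopifnot(lfc_threshold >= 0, alpha > 0, alpha <= 1, pseudocount > 0)
  check_design(expr, design, reference)
  phases <- levels(design$phase)
  phases <- phases[phases %in% design$phase]
  targets <- setdiff(phases, c(reference, exclude_phases))
  ref_samples <- design$sample_id[design$phase == reference]
  logx <- log2(expr + pseudocount)

  one_contrast <- function(ph) {
    tgt_samples <- design$sample_id[design$phase == ph]
    mt <- rowMeans(expr[, tgt_samples, drop = FALSE])
    mr <- rowMeans(expr[, ref_samples, drop = FALSE])
    lfc <- log2((mt + pseudocount) / (mr + pseudocount))
    if (length(tgt_samples) >= 2 && length(ref_samples) >= 2 &&
        !identical(sort(tgt_samples), sort(ref_samples))) {
      p <- vapply(rownames(expr), function(g)
        welch_p(logx[g, tgt_samples], logx[g, ref_samples]), numeric(1))
    } else {
      if (identical(sort(tgt_samples), sort(ref_samples))) {
        p <- rep(1, nrow(expr))     # self-contrast: no evidence by design
      } else {
        message("contrast ", ph, " vs ", reference,
                ": <2 replicates, fold-change-only mode (p set to 1)")
        p <- rep(NA_real_, nrow(expr))
      }
    }
    fdr <- if (all(is.na(p))) rep(NA_real_, length(p)) else bh_adjust(p)
    pass_p <- if (all(is.na(p))) TRUE else fdr < alpha
    call <- ifelse(abs(lfc) >= lfc_threshold & pass_p,
                   ifelse(lfc > 0, "up", "down"), "ns")
    # self-contrast or identical samples: lfc is 0, call stays ns
    data.frame(contrast = paste0(ph, "_vs_", reference),
               gene = rownames(expr), log2fc = lfc,
               p = ifelse(is.na(p), 1, p),
               fdr = ifelse(is.na(fdr), 1, fdr),
               call = call, row.names = NULL, stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(targets, one_contrast))
  out$contrast <- factor(out$contrast,
                         levels = paste0(targets, "_vs_", reference),
                         ordered = TRUE)
  class(out) <- c("deg_table", class(out))
  out
}

# Welch t-test p-value that tolerates (near-)constant groups: zero variance
# on both sides gives p = 1 when the means agree and p ~ 0 otherwise.
welch_p <- function(x, y) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12)
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else .Machine$double.xmin)
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
}

#' Up/down DEG counts per contrast
#'
#' @param degs a `deg_table`.
#' @return data.frame (contrast, up, down, total) in contrast order.
#' @export
updown_counts <- function(degs) {
  if (!nrow(degs))
    return(data.frame(contrast = character(), up = integer(),
                      down = integer(), total = integer()))
  cts <- lapply(split(degs, degs$contrast, drop = FALSE), function(d)
    c(up = sum(d$call == "up"), down = sum(d$call == "down")))
  out <- data.frame(contrast = names(cts),
                    up = vapply(cts, `[[`, integer(1), "up"),
                    down = vapply(cts, `[[`, integer(1), "down"),
                    row.names = NULL)
  out$total <- out$up + out$down
  out
}

#' DEG sets per contrast
#'
#' @param degs a `deg_table`.
#' @param direction `"any"`, `"up"` or `"down"`.
#' @return named list of gene-ID character vectors, one per contrast.
#' @export
deg_sets <- function(degs, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  keep <- if (direction == "any") degs$call != "ns" else degs$call == direction
  sets <- split(degs$gene[keep],
                factor(degs$contrast[keep], levels = levels(degs$contrast)))
  lapply(sets, as.character)
}

#' Venn partition of DEG sets
#'
#' Counts every non-empty membership pattern across up to 6 gene sets; each
#' gene of the union falls in exactly one sector, so the sector counts sum
#' to the union size.
#'
#' @param sets named list of 1..6 gene sets.
#' @return data.frame (`pattern`, one logical column per set, `count`);
#'   `pattern` is the membership bit string in set order, e.g. `"01101"`.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 1 || k > 6)
    stop("venn_partition supports 1 to 6 sets (got ", k,
         "); larger patterns are unreadable")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  genes <- unique(unlist(sets))
  if (!length(genes)) {
    out <- data.frame(pattern = character(), stringsAsFactors = FALSE)
    for (nm in names(sets)) out[[nm]] <- logical()
    out$count <- integer()
    return(out)
  }
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, ncol = k, dimnames = list(genes, names(sets)))
  pattern <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), stringsAsFactors = FALSE)
  for (j in seq_len(k))
    out[[names(sets)[j]]] <- substr(out$pattern, j, j) == "1"
  out$count <- as.integer(tab)
  out[order(out$pattern, decreasing = TRUE), , drop = FALSE]
}

#' Rank genes by their minimum phase-mean expression
#'
#' Each gene is scored by the minimum, over phases, of its mean expression
#' in that phase; a high score means the gene is highly expressed at every
#' time instant. The top `fraction` of genes (ceiling) is returned in
#' decreasing score order.
#'
#' @param expr expression matrix (non-negative scale).
#' @param design phase design.
#' @param fraction fraction of genes to keep, in (0, 1\] (default 0.10).
#' @return data.frame (gene, score) of the top genes.
#' @export
rank_top_expressed <- function(expr, design, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  phases <- unique(as.character(design$phase))
  phase_means <- vapply(phases, function(ph)
    rowMeans(expr[, design$sample_id[design$phase == ph], drop = FALSE]),
    numeric(nrow(expr)))
  score <- apply(phase_means, 1, min)
  n_top <- ceiling(fraction * nrow(expr))
  ord <- order(-score, rownames(expr))[seq_len(n_top)]
  data.frame(gene = rownames(expr)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

#' Overlay DEG status on network nodes
#'
#' Classifies every network node from its calls across the time contrasts:
#' `up_all` (called in at least one contrast and only ever up), `down_all`
#' (symmetric), `mixed` (up in some contrast and down in another), `ns`
#' (in the table, never called), `not_in_table`.
#'
#' @param net igraph network.
#' @param degs a `deg_table`.
#' @return named character vector, node -> category.
#' @export
overlay_on_network <- function(net, degs) {
  nodes <- igraph::V(net)$name
  up <- tapply(degs$call == "up", degs$gene, any)
  down <- tapply(degs$call == "down", degs$gene, any)
  status <- vapply(nodes, function(g) {
    if (!g %in% names(up)) return("not_in_table")
    u <- isTRUE(up[[g]]); d <- isTRUE(down[[g]])
    if (u && d) "mixed" else if (u) "up_all" else if (d) "down_all" else "ns"
  }, character(1))
  stats::setNames(status, nodes)
}
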