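#' Partial correlations from a covariance matrix
#'
#' Applies the precision-matrix identity
#' \eqn{\rho^{ij} = -\omega_{ij} / \sqrt{\omega_{ii}\omega_{jj}}} to the
#' inverse of `sigma`. Used by the exact estimator and as the analytic
#' reference for the sparse one.
#'
#' @param sigma symmetric positive-definite covariance matrix.
#' @return symmetric matrix of partial correlations, zero diagonal.
#' @export
pcor_from_cov <- function(sigma) {
  omega <- tryCatch(solve(sigma), error = function(e)
    stop("covariance matrix is singular (rank-deficient); ",
         "use shrinkage > 0: ", conditionMessage(e)))
  rho <- -omega / sqrt(diag(omega) %o% diag(omega))
  diag(rho) <- 0
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- dimnames(sigma)
  rho
}

new_pcor_matrix <- function(rho, method) {
  structure(list(gene_ids = rownames(rho), rho_hat = rho, method = method),
            class = "pcor_matrix")
}

#' @export
print.pcor_matrix <- function(x, ...) {
  cat("Partial-correlation matrix (", x$method, "): ",
      length(x$gene_ids), " genes, ",
      sum(abs(x$rho_hat[upper.tri(x$rho_hat)]) > 0), " nonzero pairs\n",
      sep = "")
  invisible(x)
}

#' Exact partial correlations by covariance inversion
#'
#' Estimates all pairwise partial correlations by inverting the (optionally
#' ridge-regularized) sample covariance. Suitable when samples comfortably
#' outnumber genes; the default shrinkage `1e-3 * trace(S)/p` keeps the
#' estimator usable when they do not.
#'
#' @param expr expression matrix (rows standardized or not; the covariance
#'   is taken across samples).
#' @param shrinkage ridge added to the covariance diagonal (>= 0). `NULL`
#'   (default) means 0 when `n > p`, else `1e-3 * trace(S)/p`.
#' @return a `pcor_matrix` (fields `gene_ids`, `rho_hat`, `method`).
#' @export
partial_correlations_exact <- function(expr, shrinkage = NULL) {
  if (ncol(expr) < 2) stop("need at least 2 samples")
  S <- stats::cov(t(expr))
  p <- nrow(S)
  if (is.null(shrinkage))
    shrinkage <- if (ncol(expr) > p) 0 else 1e-3 * sum(diag(S)) / p
  stopifnot(shrinkage >= 0)
  if (shrinkage > 0) S <- S + diag(shrinkage, p)
  new_pcor_matrix(pcor_from_cov(S), "exact")
}

#' Sparse partial correlations by joint regression (SPACE)
#'
#' Estimates all partial correlations simultaneously by solving the
#' symmetric joint-regression problem
#' \deqn{\min_{\rho} \tfrac12 \sum_i w_i \| x_i - \sum_{j \ne i} \beta_{ij} x_j \|^2
#'       + \lambda \sum_{i<j} | \rho^{ij} |,}
#' where \eqn{\beta_{ij} = \rho^{ij}\sqrt{\sigma^{jj}/\sigma^{ii}}} ties the
#' two regressions of each gene pair to one symmetric parameter
#' (\eqn{\sigma^{ii}} = precision diagonal, re-estimated from the residual
#' variances between sweeps). The lasso part is solved by coordinate descent
#' with an active-set ("active shooting") schedule: a full sweep over all
#' pairs, then repeated sweeps over the currently nonzero pairs until they
#' stabilise, repeated until a full sweep changes nothing.
#'
#' Gene rows are standardized internally. With `lambda = 0` and n >> p the
#' solution coincides with [partial_correlations_exact()].
#'
#' @param expr expression matrix.
#' @param lambda non-negative l1 penalty.
#' @param weights per-gene regression weights (default uniform). The
#'   original method also supports degree-based reweighting; pass the
#'   desired weights explicitly for that.
#' @param max_iter maximum outer sweeps per sigma update.
#' @param tol convergence tolerance on the largest single-parameter change.
#' @param n_sigma_updates alternations between solving for rho and
#'   re-estimating the precision diagonal from residuals.
#' @param init optional p x p warm-start matrix of partial correlations.
#' @param support optional logical p x p matrix; when given, only the marked
#'   pairs are updated (all others stay zero). Used with `lambda = 0` for
#'   the relaxed refit that removes the soft-threshold shrinkage bias from a
#'   selected support.
#' @return a `pcor_matrix` with `method = "space"`; attribute `bic` carries
#'   the residual-sum-of-squares BIC used for penalty selection.
#' @export
space_fit <- function(expr, lambda, weights = NULL, max_iter = 500,
                      tol = 1e-6, n_sigma_updates = 3, init = NULL,
                      support = NULL) {
  stopifnot(lambda >= 0, tol > 0, max_iter >= 1)
  x <- standardize(expr)
  p <- nrow(x)
  n <- ncol(x)
  if (p < 2) stop("need at least 2 genes")
  ids <- rownames(x)
  w <- if (is.null(weights)) rep(1, p) else rep_len(weights, p)

  G <- tcrossprod(x)                  # p x p Gram matrix of gene rows
  support_only <- !is.null(support)
  rho <- if (support_only) {
    stopifnot(dim(support) == c(p, p))
    # seed the support pairs so the restricted solver sees them
    r0 <- if (is.null(init)) (support * 1e-12) else unname(init) * support
    r0[!support] <- 0
    r0[r0 == 0 & support] <- 1e-12
    unname(r0)
  } else if (is.null(init)) matrix(0, p, p) else unname(init)
  sii <- rep(1, p)                    # precision diagonal estimate

  for (s in seq_len(n_sigma_updates)) {
    sol <- .space_cd(G, sii, w, lambda, rho, tol, max_iter, support_only)
    rho <- sol$rho
    rss <- sol$rss
    # update precision diagonal from residual variances
    sii_new <- n / pmax(rss, .Machine$double.eps)
    if (max(abs(sii_new - sii)) < tol) { sii <- sii_new; break }
    sii <- sii_new
  }

  df <- colSums(rho != 0)
  bic <- sum(n * log(pmax(rss, .Machine$double.eps) / n) + log(n) * df)

  dimnames(rho) <- list(ids, ids)
  out <- new_pcor_matrix(rho, "space")
  attr(out, "bic") <- bic
  attr(out, "lambda") <- lambda
  out
}

#' SPACE over a penalty grid, selected by BIC
#'
#' The pruning threshold is the sparsity control this analysis exposes for
#' reconstructed networks; the penalty itself is a nuisance parameter, chosen
#' here as the BIC minimiser over a log-spaced grid (warm starts from large
#' to small penalties).
#'
#' @param expr expression matrix.
#' @param lambda_grid penalties to scan; default 8 log-spaced values between
#'   `0.01` and `1` times `lambda_max` (the smallest penalty that zeroes
#'   every pair).
#' @param refit relaxed refit: re-estimate the partial correlations at
#'   `lambda = 0` restricted to the selected support (default `TRUE`). The
#'   l1 soft threshold shrinks every retained coefficient by about
#'   `lambda`; the refit removes that bias so a fixed pruning threshold on
#'   |rho| acts on unshrunk partial-correlation magnitudes.
#' @param scan_tol convergence tolerance used while scanning the grid (the
#'   scan only has to rank penalties and fix the support; the final
#'   estimate is re-solved at `tol`).
#' @param tol convergence tolerance of the returned estimate.
#' @param ... passed to [space_fit()].
#' @return the selected `pcor_matrix`; attribute `path` is a data.frame of
#'   (lambda, bic, n_nonzero) over the grid, attribute `lambda` the selected
#'   penalty.
#' @export
space_fit_bic <- function(expr, lambda_grid = NULL, refit = TRUE,
                          scan_tol = 1e-4, tol = 1e-6, ...) {
  x <- standardize(expr)
  if (is.null(lambda_grid)) {
    G <- tcrossprod(x)
    lmax <- 2 * max(abs(G[upper.tri(G)]))
    lambda_grid <- exp(seq(log(0.01 * lmax), log(lmax), length.out = 8))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fits <- vector("list", length(lambda_grid))
  init <- NULL
  n_worse <- 0
  best_bic <- Inf
  for (k in seq_along(lambda_grid)) {
    fits[[k]] <- space_fit(x, lambda_grid[k], init = init, tol = scan_tol, ...)
    init <- fits[[k]]$rho_hat
    bic_k <- attr(fits[[k]], "bic")
    if (bic_k < best_bic) {
      best_bic <- bic_k
      n_worse <- 0
    } else {
      n_worse <- n_worse + 1
      # BIC is past its minimum; denser fits only get slower and worse
      if (n_worse >= 2) break
    }
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  lambda_grid <- lambda_grid[seq_along(fits)]
  path <- data.frame(lambda = lambda_grid,
                     bic = vapply(fits, attr, numeric(1), which = "bic"),
                     n_nonzero = vapply(fits, function(f)
                       sum(f$rho_hat[upper.tri(f$rho_hat)] != 0), integer(1)))
  k_best <- which.min(path$bic)
  best <- fits[[k_best]]
  if (refit) {
    sel <- best$rho_hat != 0
    if (any(sel)) {
      refitted <- space_fit(x, lambda = 0, support = sel,
                            init = best$rho_hat, tol = tol, ...)
      attr(refitted, "lambda") <- attr(best, "lambda")
      attr(refitted, "bic") <- attr(best, "bic")
      best <- refitted
    }
  }
  attr(best, "path") <- path
  best
}

#' Marginal (guilt-by-association) correlation network
#'
#' Pearson or Spearman correlation between gene profiles, thresholded on
#' absolute value. Kept as the simple baseline next to the
#' partial-correlation estimators.
#'
#' @param expr expression matrix (>= 3 samples).
#' @param method `"pearson"` or `"spearman"`.
#' @param threshold absolute-correlation cutoff in (0, 1); edges with
#'   `|r| >= threshold` are kept, weight = signed correlation.
#' @return an igraph network (see [prune_to_network()] for conventions).
#' @export
marginal_correlation_network <- function(expr, method = c("pearson", "spearman"),
                                         threshold = 0.35) {
  method <- match.arg(method)
  if (ncol(expr) < 3) stop("need at least 3 samples")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  r <- stats::cor(t(expr), method = method)
  diag(r) <- 0
  build_network(r, threshold, method = paste0("marginal_", method))
}

#' Prune a partial-correlation matrix to a network
#'
#' Keeps edge (i, j) iff \eqn{|\hat\rho^{ij}| \ge} `rho_threshold` (ties at
#' the threshold are kept). Genes left with no edge are excluded from the
#' node set, mirroring how genes with no surviving association are filtered
#' out of the reconstructed network.
#'
#' @param pcm a `pcor_matrix` (or plain symmetric matrix).
#' @param rho_threshold cutoff in (0, 1); default convention is 0.35.
#' @return an igraph network: vertices named by gene ID (lexicographic
#'   order), edge attribute `weight` = signed retained value, graph
#'   attributes `method` and `threshold`.
#' @export
prune_to_network <- function(pcm, rho_threshold = 0.35) {
  if (rho_threshold <= 0 || rho_threshold >= 1)
    stop("rho_threshold must lie in (0, 1)")
  rho <- if (inherits(pcm, "pcor_matrix")) pcm$rho_hat else pcm
  method <- if (inherits(pcm, "pcor_matrix")) pcm$method else "matrix"
  build_network(rho, rho_threshold, method = method)
}

build_network <- function(assoc, threshold, method) {
  stopifnot(isSymmetric(unname(assoc), tol = 1e-8))
  ids <- rownames(assoc)
  keep <- which(upper.tri(assoc) & abs(assoc) >= threshold, arr.ind = TRUE)
  a <- ids[keep[, 1L]]; b <- ids[keep[, 2L]]
  swap <- a > b
  edges <- data.frame(gene_a = ifelse(swap, b, a),
                      gene_b = ifelse(swap, a, b),
                      weight = assoc[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::set_graph_attr(g, "method", method)
  igraph::set_graph_attr(g, "threshold", threshold)
}
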