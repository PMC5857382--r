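#' Degree distribution of a network
#'
#' @param net igraph network with >= 1 node.
#' @return object of class `degree_distribution`: list with `degrees`
#'   (named per-node counts \eqn{\eta_i}) and `pmf` (data.frame
#'   `degree`, `p` with \eqn{P(\eta)} = proportion of nodes with that
#'   degree; sums to 1).
#' @export
degree_distribution <- function(net) {
  if (igraph::vcount(net) == 0) stop("network has no nodes")
  deg <- igraph::degree(net)
  tab <- table(deg)
  structure(list(degrees = deg,
                 pmf = data.frame(degree = as.integer(names(tab)),
                                  p = as.vector(tab) / length(deg))),
            class = "degree_distribution")
}

#' Fit a truncated power law to a degree distribution
#'
#' Fits \deqn{P(\eta) = \beta \eta^{-\gamma} e^{-\alpha\eta}} by least
#' squares on the log scale,
#' \eqn{\log P = \log\beta - \gamma\log\eta - \alpha\eta}, over the observed
#' degrees with positive probability mass (matching the log-log presentation
#' of degree distributions). The exponential cutoff captures the sharp
#' drop-off among high-degree nodes; \eqn{\alpha} is constrained to be
#' non-negative (a negative unconstrained estimate is refit with
#' \eqn{\alpha = 0}, i.e. a pure power law).
#'
#' @param dd a [degree_distribution()].
#' @param min_degree smallest degree included in the fit.
#' @param method `"ls"` (default; least squares on the log pmf) or `"ml"`
#'   (discrete maximum likelihood over the observed support, requiring the
#'   raw per-node degrees).
#' @return list of class `power_law_fit`: `beta`, `gamma`, `alpha`, `rss`
#'   (residual sum of squares on log scale), `degrees_used`, `fitted_pmf`.
#' @export
fit_truncated_power_law <- function(dd, min_degree = 1,
                                    method = c("ls", "ml")) {
  stopifnot(inherits(dd, "degree_distribution"))
  method <- match.arg(method)
  pmf <- dd$pmf[dd$pmf$degree >= min_degree & dd$pmf$p > 0, , drop = FALSE]
  if (nrow(pmf) < 3)
    stop("need at least 3 distinct degrees with positive mass (got ",
         nrow(pmf), ")")
  if (method == "ml") {
    if (is.null(dd$degrees)) stop("ML fitting needs the raw degrees")
    deg <- dd$degrees[dd$degrees >= min_degree]
    support <- seq(min_degree, max(deg))
    nll <- function(par) {
      g <- par[1]; a <- par[2]
      lw <- -g * log(support) - a * support
      lz <- log(sum(exp(lw - max(lw)))) + max(lw)
      -sum(-par[1] * log(deg) - par[2] * deg - lz)
    }
    opt <- stats::optim(c(1.5, 0.01), nll, method = "L-BFGS-B",
                        lower = c(-5, 0), upper = c(10, 2))
    gamma <- opt$par[1]; alpha <- opt$par[2]
    lw <- -gamma * log(support) - alpha * support
    beta <- 1 / sum(exp(lw))
    return(structure(list(beta = beta, gamma = gamma, alpha = alpha,
                          rss = NA_real_, degrees_used = sort(unique(deg)),
                          fitted_pmf = beta * pmf$degree^(-gamma) *
                            exp(-alpha * pmf$degree)),
                     class = "power_law_fit"))
  }
  y <- log(pmf$p)
  fit <- stats::lm(y ~ log(pmf$degree) + pmf$degree)
  alpha <- -unname(stats::coef(fit)[3])
  if (alpha < 0) {                     # boundary: refit as pure power law
    fit <- stats::lm(y ~ log(pmf$degree))
    alpha <- 0
    gamma <- -unname(stats::coef(fit)[2])
  } else {
    gamma <- -unname(stats::coef(fit)[2])
  }
  beta <- exp(unname(stats::coef(fit)[1]))
  structure(list(beta = beta, gamma = gamma, alpha = alpha,
                 rss = sum(stats::residuals(fit)^2),
                 degrees_used = pmf$degree,
                 fitted_pmf = beta * pmf$degree^(-gamma) *
                   exp(-alpha * pmf$degree)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Truncated power law P(eta) = %.4g * eta^-%.3f * exp(-%.4f eta)  [rss %.3g over %d degrees]\n",
    x$beta, x$gamma, x$alpha, x$rss, length(x$degrees_used)))
  invisible(x)
}

#' Sample degrees from a truncated power law
#'
#' Utility for parameter-recovery checks: draws from
#' \eqn{P(\eta) \propto \eta^{-\gamma} e^{-\alpha\eta}} on integer support.
#'
#' @param n number of draws.
#' @param gamma power-law exponent.
#' @param alpha exponential cutoff rate (>= 0).
#' @param support integer degrees to draw from.
#' @param seed integer seed.
#' @return integer vector of degrees.
#' @export
sample_truncated_power_law <- function(n, gamma, alpha, support = 1:100,
                                       seed = 1L) {
  w <- support^(-gamma) * exp(-alpha * support)
  withr::with_seed(seed,
    sample(support, n, replace = TRUE, prob = w / sum(w)))
}

#' Local clustering coefficients
#'
#' Fraction of each node's neighbour pairs that are themselves connected
#' (triangles over wedges). Nodes of degree < 2 have no wedges; by
#' convention they are assigned 0 (the mean is also reported over nodes of
#' degree >= 2 only).
#'
#' @param net igraph network.
#' @return list with `local` (named per-node coefficients), `mean_all`
#'   (mean with the degree<2 zeros included) and `mean_deg2plus` (mean over
#'   nodes with degree >= 2; `NaN` when none exist).
#' @export
clustering_coefficients <- function(net) {
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  names(cc) <- igraph::V(net)$name
  deg <- igraph::degree(net)
  list(local = cc,
       mean_all = mean(cc),
       mean_deg2plus = mean(cc[deg >= 2]))
}

#' Random network baseline
#'
#' Uniform random simple graph with exactly the requested numbers of nodes
#' and edges (Erdos-Renyi G(n, m)), used as the null against which the
#' degree distribution and modularity of an inferred network are compared.
#'
#' @param n_nodes,n_edges size of the graph; `n_edges` must not exceed
#'   `n_nodes * (n_nodes - 1) / 2`.
#' @param seed integer seed; the same seed yields the identical graph.
#' @return igraph network with vertices named `r0001`, ...
#' @export
random_baseline <- function(n_nodes, n_edges, seed) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("n_edges exceeds the maximum for a simple graph on ", n_nodes,
         " nodes")
  g <- withr::with_seed(seed, igraph::sample_gnm(n_nodes, n_edges))
  igraph::V(g)$name <- sprintf("r%04d", seq_len(n_nodes))
  igraph::E(g)$weight <- 1
  g
}
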