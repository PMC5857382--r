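test_that("standardization centres, scales, drops constant genes", {
  x <- expr_of(rbind(rnorm(10, 5, 2), rnorm(10, -1, 0.5), rep(3, 10)))
  expect_warning(s <- standardize(x), "zero-variance")
  expect_equal(nrow(s), 2L)
  expect_true(all(abs(rowMeans(s)) < 1e-12))
  expect_true(all(abs(apply(s, 1, var) - 1) < 1e-12))
  expect_equal(unname(standardize(s)), unname(s), tolerance = 1e-12)
  expect_error(standardize(x[, 1, drop = FALSE]), "2 samples")
})

test_that("exact partial correlations recover the generating precision", {
  om <- matrix(c(1, 0.4, 0, 0.4, 1, 0.4, 0, 0.4, 1), 3, 3,
               dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  x <- sample_expression(om, 1e5, seed = 17)
  pc <- partial_correlations_exact(x)
  # pcor formula applied to the generating precision: -0.4 off the diagonal
  expect_equal(pc$rho_hat["g1", "g2"], -0.4, tolerance = 0.02)
  expect_equal(pc$rho_hat["g1", "g3"], 0, tolerance = 0.02)
  expect_true(isSymmetric(pc$rho_hat))
  expect_true(all(diag(pc$rho_hat) == 0))
})

test_that("two-gene partial correlation equals the Pearson correlation", {
  x <- expr_of(matrix(rnorm(40), 2, 20))
  pc <- partial_correlations_exact(x, shrinkage = 0)
  expect_equal(pc$rho_hat[1, 2], cor(x[1, ], x[2, ]), tolerance = 1e-10)
})

test_that("independent genes give near-zero partial correlations", {
  set.seed(31)
  x <- expr_of(matrix(rnorm(8 * 10000), 8, 10000))
  pc <- partial_correlations_exact(x, shrinkage = 0)
  expect_true(max(abs(pc$rho_hat)) < 0.05)
})

test_that("singular covariance without shrinkage is an error", {
  set.seed(1)
  x <- expr_of(matrix(rnorm(50), 10, 5))   # p > n: rank deficient
  expect_error(partial_correlations_exact(x, shrinkage = 0),
               "singular|rank")
  expect_s3_class(partial_correlations_exact(x), "pcor_matrix")  # default ridge
})

test_that("full shrinkage zeroes every SPACE coefficient", {
  set.seed(5)
  x <- expr_of(matrix(rnorm(20 * 50), 20, 50))
  G <- tcrossprod(standardize(x))
  lam <- 10 * max(abs(G[upper.tri(G)]))
  fit <- space_fit(x, lambda = lam)
  expect_true(all(fit$rho_hat == 0))
})

test_that("SPACE at lambda 0 matches the exact estimator", {
  cfg <- synthetic_config(n_genes = 10, module_sizes = c(3, 3),
                          within_pcor = 0.4, deg_fraction_per_phase = 0)
  x <- sample_expression(make_block_precision(cfg), 5000, seed = 23)
  fit <- space_fit(x, lambda = 0, tol = 1e-8)
  exact <- partial_correlations_exact(standardize(x), shrinkage = 0)
  expect_lt(max(abs(fit$rho_hat - exact$rho_hat)), 1e-4)
  expect_identical(max(abs(fit$rho_hat - t(fit$rho_hat))), 0)  # exact symmetry
})

test_that("SPACE recovers a planted sparse support", {
  cfg <- synthetic_config(n_genes = 30, module_sizes = rep(3L, 8),
                          within_pcor = 0.4, deg_fraction_per_phase = 0)
  om <- make_block_precision(cfg)
  x <- sample_expression(om, 200, seed = 29)
  truth <- abs(om) > 0 & upper.tri(om)
  G <- tcrossprod(standardize(x))
  lmax <- 2 * max(abs(G[upper.tri(G)]))
  grid <- exp(seq(log(0.02 * lmax), log(0.5 * lmax), length.out = 5))
  f1_of <- function(fit) {
    est <- fit$rho_hat != 0 & upper.tri(fit$rho_hat)
    tp <- sum(est & truth)
    2 * tp / (2 * tp + sum(est & !truth) + sum(!est & truth))
  }
  f1 <- vapply(grid, function(l) f1_of(space_fit(x, l)), numeric(1))
  expect_gte(max(f1), 0.7)   # best grid point vs planted support
})

test_that("edge sets are invariant to gene order", {
  cfg <- synthetic_config(n_genes = 12, module_sizes = rep(3L, 3),
                          within_pcor = 0.45, deg_fraction_per_phase = 0)
  x <- sample_expression(make_block_precision(cfg), 300, seed = 41)
  perm <- withr::with_seed(1, sample(nrow(x)))
  net1 <- prune_to_network(space_fit(x, lambda = 5), 0.35)
  net2 <- prune_to_network(space_fit(x[perm, ], lambda = 5), 0.35)
  key <- function(net) {
    el <- igraph::as_edgelist(net)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(net1), key(net2))
})

test_that("edge count is monotone in threshold and penalty", {
  cfg <- synthetic_config(n_genes = 12, module_sizes = rep(3L, 3),
                          within_pcor = 0.45, deg_fraction_per_phase = 0)
  x <- sample_expression(make_block_precision(cfg), 300, seed = 43)
  pc <- partial_correlations_exact(x)
  n_edges <- vapply(c(0.1, 0.3, 0.5, 0.7),
                    function(th) igraph::ecount(prune_to_network(pc, th)),
                    numeric(1))
  expect_true(all(diff(n_edges) <= 0))
  nnz <- vapply(c(1, 10, 50, 200), function(l) {
    f <- space_fit(x, lambda = l)
    sum(f$rho_hat != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("marginal correlation networks follow guilt-by-association", {
  set.seed(7)
  base <- rnorm(30)
  x <- expr_of(rbind(a = base, b = base, c = rnorm(30)),
               genes = c("a", "b", "c"))
  net <- marginal_correlation_network(x, "pearson", threshold = 0.9)
  expect_true(igraph::are_adjacent(net, "a", "b"))

  # monotone nonlinear pair: spearman captures it at least as well
  u <- sort(rnorm(30))
  y <- expr_of(rbind(a = u, b = u^3 + rnorm(30, 0, 1e-3)),
               genes = c("a", "b"))
  rp <- cor(u, u^3 + rnorm(30, 0, 1e-3))
  net_s <- marginal_correlation_network(y, "spearman", threshold = 0.99)
  expect_true(igraph::ecount(net_s) == 1)

  expect_error(marginal_correlation_network(x, "pearson", threshold = 1.0),
               "threshold")
  expect_error(marginal_correlation_network(x, "kendall"))
})

test_that("pruning keeps |rho| >= threshold and drops isolated genes", {
  rho <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  rho["a", "b"] <- rho["b", "a"] <- 0.2
  rho["a", "c"] <- rho["c", "a"] <- 0.4
  rho["b", "c"] <- rho["c", "b"] <- 0.5
  net <- prune_to_network(rho, 0.35)
  expect_equal(igraph::ecount(net), 2L)

  # tie at the threshold is kept
  net_tie <- prune_to_network(rho, 0.4)
  expect_true(igraph::are_adjacent(net_tie, "a", "c"))

  # near-zero threshold keeps every nonzero entry; zero matrix -> empty
  expect_equal(igraph::ecount(prune_to_network(rho, 1e-6)), 3L)
  empty <- prune_to_network(matrix(0, 2, 2,
                                   dimnames = list(c("x", "y"), c("x", "y"))),
                            0.35)
  expect_equal(igraph::vcount(empty), 0L)

  # isolated genes excluded from the node set
  rho2 <- rho; rho2["a", "b"] <- rho2["b", "a"] <- 0
  rho2["a", "c"] <- rho2["c", "a"] <- 0
  net2 <- prune_to_network(rho2, 0.35)
  expect_setequal(igraph::V(net2)$name, c("b", "c"))

  expect_error(prune_to_network(rho, 0), "rho_threshold")
})
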