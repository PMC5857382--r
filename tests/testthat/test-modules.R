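# brute-force modularity oracle: direct transcription of
# Q = sum_c [ e_c/m - (d_c/2m)^2 ] from edge enumeration
oracle_q <- function(net, assignment) {
  el <- igraph::as_edgelist(net)
  m <- nrow(el)
  q <- 0
  for (c in unique(assignment)) {
    genes <- names(assignment)[assignment == c]
    e_c <- sum(el[, 1] %in% genes & el[, 2] %in% genes)
    d_c <- sum(el[, 1] %in% genes) + sum(el[, 2] %in% genes)
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

test_that("modularity matches hand-derived cases", {
  tri2 <- toy_graph(c("a", "b", "b", "c", "c", "a",
                      "d", "e", "e", "f", "f", "d"))
  part <- assign_of(letters[1:6], c(1, 1, 1, 2, 2, 2))
  # two disjoint triangles: e_c = 3, m = 6, d_c = 6 per module
  expect_equal(modularity_q(tri2, part), 0.5)
  # whole network as one module
  expect_equal(modularity_q(tri2, assign_of(letters[1:6], rep(1, 6))), 0)
  # all singletons: Q = -sum (d_c/2m)^2 < 0
  singl <- assign_of(letters[1:6], 1:6)
  expect_lt(modularity_q(tri2, singl), 0)
  expect_equal(modularity_q(tri2, singl), oracle_q(tri2, singl))
  # missing node is an error naming it
  expect_error(modularity_q(tri2, part[-1]), "a")
})

test_that("modularity agrees with the formula oracle and igraph on random graphs", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      n <- sample(3:8, 1)
      g <- igraph::sample_gnp(n, 0.5)
      if (igraph::ecount(g) == 0) next
      igraph::V(g)$name <- letters[1:n]
      memb <- sample(1:3, n, replace = TRUE)
      a <- assign_of(letters[1:n], memb)
      expect_equal(modularity_q(g, a), oracle_q(g, a), tolerance = 1e-12)
      expect_equal(modularity_q(g, a),
                   igraph::modularity(g, memb), tolerance = 1e-12)
    }
  })
})

test_that("walktrap splits two joined 5-cliques at the best bipartition", {
  g <- igraph::union(clique_graph(paste0("a", 1:5)),
                     clique_graph(paste0("b", 1:5)))
  g <- igraph::add_edges(g, match(c("a1", "b1"), igraph::V(g)$name))
  igraph::E(g)$weight <- 1
  part <- walktrap_modules(g)
  truth <- assign_of(igraph::V(g)$name,
                     ifelse(grepl("^a", igraph::V(g)$name), 1, 2))
  expect_equal(ari(part$assignment[names(truth)], truth), 1)

  # brute-force best-modularity bipartition on the 10-node graph agrees
  nodes <- igraph::V(g)$name
  best_q <- -Inf; best_split <- NULL
  for (mask in 1:(2^9 - 1)) {
    lab <- c(1L, as.integer(intToBits(mask))[1:9]) # node 1 fixed: symmetry
    a <- assign_of(nodes, lab + 1L)
    q <- modularity_q(g, a)
    if (q > best_q) { best_q <- q; best_split <- a }
  }
  expect_equal(ari(best_split, truth), 1)
  expect_equal(part$q, best_q, tolerance = 1e-12)
})

test_that("walktrap recovers planted blocks and is label-invariant", {
  pm <- matrix(0.01, 4, 4); diag(pm) <- 0.3
  g <- withr::with_seed(7, igraph::sample_sbm(100, pref.matrix = pm,
                                              block.sizes = rep(25, 4)))
  igraph::V(g)$name <- sprintf("n%03d", 1:100)
  igraph::E(g)$weight <- 1
  part <- walktrap_modules(g)
  truth <- assign_of(igraph::V(g)$name, rep(1:4, each = 25))
  expect_gte(ari(part$assignment[names(truth)], truth), 0.9)

  # relabelling the nodes permutes but does not change the partition
  g2 <- g
  igraph::V(g2)$name <- sprintf("m%03d", 100:1)
  part2 <- walktrap_modules(g2)
  relabelled <- part2$assignment[sprintf("m%03d", 100:1)]
  names(relabelled) <- sprintf("n%03d", 1:100)
  expect_equal(ari(part$assignment[names(truth)], relabelled[names(truth)]), 1)
})

test_that("a single clique is one module and edgeless graphs error", {
  g <- clique_graph(letters[1:5])
  part <- walktrap_modules(g)
  expect_equal(length(unique(part$assignment)), 1L)
  lone <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lone)$name <- c("a", "b", "c")
  expect_error(walktrap_modules(lone), "pruning")
})

test_that("curation merges small detached components and never loses genes", {
  # a 6-clique plus a detached pair initially split into singletons
  g <- igraph::union(clique_graph(paste0("c", 1:6)), toy_graph(c("x", "y")))
  igraph::E(g)$weight <- 1
  raw <- module_partition(assign_of(igraph::V(g)$name,
                                    c(rep(1, 6), 2, 3)[match(igraph::V(g)$name,
                                      c(paste0("c", 1:6), "x", "y"))]),
                          g, method = "manual")
  cur <- curate_modules(raw, g, max_detached_size = 10)
  expect_equal(cur$assignment[["x"]], cur$assignment[["y"]])
  expect_equal(length(cur$assignment), length(raw$assignment))
  expect_gte(cur$q, raw$q)

  # connected network: nothing to curate
  part <- walktrap_modules(clique_graph(letters[1:4]))
  cur2 <- curate_modules(part, clique_graph(letters[1:4]))
  expect_equal(ari(cur2$assignment, part$assignment), 1)

  # curation never splits a module
  tab <- table(raw$assignment[names(cur$assignment)], cur$assignment)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("hubs are genes with at least five connections by default", {
  star <- toy_graph(as.vector(rbind("hub", paste0("leaf", 1:6))))
  h <- extract_hubs(star)
  expect_equal(h$gene, "hub")
  expect_equal(h$degree, 6)
  all_nodes <- extract_hubs(star, min_degree = 1)
  expect_equal(nrow(all_nodes), 7L)
  expect_equal(formals(extract_hubs)$min_degree, 5)
})

test_that("component census counts sizes and node fractions", {
  g <- toy_graph(c("a", "b", "c", "d", "e", "f", "f", "g"))
  cen <- component_census(g)
  expect_equal(cen$n_components[cen$size == 2], 2L)
  expect_equal(cen$node_fraction[cen$size == 2], 4 / 7)
  one <- component_census(clique_graph(letters[1:4]))
  expect_equal(one, data.frame(size = 4L, n_components = 1L,
                               node_fraction = 1))
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(component_census(empty)), 0L)
})
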