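test_that("gene-set mapping reports per-node labels and coverage", {
  net <- toy_graph(c("a", "b", "b", "c", "c", "d"))
  sets <- gene_set_collection(list(R1 = c("a", "b"), R2 = c("b", "z"),
                                   R3 = c("y", "z")),
                              universe = c("a", "b", "c", "d", "y", "z"))
  m <- map_gene_sets(net, sets)
  expect_setequal(m$annotation[["b"]], c("R1", "R2"))   # overlapping sets
  expect_equal(m$annotation[["d"]], character(0))
  cov3 <- m$coverage[m$coverage$set == "R3", ]
  expect_equal(cov3$present, 0L)
  expect_true(all(m$coverage$present + m$coverage$absent == m$coverage$size))
})

test_that("first-degree expansion takes seeds plus direct neighbours", {
  path <- toy_graph(c("a", "b", "b", "c", "c", "d"))
  sub <- first_degree_expansion(path, "b")
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(sub), 2L)
  expect_equal(unname(igraph::V(sub)$role[igraph::V(sub)$name == "b"]), "seed")
  expect_setequal(igraph::V(sub)$name[igraph::V(sub)$role == "neighbor"],
                  c("a", "c"))

  # seeds = all nodes reproduces the parent
  all_sub <- first_degree_expansion(path, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(all_sub), igraph::ecount(path))

  # isolated seed: single node, no edges
  iso <- toy_graph(c("a", "b"), isolated = "x")
  sub_iso <- first_degree_expansion(iso, "x")
  expect_equal(igraph::V(sub_iso)$name, "x")
  expect_equal(igraph::ecount(sub_iso), 0L)

  expect_error(first_degree_expansion(path, c("q", "r")), "no seed gene")

  # monotone growth: expanding the expansion only adds nodes
  s1 <- igraph::V(first_degree_expansion(path, "b"))$name
  s2 <- igraph::V(first_degree_expansion(path, s1))$name
  expect_true(all(s1 %in% s2))

  # neighbour-neighbour edges included by default, excluded on request
  tri <- toy_graph(c("s", "n1", "s", "n2", "n1", "n2"))
  expect_equal(igraph::ecount(first_degree_expansion(tri, "s")), 3L)
  expect_equal(igraph::ecount(
    first_degree_expansion(tri, "s", seeds_incident_only = TRUE)), 2L)
})

test_that("biclustering orders duplicates together and recovers groups", {
  withr::with_seed(6, {
    x <- rbind(matrix(rnorm(5 * 10, 5, 0.1), 5),
               matrix(rnorm(5 * 10, -5, 0.1), 5))
  })
  x <- expr_of(x)
  bc <- bicluster_order(x, k = 2)
  expect_setequal(names(bc$row_clusters)[bc$row_clusters == bc$row_clusters[[1]]],
                  rownames(x)[1:5])
  expect_setequal(sort(bc$col_order), seq_len(ncol(x)))

  # duplicated rows merge first and sit adjacent in the leaf order
  y <- expr_of(rbind(x[1, ], x[1, ], x[6:10, ]))
  bcy <- bicluster_order(y)
  pos <- match(c(1, 2), bcy$row_order)
  expect_equal(abs(diff(pos)), 1L)

  flat <- expr_of(matrix(1, 3, 4), log_transformed = TRUE)
  expect_warning(bf <- bicluster_order(flat), "identical")
  expect_equal(bf$row_order, 1:3)
  expect_error(bicluster_order(x[1, , drop = FALSE]), "at least 2")
})

test_that("network intersection keeps shared nodes and edges", {
  a <- toy_graph(c("a", "b", "b", "c"), weights = c(0.5, 0.6))
  b <- toy_graph(c("b", "c", "c", "d"), weights = c(0.7, 0.8))
  inter <- network_intersection(a, b)
  expect_setequal(igraph::V(inter)$name, c("b", "c"))
  expect_equal(igraph::ecount(inter), 1L)
  expect_equal(igraph::E(inter)$weight_a, 0.6)
  expect_equal(igraph::E(inter)$weight_b, 0.7)

  # identity: a network intersected with itself is itself
  self <- network_intersection(a, a)
  edge_keys <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_setequal(igraph::V(self)$name, igraph::V(a)$name)
  expect_identical(edge_keys(self), edge_keys(a))
  expect_equal(igraph::E(self)$weight_a, igraph::E(self)$weight_b)

  # commutative up to mapping direction; size bounds hold
  ba <- network_intersection(b, a)
  expect_setequal(igraph::V(ba)$name, igraph::V(inter)$name)
  expect_lte(igraph::ecount(inter),
             min(igraph::ecount(a), igraph::ecount(b)))

  # edge-disjoint networks on shared nodes: nodes kept, no edges
  c1 <- toy_graph(c("a", "b"))
  c2 <- toy_graph(c("a", "c"), isolated = "b")
  dis <- network_intersection(c1, c2)
  expect_setequal(igraph::V(dis)$name, c("a", "b"))
  expect_equal(igraph::ecount(dis), 0L)

  # explicit one-to-one mapping, collisions rejected
  b2 <- toy_graph(c("B", "C"), weights = 0.9)
  idmap <- data.frame(id_a = c("b", "c"), id_b = c("B", "C"))
  im <- network_intersection(a, b2, idmap)
  expect_equal(igraph::ecount(im), 1L)
  bad <- data.frame(id_a = c("b", "b"), id_b = c("B", "C"))
  expect_error(network_intersection(a, b2, bad), "one-to-one")
})

test_that("conserved modules reappear when intersecting planted twins", {
  ds <- make_staged_expression(small_config(seed = 31, samples_per_phase = 40,
                                            deg_fraction_per_phase = 0))
  lx <- log_transform(ds$expression)
  net <- prune_to_network(partial_correlations_exact(lx), 0.35)
  inter <- network_intersection(net, net)
  sets <- make_gene_sets(ds$truth, n_decoys = 2, decoy_size = 3, seed = 1)
  cons <- conserved_modules(inter, sets)
  truth <- ds$truth$planted_partition
  sh <- intersect(names(cons$partition$assignment), names(truth))
  expect_equal(ari(cons$partition$assignment[sh], truth[sh]), 1)
  top <- cons$enrichment[cons$enrichment$fdr < 0.05, ]
  expect_true(all(grepl("^regulon", top$set)))

  empty <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(empty)$name <- c("a", "b")
  expect_error(conserved_modules(empty, sets), "no conserved structure")
})
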