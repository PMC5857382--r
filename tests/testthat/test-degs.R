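make_two_phase <- function(ref_mean, tgt_mean, n_rep = 3, sd = 0.01,
                           n_genes = 1, seed = 1) {
  withr::with_seed(seed, {
    vals <- cbind(matrix(rnorm(n_genes * n_rep, ref_mean, sd), n_genes),
                  matrix(rnorm(n_genes * n_rep, tgt_mean, sd), n_genes))
  })
  vals[vals < 0] <- 0
  expr <- expr_of(vals, log_transformed = FALSE,
                  samples = c(paste0("P1_r", 1:n_rep), paste0("P2_r", 1:n_rep)))
  design <- phase_design(colnames(expr), rep(c("P1", "P2"), each = n_rep))
  list(expr = expr, design = design)
}

test_that("fold change follows the pseudocount formula", {
  d <- make_two_phase(100, 800)
  degs <- call_degs(d$expr, d$design)
  # log2((800 + 1) / (100 + 1)) = 2.988...
  expect_equal(degs$log2fc, log2(801 / 101), tolerance = 0.01)
  expect_equal(degs$call, "up")
})

test_that("a phase contrasted with identical values yields zero DEGs", {
  withr::with_seed(2, vals <- matrix(rexp(20 * 4, 0.01), 20, 4))
  expr <- expr_of(cbind(vals, vals), log_transformed = FALSE,
                  samples = c(paste0("P1_r", 1:4), paste0("P2_r", 1:4)))
  design <- phase_design(colnames(expr), rep(c("P1", "P2"), each = 4))
  degs <- call_degs(expr, design)
  expect_true(all(degs$log2fc == 0))
  expect_true(all(degs$call == "ns"))
})

test_that("planted DEGs are recovered with high sensitivity and low FPR", {
  cfg <- synthetic_config(samples_per_phase = 6, noise_sd = 0.1,
                          effect_log2fc = 2, seed = 5)
  ds <- make_staged_expression(cfg)
  degs <- call_degs(ds$expression, ds$design)
  called <- deg_sets(degs)
  tp <- fp <- fn <- tn <- 0
  for (ct in names(ds$truth$planted_degs)) {
    planted <- ds$truth$planted_degs[[ct]]$gene
    cl <- called[[ct]]
    neg <- setdiff(rownames(ds$expression), planted)
    tp <- tp + length(intersect(cl, planted))
    fn <- fn + length(setdiff(planted, cl))
    fp <- fp + length(intersect(cl, neg))
    tn <- tn + length(setdiff(neg, cl))
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_lte(fp / (fp + tn), 0.05)

  # planted direction is respected
  up_truth <- ds$truth$planted_degs[["P6_vs_P1"]]
  tab <- degs[degs$contrast == "P6_vs_P1" & degs$gene %in% up_truth$gene, ]
  agree <- mean(tab$call[match(up_truth$gene, tab$gene)] == up_truth$direction,
                na.rm = TRUE)
  expect_gte(agree, 0.95)
})

test_that("DEG calls are invariant to sample column order", {
  ds <- make_staged_expression(small_config())
  degs1 <- call_degs(ds$expression, ds$design)
  perm <- withr::with_seed(8, sample(ncol(ds$expression)))
  degs2 <- call_degs(ds$expression[, perm], ds$design)
  expect_equal(degs1, degs2)
})

test_that("stricter thresholds never increase the number of calls", {
  ds <- make_staged_expression(small_config(seed = 12))
  n_calls <- function(lfc, alpha)
    sum(call_degs(ds$expression, ds$design, lfc_threshold = lfc,
                  alpha = alpha)$call != "ns")
  expect_lte(n_calls(1.5, 0.05), n_calls(1, 0.05))
  expect_lte(n_calls(1, 0.01), n_calls(1, 0.05))
})

test_that("single-replicate input falls back to fold-change-only mode", {
  expr <- expr_of(matrix(c(10, 100, 50, 52), 2, 2), log_transformed = FALSE,
                  samples = c("P1_r1", "P2_r1"))
  design <- phase_design(colnames(expr), c("P1", "P2"))
  expect_message(degs <- call_degs(expr, design), "fold-change-only")
  expect_equal(degs$call, c("up", "ns"))
  expect_true(all(degs$p == 1))
})

test_that("up/down counts partition the calls and track cumulative truth", {
  empty <- call_degs(make_two_phase(50, 50)$expr,
                     make_two_phase(50, 50)$design)
  cnt0 <- updown_counts(empty)
  expect_equal(cnt0$total, 0L)

  ds <- make_staged_expression(small_config(seed = 3))
  degs <- call_degs(ds$expression, ds$design)
  cnt <- updown_counts(degs)
  expect_equal(cnt$up + cnt$down, cnt$total)
  expect_equal(sum(cnt$total), sum(degs$call != "ns"))
  expect_true(all(diff(cnt$total) >= 0))   # cumulative planting
})

test_that("venn sectors partition the union", {
  v <- venn_partition(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(sum(v$count), 3L)
  expect_equal(v$count[v$pattern == "11"], 1L)
  expect_equal(v$count[v$pattern == "10"], 1L)
  expect_equal(v$count[v$pattern == "01"], 1L)

  same <- venn_partition(list(A = letters[1:4], B = letters[1:4]))
  expect_equal(same$pattern, "11")
  expect_equal(same$count, 4L)

  withr::with_seed(5, {
    sets <- lapply(1:5, function(i) sample(letters, sample(5:15, 1)))
    names(sets) <- paste0("s", 1:5)
    v5 <- venn_partition(sets)
    expect_equal(sum(v5$count), length(unique(unlist(sets))))
  })
  expect_error(venn_partition(rep(list(letters), 7)), "1 to 6")
})

test_that("top-expressed ranking uses the minimum phase mean", {
  expr <- expr_of(rbind(A = c(5, 5, 100, 100, 100, 100),
                        B = c(50, 50, 50, 50, 50, 50)),
                  genes = c("A", "B"), log_transformed = FALSE,
                  samples = sprintf("P%d_r%d", rep(1:3, each = 2), 1:2))
  design <- phase_design(colnames(expr), rep(paste0("P", 1:3), each = 2))
  top <- rank_top_expressed(expr, design, fraction = 0.5)
  expect_equal(top$gene, "B")          # min 50 beats min 5
  expect_equal(nrow(rank_top_expressed(expr, design, fraction = 1.0)), 2L)

  ds <- make_staged_expression(small_config())
  expect_equal(nrow(rank_top_expressed(ds$expression, ds$design, 0.10)),
               ceiling(0.10 * nrow(ds$expression)))
})

test_that("the network overlay distinguishes consistent and mixed DEGs", {
  degs <- data.frame(
    contrast = rep(c("P2_vs_P1", "P6_vs_P1"), each = 4),
    gene = rep(c("up1", "mix", "nsg", "dwn"), 2),
    log2fc = 0, p = 1, fdr = 1,
    call = c("up", "up", "ns", "down", "up", "down", "ns", "down"),
    stringsAsFactors = FALSE)
  degs$contrast <- factor(degs$contrast, ordered = TRUE)
  net <- toy_graph(c("up1", "mix", "nsg", "dwn", "dwn", "ghost"))
  ov <- overlay_on_network(net, degs)
  expect_equal(unname(ov[c("up1", "mix", "nsg", "dwn", "ghost")]),
               c("up_all", "mixed", "ns", "down_all", "not_in_table"))
})
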