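#' Configuration for the synthetic sporulation dataset
#'
#' The generator emulates the structure the downstream stages are built to
#' detect: block-structured partial-correlation dependence among gene
#' modules, phase-staged mean shifts producing a growing number of
#' differentially expressed genes over the sporulation time course, and
#' regulon gene sets aligned with the planted modules.
#'
#' Defaults describe a staged sporulation study at desk scale: many small,
#' strongly partially-correlated modules (the equicorrelated precision block
#' is positive definite only when `within_pcor * (size - 1) < 1`, so modules
#' whose partial correlations survive the 0.35 pruning threshold are
#' necessarily small), a background of unconnected genes, and a sample count
#' per gene comparable to a ~250-condition compendium.
#'
#' @param n_genes total number of genes.
#' @param module_sizes integer vector of planted module sizes (each >= 2,
#'   sum <= `n_genes`; the remainder are background genes with no planted
#'   dependence).
#' @param within_pcor partial-correlation magnitude in (0, 1) shared by all
#'   within-module gene pairs.
#' @param phases ordered phase labels; the first is the reference of all
#'   differential-expression contrasts.
#' @param samples_per_phase replicates per phase.
#' @param deg_fraction_per_phase fraction of genes newly becoming
#'   differentially expressed at each post-reference phase (cumulative
#'   total must not exceed 1).
#' @param effect_log2fc log2 fold-change magnitude (>= 0) planted on
#'   differentially expressed genes from their onset phase onward.
#' @param noise_sd per-gene standard deviation (log2 scale) of the
#'   correlated biological variation.
#' @param seed integer seed; all outputs are byte-identical for a fixed seed.
#' @param baseline positive scale factor of the exported expression values
#'   (`baseline * 2^signal`), mimicking RPKM positivity.
#' @param cumulative logical; if `TRUE` (default) a gene differential at one
#'   phase stays differential at all later phases, so DEG counts versus the
#'   reference are non-decreasing over the time course. `FALSE` plants
#'   transient single-phase effects for stress-testing.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 100,
                             module_sizes = rep(3L, 25),
                             within_pcor = 0.45,
                             phases = paste0("P", 1:6),
                             samples_per_phase = 42,
                             deg_fraction_per_phase = 0.10,
                             effect_log2fc = 2,
                             noise_sd = 0.3,
                             seed = 1L,
                             baseline = 100,
                             cumulative = TRUE) {
  stopifnot(n_genes >= 1, length(phases) >= 2, samples_per_phase >= 1,
            effect_log2fc >= 0, noise_sd > 0, baseline > 0)
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) && any(module_sizes < 2))
    stop("all module sizes must be >= 2")
  if (sum(module_sizes) > n_genes)
    stop("sum of module_sizes exceeds n_genes")
  if (within_pcor <= 0 || within_pcor >= 1)
    stop("within_pcor must lie in (0, 1)")
  if (deg_fraction_per_phase < 0 || deg_fraction_per_phase > 1)
    stop("deg_fraction_per_phase must lie in [0, 1]")
  n_contrasts <- length(phases) - 1L
  if (deg_fraction_per_phase * n_contrasts > 1 + 1e-12)
    stop("cumulative DEG fraction ", deg_fraction_per_phase * n_contrasts,
         " exceeds 1; lower deg_fraction_per_phase")
  structure(list(n_genes = as.integer(n_genes), module_sizes = module_sizes,
                 within_pcor = within_pcor, phases = phases,
                 samples_per_phase = as.integer(samples_per_phase),
                 deg_fraction_per_phase = deg_fraction_per_phase,
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 seed = as.integer(seed), baseline = baseline,
                 cumulative = isTRUE(cumulative)),
            class = "synthetic_config")
}

synthetic_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Block-structured precision matrix with known partial correlations
#'
#' Builds the inverse covariance of the generating Gaussian graphical model:
#' unit diagonal, off-diagonal `-within_pcor` inside each module block, zero
#' elsewhere. The implied partial correlation
#' \eqn{\rho^{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}} then equals
#' `within_pcor` exactly for every within-module pair, and background genes
#' are independent of everything.
#'
#' A block of size m is positive definite iff `within_pcor * (m - 1) < 1`;
#' infeasible configurations are rejected with a diagnostic naming the
#' offending block rather than silently distorting the planted correlations.
#'
#' @param config a [synthetic_config()].
#' @return symmetric positive-definite matrix with gene ID dimnames.
#' @export
make_block_precision <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  w <- config$within_pcor
  sizes <- config$module_sizes
  bad <- which(w * (sizes - 1) >= 1 - 1e-10)
  if (length(bad))
    stop("precision block ", bad[1], " (size ", sizes[bad[1]],
         ", within_pcor ", w, ") is not positive definite; ",
         "need within_pcor < 1/(size - 1)")
  ids <- synthetic_gene_ids(config$n_genes)
  omega <- diag(config$n_genes)
  at <- 0L
  for (m in sizes) {
    idx <- at + seq_len(m)
    omega[idx, idx] <- -w
    diag(omega)[idx] <- 1
    at <- at + m
  }
  dimnames(omega) <- list(ids, ids)
  omega
}

#' Sample from the Gaussian graphical model
#'
#' Draws `n_samples` zero-mean multivariate normal vectors with covariance
#' equal to the inverse of `precision`, via the Cholesky factor of the
#' covariance. Reproducible for a fixed seed.
#'
#' @param precision symmetric positive-definite matrix (genes x genes).
#' @param n_samples number of samples (>= 1).
#' @param seed integer seed.
#' @return genes x samples numeric matrix.
#' @export
sample_expression <- function(precision, n_samples, seed) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  p <- nrow(precision)
  if (!isSymmetric(unname(precision), tol = 1e-8))
    stop("precision matrix must be symmetric")
  R <- tryCatch(chol(precision), error = function(e)
    stop("precision matrix is not positive definite"))
  # x = L z with L L' = Sigma = Omega^-1; take L' = R^-1 (R upper Cholesky
  # of Omega), i.e. solve R x = z.
  z <- withr::with_seed(seed, matrix(stats::rnorm(p * n_samples), p, n_samples))
  x <- backsolve(R, z)
  rownames(x) <- rownames(precision)
  colnames(x) <- sprintf("s%05d", seq_len(n_samples))
  x
}

#' Generate the staged synthetic expression dataset
#'
#' All samples share the block covariance of [make_block_precision()]. The
#' correlated draw is rescaled to unit per-gene variance (a diagonal
#' rescaling, which leaves partial correlations untouched) and multiplied by
#' `noise_sd`, so `noise_sd` is the within-phase per-gene standard deviation
#' on the log2 scale. Planted differentially expressed genes receive a mean
#' shift of `+/- effect_log2fc` from their onset phase onward (cumulative
#' staging: DEG counts versus the reference are non-decreasing over phases).
#' Values are exported on a non-negative scale, `baseline * 2^signal`, so
#' fold changes on the export scale equal `2^effect_log2fc`.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements
#'   `expression` (genes x samples, export scale), `design` (phase design
#'   data.frame), and `truth` (list: `planted_partition` named integer
#'   vector with 0 = background, `planted_regulons` gene-set collection,
#'   `planted_degs` per-contrast data.frames with columns gene/direction,
#'   `precision` the generating inverse covariance, `config`).
#' @export
make_staged_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  omega <- make_block_precision(config)
  ids <- rownames(omega)
  phases <- config$phases
  reference <- phases[1]
  onset_phases <- phases[-1]
  n <- length(phases) * config$samples_per_phase

  z <- sample_expression(omega, n, seed = config$seed)
  sigma_marg <- sqrt(diag(solve(omega)))
  z <- z / sigma_marg * config$noise_sd

  sample_phase <- rep(phases, each = config$samples_per_phase)
  sample_id <- sprintf("%s_r%02d", sample_phase,
                       rep(seq_len(config$samples_per_phase), times = length(phases)))
  colnames(z) <- sample_id
  design <- phase_design(sample_id, sample_phase, phase_levels = phases)

  # planted partition: module genes first, background = 0
  part <- integer(config$n_genes)
  at <- 0L
  for (k in seq_along(config$module_sizes)) {
    part[at + seq_len(config$module_sizes[k])] <- k
    at <- at + config$module_sizes[k]
  }
  names(part) <- ids

  # staged DEG onsets: disjoint draws per onset phase, signs +/- at random
  n_new <- round(config$deg_fraction_per_phase * config$n_genes)
  deg_onset <- withr::with_seed(config$seed + 1L, {
    pool <- ids
    lapply(onset_phases, function(ph) {
      take <- sample(pool, min(n_new, length(pool)))
      pool <<- setdiff(pool, take)
      stats::setNames(sample(c(-1, 1), length(take), replace = TRUE), take)
    })
  })
  names(deg_onset) <- onset_phases

  mu <- matrix(0, config$n_genes, n, dimnames = list(ids, sample_id))
  for (k in seq_along(onset_phases)) {
    genes <- names(deg_onset[[k]])
    if (!length(genes)) next
    cols <- if (config$cumulative)
      sample_phase %in% onset_phases[k:length(onset_phases)]
    else sample_phase == onset_phases[k]
    mu[genes, cols] <- mu[genes, cols] +
      deg_onset[[k]] * config$effect_log2fc
  }

  expr <- expression_matrix(config$baseline * 2^(mu + z), log_transformed = FALSE)

  # per-contrast planted DEG sets (cumulative => nested P2 <= ... <= P6)
  planted_degs <- list()
  for (k in seq_along(onset_phases)) {
    active <- if (config$cumulative) seq_len(k) else k
    d <- unlist(unname(deg_onset[active]))
    planted_degs[[paste0(onset_phases[k], "_vs_", reference)]] <-
      data.frame(gene = names(d),
                 direction = ifelse(d > 0, "up", "down"),
                 stringsAsFactors = FALSE)
  }

  regs <- split(names(part)[part > 0], part[part > 0])
  names(regs) <- sprintf("regulon_%02d", as.integer(names(regs)))
  truth <- list(planted_partition = part,
                planted_regulons = gene_set_collection(regs, universe = ids),
                planted_degs = planted_degs,
                precision = omega,
                config = config)
  structure(list(expression = expr, design = design, truth = truth),
            class = "synthetic_dataset")
}

#' Regulon-style gene sets from the planted truth, plus decoys
#'
#' One set per planted module (the synthetic "regulons", standing in for
#' curated regulon lists) plus `n_decoys` uniformly random gene sets drawn
#' from the full gene universe, used to calibrate enrichment specificity.
#'
#' @param truth the `truth` element of a [make_staged_expression()] result.
#' @param n_decoys number of random decoy sets.
#' @param decoy_size genes per decoy set (<= universe size).
#' @param seed integer seed for the decoy draws.
#' @return a [gene_set_collection()].
#' @export
make_gene_sets <- function(truth, n_decoys = 0, decoy_size = 10, seed = 1L) {
  universe <- names(truth$planted_partition)
  if (!length(universe)) stop("empty gene universe")
  if (n_decoys > 0 && decoy_size > length(universe))
    stop("decoy_size exceeds the universe size")
  sets <- truth$planted_regulons$sets
  if (n_decoys > 0) {
    decoys <- withr::with_seed(seed, lapply(seq_len(n_decoys), function(i)
      sample(universe, decoy_size)))
    names(decoys) <- sprintf("decoy_%02d", seq_len(n_decoys))
    sets <- c(sets, decoys)
  }
  gene_set_collection(sets, universe = universe)
}

#' Write a synthetic dataset to disk
#'
#' Exports the expression matrix and design as TSV, the planted regulons as
#' GMT, and the planted partition / DEG truth as TSV sidecars.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written file paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             design = file.path(dir, "design.tsv"),
             regulons = file.path(dir, "regulons.gmt"),
             truth_partition = file.path(dir, "truth_partition.tsv"),
             truth_degs = file.path(dir, "truth_degs.tsv"))
  write_expression_tsv(dataset$expression, paths["expression"])
  utils::write.table(dataset$design, paths["design"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(dataset$truth$planted_regulons, paths["regulons"])
  part <- dataset$truth$planted_partition
  utils::write.table(data.frame(gene_id = names(part), module_id = part),
                     paths["truth_partition"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  degs <- do.call(rbind, lapply(names(dataset$truth$planted_degs), function(ct)
    cbind(contrast = ct, dataset$truth$planted_degs[[ct]])))
  if (is.null(degs)) degs <- data.frame(contrast = character(),
                                        gene = character(),
                                        direction = character())
  utils::write.table(degs, paths["truth_degs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
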