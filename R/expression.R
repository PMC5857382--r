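#' Construct an expression matrix
#'
#' Wraps a numeric genes x samples matrix with the minimal validation the
#' downstream inference steps rely on: unique gene and sample identifiers,
#' no missing values, and a flag recording whether the values are already on
#' a log scale (RPKM-like inputs are non-negative and get log2-transformed
#' before correlation-based inference).
#'
#' @param values numeric matrix, rows = genes, columns = samples; must carry
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param log_transformed logical; `TRUE` if values are already logged.
#' @return the validated matrix with attribute `log_transformed` set.
#' @export
expression_matrix <- function(values, log_transformed = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (gene IDs) and colnames (sample IDs)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (!log_transformed && any(values < 0))
    stop("non-logged expression values must be non-negative")
  attr(values, "log_transformed") <- isTRUE(log_transformed)
  values
}

#' Is an expression matrix on the log scale?
#' @param expr expression matrix.
#' @return logical flag (defaults to `FALSE` when the attribute is absent).
#' @export
is_log_transformed <- function(expr) isTRUE(attr(expr, "log_transformed"))

#' Log2-transform an expression matrix
#'
#' `log2(x + pseudocount)`; a no-op when the matrix is already logged. The
#' pseudocount guards genes with zero expression in some samples.
#'
#' @param expr expression matrix (non-negative values).
#' @param pseudocount positive offset added before taking logs.
#' @return log-scale expression matrix.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (is_log_transformed(expr)) return(expr)
  stopifnot(pseudocount > 0)
  out <- log2(expr + pseudocount)
  attr(out, "log_transformed") <- TRUE
  out
}

#' Standardize gene rows to mean zero, unit variance
#'
#' Genes with zero sample variance carry no correlation information and are
#' dropped with a warning listing their IDs.
#'
#' @param expr expression matrix (any scale).
#' @return standardized matrix; rows have mean 0 and variance 1.
#' @export
standardize <- function(expr) {
  if (ncol(expr) < 2) stop("standardization requires at least 2 samples")
  v <- apply(expr, 1, stats::var)
  zero <- v <= .Machine$double.eps * 100
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(rownames(expr)[zero], 10), collapse = ", "),
            if (sum(zero) > 10) ", ..." else "")
    expr <- expr[!zero, , drop = FALSE]
    v <- v[!zero]
  }
  if (nrow(expr) == 0) stop("no genes left after dropping zero-variance rows")
  out <- (expr - rowMeans(expr)) / sqrt(v)
  attr(out, "log_transformed") <- attr(expr, "log_transformed")
  out
}

#' Build a phase design table
#'
#' Maps samples to ordered sporulation phases (P0 = before the onset of
#' sporulation, P1 = before asymmetric division, ... P6 = phase-bright
#' spores). P1 is the reference phase of the differential-expression
#' contrasts; P0, when present, is carried but never contrasted.
#'
#' @param sample_id character vector of sample IDs.
#' @param phase character vector (same length) of phase labels.
#' @param replicate optional replicate labels; defaults to a counter within
#'   phase.
#' @param phase_levels ordered phase labels; defaults to the order of first
#'   appearance.
#' @return data.frame with columns `sample_id`, `phase` (ordered factor),
#'   `replicate`.
#' @export
phase_design <- function(sample_id, phase, replicate = NULL,
                         phase_levels = unique(phase)) {
  stopifnot(length(sample_id) == length(phase))
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in design")
  if (!all(phase %in% phase_levels)) stop("phase labels outside `phase_levels`")
  if (is.null(replicate)) replicate <- stats::ave(seq_along(phase), phase, FUN = seq_along)
  data.frame(sample_id = as.character(sample_id),
             phase = factor(phase, levels = phase_levels, ordered = TRUE),
             replicate = replicate,
             stringsAsFactors = FALSE)
}

check_design <- function(expr, design, reference) {
  if (!all(colnames(expr) %in% design$sample_id))
    stop("samples missing from design: ",
         paste(setdiff(colnames(expr), design$sample_id), collapse = ", "))
  if (!reference %in% design$phase)
    stop("reference phase ", reference, " has no samples")
  invisible(TRUE)
}
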