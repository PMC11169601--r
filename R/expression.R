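# Expression preprocessing: the CPM inclusion filter and expression PCs.

subset_grm <- function(grm, ids) {
  if (is.null(grm)) return(NULL)
  ix <- match(ids, grm$sample_ids)
  if (anyNA(ix)) abort("GRM is missing requested samples")
  structure(list(values = grm$values[ix, ix, drop = FALSE],
                 sample_ids = ids,
                 n_variants_used = grm$n_variants_used),
            class = "grm")
}

#' Filter lowly expressed genes on counts per million
#'
#' CPM = count x 1e6 / library size (library size = total counts of the
#' sample at matrix creation). A gene is excluded iff the fraction of
#' samples with CPM below `min_cpm` is at least `max_low_prop` ("at least"
#' is read inclusively: a gene low in exactly 25% of samples is excluded).
#' Log-CPM for the retained genes is attached for downstream modelling.
#'
#' @param expr An `expr_matrix`.
#' @param min_cpm CPM threshold (default 3).
#' @param max_low_prop Maximum tolerated fraction of low-CPM samples
#'   (default 0.25, exclusion is inclusive at the boundary).
#' @return The filtered `expr_matrix` with a `log_cpm` element (log2 CPM).
#' @export
cpm_filter <- function(expr, min_cpm = 3, max_low_prop = 0.25) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (any(expr$lib_size == 0)) abort("sample with zero library size")
  cpm <- edgeR::cpm(expr$counts, lib.size = expr$lib_size)
  low_prop <- rowMeans(cpm < min_cpm)
  keep <- low_prop < max_low_prop
  inform(sprintf("CPM filter: %d of %d genes retained (CPM >= %g in > %g%% of samples)",
                 sum(keep), length(keep), min_cpm, 100 * (1 - max_low_prop)))
  out <- new_expr_matrix(expr$counts[keep, , drop = FALSE],
                         expr$annotation[keep, ], expr$samples)
  out$lib_size <- expr$lib_size
  out$log_cpm <- edgeR::cpm(out$counts, lib.size = out$lib_size, log = TRUE)
  out
}

#' Principal components of log-CPM expression
#'
#' PCs of the sample x gene log-CPM matrix after centering genes, used as
#' fixed covariates to absorb batch structure. Deterministic sign
#' convention: within each component the largest-magnitude gene loading is
#' made positive.
#'
#' @param log_cpm Gene x sample log-CPM matrix.
#' @param q Number of components (default 4). `q = 0` returns an empty
#'   covariate block.
#' @return n_samples x q matrix of PC scores (columns PC1..PCq).
#' @export
expression_pcs <- function(log_cpm, q = 4) {
  n <- ncol(log_cpm)
  if (q >= n) abort("`q` must be smaller than the number of samples")
  if (q == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(colnames(log_cpm), NULL)))
  }
  pc <- prcomp(t(log_cpm), center = TRUE, scale. = FALSE, rank. = q)
  flip <- vapply(seq_len(q), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(q), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(q))
  rownames(scores) <- colnames(log_cpm)
  scores
}
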