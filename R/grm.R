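#' Compute the allele-frequency-standardized genomic relationship matrix
#'
#' G_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
#' with p_i the sample allele frequency, over the m variants passing the MAF
#' filter. This is the standardized GRM used as the covariance kernel of the
#' polygenic random effect in the mixed model.
#'
#' @param geno A `geno_matrix`.
#' @param maf_min Minimum folded MAF for a variant to enter the GRM
#'   (default 0.01, the usual GRM filter).
#' @return A `grm`: list with `values` (n x n symmetric matrix),
#'   `sample_ids`, `n_variants_used`.
#' @export
compute_grm <- function(geno, maf_min = 0.01) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- length(geno$sample_ids)
  if (n < 2) abort("need at least 2 samples for a GRM")
  p <- colMeans(geno$dosage) / 2
  mono <- p <= 0 | p >= 1
  keep <- !mono & fold_maf(p) >= maf_min
  if (any(mono)) {
    warn(sprintf("excluding %d monomorphic variant(s) from the GRM", sum(mono)))
  }
  if (!any(keep)) abort("no polymorphic variants pass the GRM MAF filter")
  X <- geno$dosage[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(Z)
  dimnames(G) <- list(geno$sample_ids, geno$sample_ids)
  structure(list(values = G, sample_ids = geno$sample_ids,
                 n_variants_used = sum(keep)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", length(x$sample_ids), " samples, built from ",
      x$n_variants_used, " variants; mean diagonal ",
      round(mean(diag(x$values)), 3), "\n", sep = "")
  invisible(x)
}

#' Persist / load a GRM as a plain-text id + lower-triangle triplet
#'
#' @param grm A `grm` object.
#' @param path Output path prefix; writes `<path>.grm.id` and `<path>.grm.tsv`.
#' @return `write_grm` returns `path` invisibly; `read_grm` a `grm`.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  readr::write_tsv(tibble(sample_id = grm$sample_ids),
                   paste0(path, ".grm.id"), col_names = FALSE)
  n <- length(grm$sample_ids)
  idx <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  readr::write_tsv(
    tibble(i = idx[, 1], j = idx[, 2],
           n_variants = grm$n_variants_used,
           value = grm$values[idx]),
    paste0(path, ".grm.tsv"))
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  ids <- readr::read_tsv(paste0(path, ".grm.id"), col_names = "sample_id",
                         show_col_types = FALSE)$sample_id
  tri <- readr::read_tsv(paste0(path, ".grm.tsv"), show_col_types = FALSE)
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(tri$i, tri$j)] <- tri$value
  G[cbind(tri$j, tri$i)] <- tri$value
  structure(list(values = G, sample_ids = ids,
                 n_variants_used = tri$n_variants[1]),
            class = "grm")
}
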