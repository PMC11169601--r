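# Shared GLS machinery. After rotating by the GRM eigenvectors and weighting
# by 1/sqrt(gamma * d + 1), every scan is ordinary least squares; betas and
# SEs for all (variant, response) pairs come from three cross-products.

#' Precompute the rotated genotype block reused across scans
#'
#' The eigen-rotation of the dosage matrix is the expensive part of a mixed
#' model scan and does not depend on the trait, the variance components, or
#' the conditioning set. Build it once and pass it to [assoc_scan()] (and the
#' eQTL mappers) when scanning many traits, genes or cycles.
#'
#' @param geno A `geno_matrix`.
#' @param grm A `grm` aligned with `geno`, or `NULL` for the fixed-effects
#'   path (no rotation).
#' @param keep Logical vector of samples in the analysis subset (default all).
#' @return A `scan_context` used by the scan functions.
#' @export
scan_context <- function(geno, grm = NULL, keep = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  n <- length(geno$sample_ids)
  keep <- keep %||% rep(TRUE, n)
  W <- geno$dosage[keep, , drop = FALSE]
  if (is.null(grm)) {
    d <- NULL; U <- NULL; Wt <- W
  } else {
    eg <- eigen(grm$values[keep, keep, drop = FALSE], symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
    Wt <- crossprod(U, W)
  }
  structure(list(keep = keep, d = d, U = U, Wt = Wt,
                 freq = colMeans(W) / 2, variants = geno$variants),
            class = "scan_context")
}

# core: weighted residualized cross-products for response matrix Y (already
# rotated) against rotated variants Wt, given covariate block Xt (rotated)
# and weights w. Returns beta, se, t matrices (m x q).
gls_pair_scan <- function(Wt, Yt, Xt, w) {
  sw <- sqrt(w)
  Xs <- Xt * sw
  Ys <- Yt * sw
  Ws <- Wt * sw
  qrX <- qr(Xs)
  rY <- as.matrix(qr.resid(qrX, Ys))
  rW <- qr.resid(qrX, Ws)
  n <- nrow(Xs); p <- ncol(Xs)
  s_ww <- colSums(rW^2)
  s_yy <- colSums(rY^2)
  S <- crossprod(rW, rY)                      # m x q
  mono <- s_ww <= 1e-12
  s_ww_safe <- ifelse(mono, 1, s_ww)
  beta <- S / s_ww_safe
  rss <- sweep(-(S^2) / s_ww_safe, 2, s_yy, "+")
  df <- n - p - 1
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sweep(sigma2, 1, s_ww_safe, "/"))
  tval <- ifelse(se > 0, beta / se, 0)
  beta[mono, ] <- 0
  se[mono, ] <- NA_real_
  tval[mono, ] <- 0
  list(beta = beta, se = se, t = tval, mono = mono, df = df)
}

#' Single-trait mixed-model association scan
#'
#' Tests each variant, one at a time, as a fixed covariate in the linear
#' mixed model, with the phenotypic covariance V = sigma_g^2 G + sigma_e^2 I
#' held fixed at the null-model REML estimates. Variants listed in
#' `conditioning_set` are jointly fitted as fixed covariates in every test
#' (the conditional scan used by stepwise multi-trait selection). Two-sided
#' p-values use the standard-normal reference on t = beta/se.
#'
#' @param geno A `geno_matrix`.
#' @param y Phenotype vector aligned with `geno$sample_ids`.
#' @param X Covariates (data frame, matrix, or `NULL`).
#' @param grm A `grm` or `NULL` (ordinary least squares limit).
#' @param varcomp An `lmm_fit` from [fit_null_lmm()] on the same data, or
#'   `NULL` to fit it here.
#' @param conditioning_set Character vector of variant ids to condition on.
#' @param trait Trait label stored in the output.
#' @param context Optional [scan_context()] to reuse the rotated genotypes.
#' @return Tibble of association records: trait, chrom, pos, id, a1 (effect
#'   allele = alt), a2, freq (effect-allele frequency in the analyzed
#'   subset), beta, se, t, p, n, flagged (monomorphic or dropped-collinear
#'   conditioning).
#' @export
assoc_scan <- function(geno, y, X = NULL, grm = NULL, varcomp = NULL,
                       conditioning_set = character(), trait = "trait",
                       context = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  n_all <- length(geno$sample_ids)
  if (length(y) != n_all) abort("`y` must align with `geno` samples")
  Xm <- build_design(X, n_all)
  keep <- complete.cases(y, Xm)
  if (is.null(varcomp)) {
    varcomp <- fit_null_lmm(y, X, grm)
  }
  if (!identical(which(varcomp$keep), which(keep))) {
    abort("`varcomp` was fitted on a different sample subset")
  }
  if (is.null(context) || !identical(context$keep, keep)) {
    context <- scan_context(geno, grm, keep)
  }
  yk <- y[keep]
  Xk <- Xm[keep, , drop = FALSE]

  # conditioning variants enter the fixed-effect block
  cond_flagged <- character()
  if (length(conditioning_set)) {
    ci <- match(conditioning_set, geno$variants$id)
    if (anyNA(ci)) abort("unknown variant id in `conditioning_set`")
    C <- geno$dosage[keep, ci, drop = FALSE]
    colnames(C) <- conditioning_set
    Xc <- cbind(Xk, C)
    Xc2 <- suppressWarnings(drop_collinear(Xc, "conditioning set"))
    dropped <- setdiff(colnames(Xc), colnames(Xc2))
    cond_flagged <- intersect(dropped, conditioning_set)
    if (length(cond_flagged)) {
      warn(sprintf("conditioning variant(s) collinear with covariates, dropped: %s",
                   paste(cond_flagged, collapse = ", ")))
    }
    Xk <- Xc2
  } else {
    Xk <- drop_collinear(Xk, "covariates")
  }

  if (is.null(context$U)) {
    Yt <- matrix(yk, ncol = 1); Xt <- Xk; w <- rep(1, sum(keep))
  } else {
    Yt <- crossprod(context$U, yk)
    Xt <- crossprod(context$U, Xk)
    gamma <- if (varcomp$sigma_e2 > 0) varcomp$sigma_g2 / varcomp$sigma_e2 else 0
    w <- 1 / (gamma * context$d + 1)
  }
  res <- gls_pair_scan(context$Wt, Yt, Xt, w)
  tv <- as.numeric(res$t)
  out <- tibble(
    trait = trait,
    chrom = context$variants$chrom,
    pos = context$variants$pos,
    id = context$variants$id,
    a1 = context$variants$alt,
    a2 = context$variants$ref,
    freq = context$freq,
    beta = as.numeric(res$beta),
    se = as.numeric(res$se),
    t = tv,
    p = 2 * pnorm(-abs(tv)),
    n = sum(keep),
    flagged = res$mono
  )
  # a variant conditioned on is collinear with itself: flag it
  if (length(conditioning_set)) {
    sel <- out$id %in% setdiff(conditioning_set, cond_flagged)
    out$flagged[sel] <- TRUE
  }
  out
}

#' Closed-form false discovery rate from significance counts
#'
#' FDR = P (1 - A/T) / ((A/T) (1 - P)), where P is the p-value threshold
#' tested, A the number of variants significant at P, and T the number of
#' variants tested. Capped at 1; A = 0 returns 1 by convention (logged).
#'
#' @param p_threshold Significance threshold P, in (0, 1).
#' @param n_significant Count A of significant variants, 0 <= A <= T.
#' @param n_tested Count T of tested variants, T >= 1.
#' @return FDR value in [0, 1] at full precision (truncate only for
#'   reporting, e.g. with [truncate_decimals()]).
#' @export
#' @examples
#' fdr_from_counts(5e-8, 3, 31140417)        # 0.519..., prints as 0.51
#' fdr_from_counts(0.002, 11, 225)           # 0.03898..., prints as 3.8%
fdr_from_counts <- function(p_threshold, n_significant, n_tested) {
  if (n_tested < 1) abort("`n_tested` must be at least 1")
  assert_prob(p_threshold, "p_threshold", lo_open = TRUE, hi_open = TRUE)
  if (n_significant < 0 || n_significant > n_tested) {
    abort("`n_significant` must lie in [0, n_tested]")
  }
  if (n_significant == 0) {
    inform("no significant variants; FDR reported as 1 by convention")
    return(1)
  }
  rate <- n_significant / n_tested
  min(1, p_threshold * (1 - rate) / (rate * (1 - p_threshold)))
}
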