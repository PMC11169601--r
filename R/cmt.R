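# Conditional multi-trait GWAS: the k-df chi-squared pleiotropy statistic on
# signed t-values, and the cyclic stepwise LD-aware selection of independent
# putative causal variants.

#' Squared LD correlation between two variants
#'
#' Squared Pearson correlation of the dosage vectors over samples
#' non-missing at both variants.
#'
#' @param geno A `geno_matrix`.
#' @param variant_i,variant_j Variant ids (or column indices).
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(geno, variant_i, variant_j) {
  stopifnot(inherits(geno, "geno_matrix"))
  ix <- if (is.character(variant_i)) match(variant_i, geno$variants$id) else variant_i
  jx <- if (is.character(variant_j)) match(variant_j, geno$variants$id) else variant_j
  if (anyNA(c(ix, jx))) abort("unknown variant id")
  x <- geno$dosage[, ix]
  y <- geno$dosage[, jx]
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("monomorphic variant in ld_r2()")
  }
  cor(x[ok], y[ok])^2
}

# r^2 of each column in `ids` against each column in `against`
ld_r2_block <- function(geno, ids, against) {
  ii <- match(ids, geno$variants$id)
  jj <- match(against, geno$variants$id)
  r <- suppressWarnings(cor(geno$dosage[, ii, drop = FALSE],
                            geno$dosage[, jj, drop = FALSE],
                            use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r^2
}

#' Correlation matrix of signed t-values across traits
#'
#' Entry (a, b) is the Pearson correlation, across all scanned variants, of
#' the signed t-values of traits a and b; this is the V matrix inverted by
#' the multi-trait chi-squared statistic. Under the null it approximates the
#' phenotypic correlation of the traits on shared samples. The diagonal is
#' forced to 1 and the matrix is ridge-regularized towards the identity if
#' numerically non-positive-definite (logged).
#'
#' @param stats Long summary-statistics tibble with columns `trait`, `id`,
#'   `t` (as produced by [assoc_scan()] row-bound across traits).
#' @return k x k correlation matrix with trait dimnames.
#' @export
compute_v_matrix <- function(stats) {
  wide <- tidyr::pivot_wider(dplyr::select(stats, "id", "trait", "t"),
                             names_from = "trait", values_from = "t")
  traits <- setdiff(names(wide), "id")
  if (length(traits) < 2) abort("need at least 2 traits to form V")
  tm <- as.matrix(wide[traits])
  tm <- tm[complete.cases(tm), , drop = FALSE]
  if (nrow(tm) < 2) abort("fewer than 2 shared variants across traits")
  if (nrow(tm) < 100) {
    warn(sprintf("V estimated from only %d shared variants", nrow(tm)))
  }
  V <- cor(tm)
  diag(V) <- 1
  eps <- 0
  while (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    eps <- max(eps * 10, 1e-6)
    V <- (1 - eps) * V + eps * diag(ncol(V))
    inform(sprintf("V regularized towards identity (eps = %g)", eps))
    if (eps >= 0.1) abort("V matrix remains singular after regularization")
  }
  dimnames(V) <- list(traits, traits)
  V
}

#' Multi-trait chi-squared pleiotropy statistic
#'
#' X^2 = t' V^{-1} t with k degrees of freedom (k = number of traits),
#' computed through a Cholesky solve (no explicit inverse). p is the
#' chi-squared upper tail.
#'
#' @param t_vec Signed t-values: a length-k vector (one variant) or an
#'   m x k matrix (variants in rows, traits in columns, matching V's order).
#' @param v The k x k signed-t correlation matrix from [compute_v_matrix()].
#' @param ids Optional variant ids for the output.
#' @return Tibble with columns id (if given), chi2, df, p.
#' @export
#' @examples
#' multi_trait_chi2(c(2, 0, 0, 0), diag(4))  # chi2 = 4
multi_trait_chi2 <- function(t_vec, v, ids = NULL) {
  Tm <- if (is.matrix(t_vec)) t_vec else matrix(t_vec, nrow = 1)
  if (ncol(Tm) != ncol(v)) abort("t_vec length must equal the V dimension")
  if (any(!is.finite(Tm))) abort("t values must be finite")
  R <- tryCatch(chol(v), error = function(e) abort("V matrix is singular"))
  A <- forwardsolve(t(R), t(Tm))
  chi2 <- colSums(A^2)
  k <- ncol(v)
  out <- tibble(chi2 = chi2, df = k,
                p = pchisq(chi2, df = k, lower.tail = FALSE))
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble(id = ids), out)
  out
}

#' Stepwise conditional multi-trait selection of putative causal variants
#'
#' Cycles between single-trait mixed-model scans (conditioning on the
#' current causal set) and the multi-trait chi-squared statistic. Within each
#' cycle, per chromosome, the most significant multi-trait variant with
#' p below `p_threshold` is selected; every other significant variant on the
#' same chromosome with LD r^2 above `r2_max` to a selected variant is set
#' aside as tagging the same QTL; selection repeats until no significant
#' variant remains in the cycle. The signed-t correlation matrix V is
#' estimated once from the unconditional scans and held fixed across cycles.
#' Stops when a cycle selects nothing or `max_cycles` is reached.
#'
#' @param geno A `geno_matrix`.
#' @param traits Trait table (tibble with `sample_id`, trait columns and
#'   covariate columns), aligned with `geno` samples.
#' @param grm A `grm` (or `NULL` for the fixed-effects path).
#' @param trait_cols Names of the trait columns.
#' @param covar_cols Names of covariate columns (default: every column that
#'   is neither `sample_id` nor a trait).
#' @param p_threshold Multi-trait significance threshold for selection
#'   (default 5e-6).
#' @param r2_max LD clumping threshold (default 0.1).
#' @param max_cycles Safety cap on cycles (default 10).
#' @return List: `causal_set` (tibble: cycle, chrom, pos, id, p at
#'   selection), `sumstats` (final conditional single-trait stats, long),
#'   `mgwas` (final multi-trait records), `v` (the V matrix), `n_cycles`.
#' @export
stepwise_conditional_selection <- function(geno, traits, grm = NULL,
                                           trait_cols,
                                           covar_cols = NULL,
                                           p_threshold = 5e-6,
                                           r2_max = 0.1,
                                           max_cycles = 10) {
  stopifnot(inherits(geno, "geno_matrix"))
  traits <- as_tibble(traits)
  if (!identical(traits$sample_id, geno$sample_ids)) {
    abort("`traits` must be aligned with `geno` samples (same order)")
  }
  covar_cols <- covar_cols %||% setdiff(names(traits), c("sample_id", trait_cols))
  X <- if (length(covar_cols)) traits[covar_cols] else NULL

  # null fits and the shared rotation are computed once per trait
  fits <- lapply(trait_cols, function(tc) fit_null_lmm(traits[[tc]], X, grm))
  names(fits) <- trait_cols
  contexts <- list()
  ctx_for <- function(keep) {
    key <- paste(which(!keep), collapse = ",")
    if (is.null(contexts[[key]])) {
      contexts[[key]] <<- scan_context(geno, grm, keep)
    }
    contexts[[key]]
  }

  scan_all <- function(cond) {
    purrr::map_dfr(trait_cols, function(tc) {
      fit <- fits[[tc]]
      assoc_scan(geno, traits[[tc]], X, grm, varcomp = fit,
                 conditioning_set = cond, trait = tc,
                 context = ctx_for(fit$keep))
    })
  }
  run_mgwas <- function(stats) {
    wide <- tidyr::pivot_wider(dplyr::select(stats, "id", "trait", "t"),
                               names_from = "trait", values_from = "t")
    tm <- as.matrix(wide[trait_cols])
    multi_trait_chi2(tm, V, ids = wide$id)
  }

  stats0 <- scan_all(character())
  V <- compute_v_matrix(stats0)

  causal <- tibble(cycle = integer(), chrom = character(),
                   pos = integer(), id = character(), p = numeric())
  stats_now <- stats0
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    if (cycle > 1L) stats_now <- scan_all(causal$id)
    mg <- run_mgwas(stats_now)
    flagged <- stats_now |>
      dplyr::filter(.data$flagged) |>
      dplyr::pull(.data$id) |>
      unique()
    cand <- mg |>
      dplyr::filter(.data$p < p_threshold,
                    !.data$id %in% causal$id,
                    !.data$id %in% flagged) |>
      dplyr::left_join(dplyr::select(geno$variants, "id", "chrom", "pos"),
                       by = "id") |>
      dplyr::arrange(.data$p, as_chrom_order(.data$chrom), .data$pos)
    picked <- character()
    for (chr in unique(cand$chrom)) {
      pool <- cand[cand$chrom == chr, ]
      members <- causal$id[causal$chrom == chr]
      while (nrow(pool)) {
        top <- pool[1, ]
        pool <- pool[-1, , drop = FALSE]
        if (length(members)) {
          r2 <- ld_r2_block(geno, top$id, members)
          if (any(r2 > r2_max)) next  # tags an already-selected QTL
        }
        picked <- c(picked, top$id)
        causal <- dplyr::bind_rows(causal, tibble(
          cycle = cycle, chrom = top$chrom, pos = top$pos,
          id = top$id, p = top$p))
        members <- c(members, top$id)
        if (nrow(pool)) {
          r2 <- ld_r2_block(geno, pool$id, top$id)
          pool <- pool[r2[, 1] <= r2_max, , drop = FALSE]
        }
      }
    }
    if (!length(picked) || cycle >= max_cycles) {
      mg_final <- mg
      stats_final <- stats_now
      break
    }
  }

  # invariant: same-chromosome pairwise r^2 among members <= r2_max
  for (chr in unique(causal$chrom)) {
    ids <- causal$id[causal$chrom == chr]
    if (length(ids) > 1) {
      r2 <- ld_r2_block(geno, ids, ids)
      diag(r2) <- 0
      stopifnot(all(r2 <= r2_max + 1e-12))
    }
  }

  list(causal_set = causal, sumstats = stats_final, mgwas = mg_final,
       v = V, n_cycles = cycle)
}
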