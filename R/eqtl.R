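# cis/trans eQTL mapping with the mixed-model engine, the two-step
# hierarchical Bonferroni correction, trans test-set construction,
# split-half reproducibility, and TSS-distance profiling.

# per-gene scan against a set of rotated variant columns
scan_gene <- function(ctx, cols, yt, Xt, d, use_reml) {
  if (use_reml) {
    prof <- reml_profile(yt, Xt, d)
    w <- 1 / (prof$gamma * d + 1)
  } else {
    w <- rep(1, length(yt))
  }
  gls_pair_scan(ctx$Wt[, cols, drop = FALSE], matrix(yt, ncol = 1), Xt, w)
}

# assemble the fixed-effects design for the expression model
eqtl_design <- function(expr, q_pcs, covar_cols) {
  covar_cols <- intersect(covar_cols, names(expr$samples))
  X <- if (length(covar_cols)) as.data.frame(expr$samples[covar_cols]) else NULL
  Xm <- build_design(X, nrow(expr$samples))
  if (q_pcs > 0) {
    if (is.null(expr$log_cpm)) abort("run cpm_filter() first to attach log-CPM")
    Xm <- cbind(Xm, expression_pcs(expr$log_cpm, q_pcs))
  }
  drop_collinear(Xm, "expression covariates")
}

eqtl_scan_records <- function(expr, geno, grm, pairs_for_gene, scope,
                              q_pcs, covar_cols, maf_min) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(geno, "geno_matrix"))
  if (is.null(expr$log_cpm)) {
    expr$log_cpm <- edgeR::cpm(expr$counts, lib.size = expr$lib_size, log = TRUE)
  }
  geno <- subset_geno(geno, expr$samples$sample_id)
  keep_v <- which(fold_maf(colMeans(geno$dosage) / 2) >= maf_min)
  geno <- subset_geno(geno, variants = keep_v)
  grm <- subset_grm(grm, expr$samples$sample_id)
  Xm <- eqtl_design(expr, q_pcs, covar_cols)
  ctx <- scan_context(geno, grm)
  n <- nrow(Xm)
  if (is.null(ctx$U)) {
    Xt <- Xm
    rot <- function(y) y
    d <- NULL
  } else {
    Xt <- crossprod(ctx$U, Xm)
    rot <- function(y) drop(crossprod(ctx$U, y))
    d <- ctx$d
  }
  ann <- expr$annotation
  v <- geno$variants
  cols_list <- lapply(seq_len(nrow(ann)), function(g) pairs_for_gene(ann[g, ], v))
  skipped <- sum(lengths(cols_list) == 0)
  if (skipped > 0) {
    inform(sprintf("%d gene(s) had no testable variants (%s scan)", skipped, scope))
  }

  assemble <- function(gidx, vidx, beta, se, tval) {
    sgn <- ifelse(ann$strand[gidx] == "-", -1L, 1L)
    tibble(
      gene_id = ann$gene_id[gidx],
      chrom = v$chrom[vidx], pos = v$pos[vidx], id = v$id[vidx],
      a1 = v$alt[vidx], a2 = v$ref[vidx], freq = ctx$freq[vidx],
      beta = beta, se = se, t = tval,
      p = 2 * pnorm(-abs(tval)),
      tss_distance = sgn * (v$pos[vidx] - ann$tss[gidx]),
      scope = scope, n = n
    )
  }

  if (is.null(d)) {
    # shared weights: every (variant, gene) pair from three cross-products,
    # gene-chunked to bound the pair-matrix size
    m <- ncol(ctx$Wt)
    chunk <- max(1L, ceiling(1e7 / m))
    gene_sets <- split(seq_len(nrow(ann)),
                       ceiling(seq_len(nrow(ann)) / chunk))
    recs <- lapply(gene_sets, function(gs) {
      gs <- gs[lengths(cols_list[gs]) > 0]
      if (!length(gs)) return(NULL)
      Yt <- t(expr$log_cpm[gs, , drop = FALSE])
      res <- gls_pair_scan(ctx$Wt, Yt, Xt, rep(1, n))
      gcol <- rep(seq_along(gs), lengths(cols_list[gs]))
      vidx <- unlist(cols_list[gs], use.names = FALSE)
      flat <- cbind(vidx, gcol)
      assemble(gs[gcol], vidx, res$beta[flat], res$se[flat], res$t[flat])
    })
    return(dplyr::bind_rows(recs))
  }

  recs <- vector("list", nrow(ann))
  for (g in seq_len(nrow(ann))) {
    cols <- cols_list[[g]]
    if (!length(cols)) next
    yt <- rot(expr$log_cpm[g, ])
    res <- scan_gene(ctx, cols, yt, Xt, d, use_reml = TRUE)
    recs[[g]] <- assemble(rep(g, length(cols)), cols,
                          as.numeric(res$beta), as.numeric(res$se),
                          as.numeric(res$t))
  }
  dplyr::bind_rows(recs)
}

#' Map cis eQTLs with a mixed linear model
#'
#' For each gene, every variant within `window_bp` of the annotated TSS on
#' the gene's chromosome (closed window: a variant at exactly TSS +/-
#' `window_bp` is included) is tested against log-CPM expression. Fixed
#' effects are the sample covariates plus the first `q_pcs` expression PCs;
#' the polygenic random effect uses the GRM, with per-gene variance
#' components estimated by REML under the null and held fixed across
#' variants. Variants below `maf_min` folded MAF are excluded first.
#'
#' @param expr A CPM-filtered `expr_matrix` (see [cpm_filter()]).
#' @param geno A `geno_matrix` containing the expression samples.
#' @param grm A `grm`, or `NULL` for the fixed-effects model.
#' @param window_bp cis window half-width around the TSS (default 2 Mb).
#' @param q_pcs Number of expression PCs as covariates (default 4).
#' @param covar_cols Sample covariate columns used as fixed effects.
#' @param maf_min Folded-MAF filter for tested variants (default 0.05).
#' @return Tibble of eQTL records: gene_id, chrom, pos, id, a1, a2, freq,
#'   beta, se, t, p, tss_distance (signed, strand-oriented), scope, n.
#' @export
map_cis_eqtl <- function(expr, geno, grm = NULL, window_bp = 2e6,
                         q_pcs = 4,
                         covar_cols = c("contemporary_group", "lactation",
                                        "weeks_pregnant"),
                         maf_min = 0.05) {
  pairs_for_gene <- function(gene, v) {
    which(v$chrom == gene$chrom & abs(v$pos - gene$tss) <= window_bp)
  }
  eqtl_scan_records(expr, geno, grm, pairs_for_gene, "cis",
                    q_pcs, covar_cols, maf_min)
}

#' Two-step hierarchical multiple-testing correction and eGene calling
#'
#' Step 1 (local): within each gene, p-values are Bonferroni-adjusted for
#' the number of variants tested for that gene, p_local = min(1, p * m_g).
#' Step 2 (global): a gene is an eGene iff its minimum p_local, multiplied
#' by the number of genes tested, is below `alpha`; its significant eQTLs
#' are the variants with p_local * n_genes_tested < alpha. The lead eQTL is
#' the smallest-p record (ties: smallest |tss_distance|, then lowest
#' position). Output labels call the Step-2 quantity global FDR, as is
#' conventional, though the procedure is Bonferroni-style.
#'
#' @param records eQTL record tibble from [map_cis_eqtl()] /
#'   [map_trans_eqtl()].
#' @param n_genes_tested Number of genes entering the scan (>= the distinct
#'   genes in `records`).
#' @param alpha eGene threshold on the globally adjusted p (default 0.01).
#' @return An `egene_set`: list with `egenes` (one row per eGene: lead
#'   record columns, p_local, p_global, n_eqtls), `eqtls` (significant
#'   records with `lead` flag), `n_genes_tested`, `alpha`.
#' @export
hierarchical_correction <- function(records, n_genes_tested, alpha = 0.01) {
  n_distinct <- dplyr::n_distinct(records$gene_id)
  if (n_genes_tested < n_distinct) {
    abort("`n_genes_tested` is smaller than the number of genes in `records`")
  }
  adj <- records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(m_g = dplyr::n(),
                  p_local = pmin(1, .data$p * .data$m_g)) |>
    dplyr::ungroup()
  sig <- adj |>
    dplyr::filter(.data$p_local * n_genes_tested < alpha) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(.data$p, abs(.data$tss_distance), .data$pos,
                   .by_group = TRUE) |>
    dplyr::mutate(lead = dplyr::row_number() == 1L) |>
    dplyr::ungroup()
  egenes <- sig |>
    dplyr::filter(.data$lead) |>
    dplyr::mutate(p_global = pmin(1, .data$p_local * n_genes_tested)) |>
    dplyr::left_join(dplyr::count(sig, .data$gene_id, name = "n_eqtls"),
                     by = "gene_id") |>
    dplyr::arrange(.data$p_global)
  structure(list(egenes = egenes, eqtls = sig,
                 n_genes_tested = n_genes_tested, alpha = alpha),
            class = "egene_set")
}

#' @export
print.egene_set <- function(x, ...) {
  cat("<egene_set> ", nrow(x$egenes), " eGene(s) of ", x$n_genes_tested,
      " genes tested (alpha = ", x$alpha, "); ",
      nrow(x$eqtls), " significant eQTL record(s)\n", sep = "")
  invisible(x)
}

#' Build the trans-eQTL test set of variants
#'
#' Deduplicated union of the lead cis-eQTL of every eGene, the genome-wide
#' significant GWAS variants, and all panel variants within `flank_bp` of
#' any of these seeds.
#'
#' @param egenes An `egene_set` from the cis analysis (or a tibble with an
#'   `id` column of lead variants).
#' @param gwas_hits Character vector of GWAS-significant variant ids.
#' @param geno The `geno_matrix` panel supplying flanking variants.
#' @param flank_bp Flank width in bp (default 100).
#' @return Tibble of selected variants (columns of `geno$variants`).
#' @export
select_trans_test_set <- function(egenes, gwas_hits, geno, flank_bp = 100) {
  stopifnot(inherits(geno, "geno_matrix"))
  lead_ids <- if (inherits(egenes, "egene_set")) egenes$egenes$id
              else if (is.data.frame(egenes)) egenes$id
              else as.character(egenes)
  seeds <- unique(c(lead_ids, gwas_hits))
  v <- geno$variants
  sel <- v$id %in% seeds
  if (flank_bp > 0 && any(sel)) {
    for (chr in unique(v$chrom[sel])) {
      on_chr <- v$chrom == chr
      spos <- v$pos[sel & on_chr]
      cand <- which(on_chr & !sel)
      if (length(cand) && length(spos)) {
        near <- vapply(v$pos[cand],
                       function(p) any(abs(p - spos) <= flank_bp),
                       logical(1))
        sel[cand[near]] <- TRUE
      }
    }
  }
  v[sel, ]
}

#' Map trans eQTLs for a selected variant test set
#'
#' Tests each (variant, gene) pair where the variant lies on the gene's
#' chromosome strictly more than `min_distance_bp` from the TSS (so the
#' association cannot tag a cis effect), using the same mixed model as the
#' cis scan. The hierarchical correction uses, per gene, the number of
#' test-set variants actually tested for that gene.
#'
#' @inheritParams map_cis_eqtl
#' @param test_set Variant tibble from [select_trans_test_set()] (or ids).
#' @param min_distance_bp Minimum TSS distance (default 5 Mb, strict).
#' @param alpha eGene threshold passed to [hierarchical_correction()].
#' @return List: `records` (all tested pairs, scope "trans") and `egenes`
#'   (an `egene_set` over the genes with at least one tested pair).
#' @export
map_trans_eqtl <- function(test_set, expr, geno, grm = NULL,
                           min_distance_bp = 5e6, q_pcs = 4,
                           covar_cols = c("contemporary_group", "lactation",
                                          "weeks_pregnant"),
                           maf_min = 0.05, alpha = 0.01) {
  ids <- if (is.data.frame(test_set)) test_set$id else as.character(test_set)
  if (!length(ids)) abort("`test_set` is empty")
  pairs_for_gene <- function(gene, v) {
    which(v$id %in% ids & v$chrom == gene$chrom &
            abs(v$pos - gene$tss) > min_distance_bp)
  }
  records <- eqtl_scan_records(expr, geno, grm, pairs_for_gene, "trans",
                               q_pcs, covar_cols, maf_min)
  if (!nrow(records)) {
    return(list(records = records, egenes = NULL))
  }
  egenes <- hierarchical_correction(
    records, n_genes_tested = dplyr::n_distinct(records$gene_id),
    alpha = alpha)
  list(records = records, egenes = egenes)
}

#' Split-half reproducibility of the cis-eQTL analysis
#'
#' Randomly halves the expression cohort, runs the full cis pipeline in each
#' half, and reports the proportion of half-1 eGenes recovered in half-2 and
#' vice versa, plus the Pearson correlation of half-1 lead-eQTL effect sizes
#' with the same (gene, variant) effects estimated in half-2.
#'
#' @inheritParams map_cis_eqtl
#' @param seed Integer seed controlling the split.
#' @param alpha eGene threshold.
#' @return One-row tibble: n_egenes_1, n_egenes_2, prop_1in2, prop_2in1,
#'   lead_effect_correlation. Proportions are NA when a half finds no
#'   eGenes.
#' @export
split_half_reproducibility <- function(expr, geno, grm = NULL, seed = 1,
                                       window_bp = 2e6, q_pcs = 4,
                                       covar_cols = c("contemporary_group",
                                                      "lactation",
                                                      "weeks_pregnant"),
                                       maf_min = 0.05, alpha = 0.01) {
  n <- nrow(expr$samples)
  if (n < 40) abort("need at least 40 samples for a split-half analysis")
  halves <- withr::with_seed(seed, sample(rep(1:2, length.out = n)))
  run_half <- function(h) {
    idx <- which(halves == h)
    sub <- new_expr_matrix(expr$counts[, idx, drop = FALSE],
                           expr$annotation, expr$samples[idx, ])
    sub$lib_size <- expr$lib_size[idx]
    sub$log_cpm <- edgeR::cpm(sub$counts, lib.size = sub$lib_size, log = TRUE)
    rec <- map_cis_eqtl(sub, geno, grm, window_bp = window_bp,
                        q_pcs = q_pcs, covar_cols = covar_cols,
                        maf_min = maf_min)
    list(records = rec,
         egenes = hierarchical_correction(rec, nrow(expr$annotation), alpha))
  }
  h1 <- run_half(1)
  h2 <- run_half(2)
  e1 <- h1$egenes$egenes
  e2 <- h2$egenes$egenes
  prop_1in2 <- if (nrow(e1)) mean(e1$gene_id %in% e2$gene_id) else NA_real_
  prop_2in1 <- if (nrow(e2)) mean(e2$gene_id %in% e1$gene_id) else NA_real_
  matched <- dplyr::inner_join(
    dplyr::select(e1, "gene_id", "id", beta1 = "beta"),
    dplyr::select(h2$records, "gene_id", "id", beta2 = "beta"),
    by = c("gene_id", "id"))
  lead_cor <- if (nrow(matched) >= 3) cor(matched$beta1, matched$beta2)
              else NA_real_
  tibble(n_egenes_1 = nrow(e1), n_egenes_2 = nrow(e2),
         prop_1in2 = prop_1in2, prop_2in1 = prop_2in1,
         lead_effect_correlation = lead_cor)
}

#' TSS-distance profile of lead eQTLs
#'
#' Bins the absolute TSS distance of lead eQTLs and reports counts and
#' proportions, plus the fraction of leads lying within their gene body
#' when annotation is supplied.
#'
#' @param egenes An `egene_set` (or a tibble of lead records with
#'   `tss_distance` and `pos`).
#' @param breaks Increasing bin edges in bp; distances beyond the last edge
#'   fall in an overflow bin.
#' @param annotation Optional gene annotation for the gene-body fraction.
#' @return List: `bins` tibble (bin, n, proportion) and `gene_body_fraction`
#'   (NA without annotation).
#' @export
tss_distance_profile <- function(egenes,
                                 breaks = c(0, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6),
                                 annotation = NULL) {
  leads <- if (inherits(egenes, "egene_set")) egenes$egenes else egenes
  if (!nrow(leads)) abort("no lead eQTLs to profile")
  d <- abs(leads$tss_distance)
  edges <- unique(c(breaks, Inf))
  binned <- cut(d, edges, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(binned))
  bins <- tibble(bin = levels(binned), n = counts,
                 proportion = counts / sum(counts))
  gbf <- NA_real_
  if (!is.null(annotation)) {
    ann <- annotation[match(leads$gene_id, annotation$gene_id), ]
    gbf <- mean(leads$pos >= ann$start & leads$pos <= ann$end)
  }
  list(bins = bins, gene_body_fraction = gbf)
}
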