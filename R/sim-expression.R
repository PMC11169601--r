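#' Simulate expression counts with planted cis and trans effects
#'
#' Gene counts follow a negative-binomial model whose log-mean combines a
#' gene baseline, planted genetic effects (cis: regulating variant within
#' +/- 2 Mb of the TSS; trans: > 5 Mb away on the same chromosome), latent
#' batch factors, Gaussian log-scale biological noise, and library-size
#' variation. Sample covariates (contemporary group, lactation status, weeks
#' pregnant) are generated with small effects so the eQTL model has real
#' nuisance structure to remove.
#'
#' @param geno A `geno_matrix`; its samples become the expression panel.
#' @param config The [sim_config()] used to generate `geno`.
#' @param cis_window_bp Window defining eligible cis regulators (default 2 Mb).
#' @param trans_min_bp Minimum TSS distance for trans regulators (default 5 Mb).
#' @param effects Optional tibble (`gene_id`, `id`, `scope`, `beta`) planting
#'   exact regulator effects (log-expression units per allele) instead of the
#'   random architecture; gene ids refer to the generated annotation
#'   (G0001..), variant ids to `geno`.
#' @return List with `expr` (an `expr_matrix`: counts, annotation, samples,
#'   library sizes) and `truth` (a `sim_truth` with an `egene_truth` tibble:
#'   gene_id, id, scope, beta).
#' @export
simulate_expression <- function(geno, config,
                                cis_window_bp = 2e6, trans_min_bp = 5e6,
                                effects = NULL) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(config, "sim_config"))
  assert_prob(config$prop_egenes, "prop_egenes")
  n <- length(geno$sample_ids)
  withr::with_seed(sub_seed(config$seed, 3L), {
    ngene <- config$n_genes
    chroms <- unique(geno$variants$chrom)
    chrom_len <- config$chrom_length_bp

    gene_chrom <- sample(chroms, ngene, replace = TRUE)
    tss <- as.integer(runif(ngene, 1, chrom_len))
    strand <- sample(c("+", "-"), ngene, replace = TRUE)
    glen <- pmin(as.integer(rexp(ngene, 1 / 30000)) + 1000L, 500000L)
    start <- ifelse(strand == "+", tss, pmax(1L, tss - glen))
    end <- ifelse(strand == "+", pmin(chrom_len, tss + glen), tss)
    annotation <- tibble(
      gene_id = sprintf("G%04d", seq_len(ngene)),
      chrom = gene_chrom, tss = tss, strand = strand,
      start = as.integer(start), end = as.integer(end)
    )

    # planted regulators
    pick_regulator <- function(g, lo_off, hi_off, min_dist = 0) {
      v <- geno$variants
      d <- abs(v$pos - annotation$tss[g])
      ok <- v$chrom == annotation$chrom[g] & d >= lo_off & d <= hi_off &
        d > min_dist & v$maf > 0.05
      if (!any(ok)) return(NA_integer_)
      sample(which(ok), 1)
    }
    if (is.null(effects)) {
      n_eg <- round(config$prop_egenes * ngene)
      cis_genes <- if (n_eg > 0) sort(sample.int(ngene, n_eg)) else integer()
      cis_idx <- vapply(cis_genes, pick_regulator, integer(1),
                        lo_off = 0, hi_off = cis_window_bp)
      keep <- !is.na(cis_idx)
      cis_genes <- cis_genes[keep]; cis_idx <- cis_idx[keep]
      cis_beta <- rnorm(length(cis_genes), 0, config$cis_effect_sd)

      n_tr <- min(config$n_trans_genes, ngene)
      trans_genes <- if (n_tr > 0) sample.int(ngene, n_tr) else integer()
      trans_idx <- vapply(trans_genes, pick_regulator, integer(1),
                          lo_off = trans_min_bp + 1, hi_off = Inf)
      keep <- !is.na(trans_idx)
      trans_genes <- trans_genes[keep]; trans_idx <- trans_idx[keep]
      trans_beta <- rnorm(length(trans_genes), 0, config$trans_effect_sd)
    } else {
      effects <- as_tibble(effects)
      stopifnot(all(c("gene_id", "id", "scope", "beta") %in% names(effects)))
      gidx <- match(effects$gene_id, annotation$gene_id)
      vidx <- match(effects$id, geno$variants$id)
      if (anyNA(gidx) || anyNA(vidx)) {
        abort("`effects` references unknown gene or variant ids")
      }
      is_cis <- effects$scope == "cis"
      dist <- abs(geno$variants$pos[vidx] - annotation$tss[gidx])
      same_chr <- geno$variants$chrom[vidx] == annotation$chrom[gidx]
      if (any(is_cis & (!same_chr | dist > cis_window_bp)) ||
          any(!is_cis & (!same_chr | dist <= trans_min_bp))) {
        abort("`effects` violates the cis-window / trans-distance constraints")
      }
      cis_genes <- gidx[is_cis]; cis_idx <- vidx[is_cis]
      cis_beta <- effects$beta[is_cis]
      trans_genes <- gidx[!is_cis]; trans_idx <- vidx[!is_cis]
      trans_beta <- effects$beta[!is_cis]
    }

    # sample covariates and batch factors
    samples <- tibble(
      sample_id = geno$sample_ids,
      contemporary_group = sample(sprintf("cg%d", 1:7), n, replace = TRUE),
      lactation = sample(c(0, 1), n, replace = TRUE, prob = c(0.7, 0.3)),
      weeks_pregnant = pmax(0, round(rnorm(n, 10, 8)))
    )
    batch <- matrix(rnorm(n * config$n_batch_factors), n)
    load <- matrix(rnorm(ngene * config$n_batch_factors, 0, 0.3), ngene)

    base <- rnorm(ngene, 4.5, 1.5)               # log mean counts
    lib <- exp(rnorm(n, 0, 0.25))                # library-size factors
    cg_eff <- setNames(rnorm(7, 0, 0.2), sprintf("cg%d", 1:7))

    logmu <- matrix(base, ngene, n) +
      load %*% t(batch) +
      matrix(rnorm(ngene * n, 0, config$expr_noise_sd), ngene) +
      rep(log(lib) + cg_eff[samples$contemporary_group] +
            0.1 * samples$lactation + 0.005 * samples$weeks_pregnant,
          each = ngene)
    if (length(cis_genes)) {
      logmu[cis_genes, ] <- logmu[cis_genes, ] +
        matrix(cis_beta, length(cis_genes), n) *
        t(geno$dosage[, cis_idx, drop = FALSE])
    }
    if (length(trans_genes)) {
      logmu[trans_genes, ] <- logmu[trans_genes, ] +
        matrix(trans_beta, length(trans_genes), n) *
        t(geno$dosage[, trans_idx, drop = FALSE])
    }

    disp <- rgamma(ngene, shape = 2, rate = 2 / config$nb_dispersion)
    counts <- matrix(rnbinom(ngene * n, mu = pmin(exp(logmu), 1e7),
                             size = 1 / pmax(disp, 1e-8)),
                     ngene, n,
                     dimnames = list(annotation$gene_id, geno$sample_ids))

    truth <- structure(
      list(egene_truth = dplyr::bind_rows(
        tibble(gene_id = annotation$gene_id[cis_genes],
               id = geno$variants$id[cis_idx], scope = "cis", beta = cis_beta),
        tibble(gene_id = annotation$gene_id[trans_genes],
               id = geno$variants$id[trans_idx], scope = "trans",
               beta = trans_beta)
      )),
      class = "sim_truth")
    list(expr = new_expr_matrix(counts, annotation, samples), truth = truth)
  })
}

new_expr_matrix <- function(counts, annotation, samples) {
  stopifnot(nrow(counts) == nrow(annotation),
            ncol(counts) == nrow(samples),
            all(counts >= 0), all(annotation$start <= annotation$end))
  structure(list(counts = counts, annotation = annotation,
                 samples = samples,
                 lib_size = colSums(counts)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples (median library size ",
      format(median(x$lib_size), big.mark = ","), ")\n", sep = "")
  invisible(x)
}
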