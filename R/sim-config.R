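#' Configuration for the synthetic-data generator
#'
#' Builds a validated configuration describing a synthetic study: a genotyped
#' herd with block-LD haplotypes, four correlated fertility traits (one
#' binarised through a liability threshold, emulating pregnancy status), and a
#' whole-blood expression panel with planted cis and trans effects. The
#' defaults describe the bundled demo design: 500 animals, 5 chromosomes of
#' 2,000 variants each, 300 genes.
#'
#' @param n_samples Number of individuals.
#' @param n_chromosomes Number of autosomes to simulate.
#' @param variants_per_chrom Variants per chromosome.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param maf_range Length-2 vector, target allele-frequency range in (0, 0.5].
#' @param ld_rho Adjacent-haplotype allele correlation in [0, 1). Haplotypes
#'   follow a first-order Markov chain: each allele is copied from the
#'   previous site with probability `ld_rho`, else drawn fresh.
#' @param n_traits Number of traits (default 4: dtc, afc, preg_st, wks_preg).
#' @param n_causal_shared Number of pleiotropic causal variants shared by all
#'   traits.
#' @param n_causal_private Causal variants private to each trait.
#' @param h2 Per-trait narrow-sense heritability in [0, 1); recycled to
#'   `n_traits`.
#' @param prop_h2_causal Share of each trait's genetic variance carried by the
#'   planted causal variants (the rest is GRM polygenic background).
#' @param residual_corr Residual correlation across traits: either a single
#'   exchangeable correlation or a full k x k positive-definite matrix.
#' @param liability_trait Index of the trait binarised on the liability scale
#'   (default 3, the pregnancy-status slot).
#' @param liability_threshold Quantile of the latent liability below which the
#'   binary trait is 0 (default 0.3, i.e. 70% success rate).
#' @param missing_prop Per-trait fraction of phenotypes set missing at random.
#' @param n_genes Number of expressed genes.
#' @param prop_egenes Fraction of genes given a planted cis effect.
#' @param n_trans_genes Number of genes additionally given a planted trans
#'   effect (variant > 5 Mb away on the same chromosome).
#' @param cis_effect_sd,trans_effect_sd Scale (log-expression units per allele)
#'   of planted cis/trans effect sizes.
#' @param expr_noise_sd Gaussian log-scale biological noise SD for expression.
#' @param nb_dispersion Mean negative-binomial dispersion of counts.
#' @param n_batch_factors Latent batch factors loading on expression.
#' @param seed Integer seed; all generator sub-streams derive from it.
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 50, n_chromosomes = 2, variants_per_chrom = 100)
#' cfg$n_traits
sim_config <- function(n_samples = 500,
                       n_chromosomes = 5,
                       variants_per_chrom = 2000,
                       chrom_length_bp = 5e7,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.9,
                       n_traits = 4,
                       n_causal_shared = 3,
                       n_causal_private = 2,
                       h2 = 0.3,
                       prop_h2_causal = 0.2,
                       residual_corr = 0.5,
                       liability_trait = 3,
                       liability_threshold = 0.3,
                       missing_prop = 0,
                       n_genes = 300,
                       prop_egenes = 0.4,
                       n_trans_genes = 15,
                       cis_effect_sd = 0.6,
                       trans_effect_sd = 0.4,
                       expr_noise_sd = 0.5,
                       nb_dispersion = 0.05,
                       n_batch_factors = 2,
                       seed = 1L) {
  for (nm in c("n_samples", "n_chromosomes", "variants_per_chrom",
               "chrom_length_bp", "n_traits", "n_genes")) {
    assert_count(get(nm), nm)
  }
  if (n_causal_shared < 0 || n_causal_private < 0) {
    abort("causal variant counts must be non-negative")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5]")
  }
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1) {
    abort("`ld_rho` must lie in [0, 1)")
  }
  h2 <- rep_len(h2, n_traits)
  assert_prob(h2, "h2", hi_open = TRUE)
  assert_prob(prop_h2_causal, "prop_h2_causal")
  assert_prob(prop_egenes, "prop_egenes")
  assert_prob(missing_prop, "missing_prop", hi = 0.9)
  if (is.matrix(residual_corr)) {
    if (nrow(residual_corr) != n_traits || ncol(residual_corr) != n_traits ||
        !isTRUE(all.equal(residual_corr, t(residual_corr))) ||
        any(eigen(residual_corr, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      abort("`residual_corr` matrix must be k x k symmetric positive-definite")
    }
  } else {
    rho <- residual_corr
    if (rho <= -1 / (n_traits - 1) || rho >= 1) {
      abort("exchangeable `residual_corr` out of the positive-definite range")
    }
    residual_corr <- matrix(rho, n_traits, n_traits)
    diag(residual_corr) <- 1
  }
  trait_names <- if (n_traits == 4) {
    c("dtc", "afc", "preg_st", "wks_preg")
  } else {
    paste0("trait", seq_len(n_traits))
  }
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    variants_per_chrom = as.integer(variants_per_chrom),
    chrom_length_bp = as.integer(chrom_length_bp),
    maf_range = maf_range, ld_rho = ld_rho,
    n_traits = as.integer(n_traits), trait_names = trait_names,
    n_causal_shared = as.integer(n_causal_shared),
    n_causal_private = as.integer(n_causal_private),
    h2 = h2, prop_h2_causal = prop_h2_causal,
    residual_corr = residual_corr,
    liability_trait = as.integer(liability_trait),
    liability_threshold = liability_threshold,
    missing_prop = missing_prop,
    n_genes = as.integer(n_genes), prop_egenes = prop_egenes,
    n_trans_genes = as.integer(n_trans_genes),
    cis_effect_sd = cis_effect_sd, trans_effect_sd = trans_effect_sd,
    expr_noise_sd = expr_noise_sd, nb_dispersion = nb_dispersion,
    n_batch_factors = as.integer(n_batch_factors),
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_samples, " samples, ",
      x$n_chromosomes, " x ", x$variants_per_chrom, " variants, ",
      x$n_traits, " traits, ", x$n_genes, " genes (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
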