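# Summary-data-based Mendelian randomisation: lead cis-eQTLs as instruments
# linking gene expression to trait associations.

#' Select SMR instruments from eGenes and GWAS summary statistics
#'
#' For each eGene whose lead eQTL passes `p_eqtl_max`, and for each trait in
#' which that variant's GWAS p-value passes `p_gwas_max`, emits one
#' instrument. Variants are aligned by (chrom, pos) and alleles; when the
#' effect alleles are swapped between the files the GWAS beta sign is
#' flipped; pairs whose alleles cannot be reconciled are skipped with a
#' warning.
#'
#' @param egenes An `egene_set` from [hierarchical_correction()] (or its
#'   `egenes` tibble).
#' @param gwas Long GWAS summary statistics (rows for all traits, columns as
#'   from [assoc_scan()]).
#' @param p_eqtl_max Instrument eQTL p threshold (default 5e-8).
#' @param p_gwas_max Instrument GWAS p threshold (default 5e-3).
#' @return Instrument tibble: gene_id, trait, id, chrom, pos, b_eqtl,
#'   se_eqtl, p_eqtl, b_gwas, se_gwas, p_gwas.
#' @export
select_instruments <- function(egenes, gwas, p_eqtl_max = 5e-8,
                               p_gwas_max = 5e-3) {
  leads <- if (inherits(egenes, "egene_set")) egenes$egenes else egenes
  leads <- dplyr::filter(leads, .data$p < p_eqtl_max)
  if (!nrow(leads)) return(tibble())
  merged <- dplyr::inner_join(
    dplyr::select(leads, "gene_id", "id", "chrom", "pos",
                  e_a1 = "a1", e_a2 = "a2",
                  b_eqtl = "beta", se_eqtl = "se", p_eqtl = "p"),
    dplyr::select(gwas, "trait", "chrom", "pos",
                  g_a1 = "a1", g_a2 = "a2",
                  b_gwas = "beta", se_gwas = "se", p_gwas = "p"),
    by = c("chrom", "pos"), relationship = "many-to-many")
  same <- merged$g_a1 == merged$e_a1 & merged$g_a2 == merged$e_a2
  swapped <- merged$g_a1 == merged$e_a2 & merged$g_a2 == merged$e_a1
  bad <- !(same | swapped)
  if (any(bad)) {
    warn(sprintf("%d (gene, trait) pair(s) skipped: unalignable alleles",
                 sum(bad)))
    merged <- merged[!bad, ]
    same <- same[!bad]; swapped <- swapped[!bad]
  }
  merged$b_gwas[swapped] <- -merged$b_gwas[swapped]
  merged |>
    dplyr::filter(.data$p_gwas < p_gwas_max) |>
    dplyr::transmute(.data$gene_id, .data$trait, .data$id,
                     .data$chrom, .data$pos,
                     .data$b_eqtl, .data$se_eqtl, .data$p_eqtl,
                     .data$b_gwas, .data$se_gwas, .data$p_gwas)
}

#' SMR test for expression-mediated trait associations
#'
#' With z_g = b_gwas/se_gwas and z_e = b_eqtl/se_eqtl, the SMR statistic is
#' t_smr = z_g^2 z_e^2 / (z_g^2 + z_e^2), referred to chi-squared with 1 df;
#' the putative expression-to-trait effect is b_xy = b_gwas / b_eqtl. The
#' statistic is symmetric in (z_g, z_e) and bounded by min(z_g^2, z_e^2).
#'
#' @param instruments Instrument tibble from [select_instruments()] (or any
#'   tibble with b_gwas, se_gwas, b_eqtl, se_eqtl columns).
#' @return The input with b_xy, t_smr, p_smr columns appended.
#' @export
#' @examples
#' smr_test(tibble::tibble(b_gwas = 0.3, se_gwas = 0.1,
#'                         b_eqtl = 0.8, se_eqtl = 0.2))
smr_test <- function(instruments) {
  x <- as_tibble(instruments)
  if (!nrow(x)) return(dplyr::mutate(x, b_xy = numeric(0),
                                     t_smr = numeric(0), p_smr = numeric(0)))
  if (any(x$se_gwas <= 0 | x$se_eqtl <= 0)) abort("standard errors must be positive")
  if (any(x$b_eqtl == 0)) abort("b_eqtl = 0: no instrument strength")
  z_g <- x$b_gwas / x$se_gwas
  z_e <- x$b_eqtl / x$se_eqtl
  t_smr <- (z_g^2 * z_e^2) / (z_g^2 + z_e^2)
  t_smr[z_g == 0] <- 0
  dplyr::mutate(x,
                b_xy = .data$b_gwas / .data$b_eqtl,
                t_smr = t_smr,
                p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE))
}

#' Bonferroni threshold for the SMR gene set
#'
#' @param alpha Family-wise error target (default 0.05).
#' @param n_tests Number of genes tested.
#' @return alpha / n_tests at full precision (reports round to 2 significant
#'   figures, e.g. 0.05/141 prints as 3.5e-4).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  assert_count(n_tests, "n_tests")
  assert_prob(alpha, "alpha", lo_open = TRUE)
  alpha / n_tests
}
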