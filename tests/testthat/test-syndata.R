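test_that("genotype simulation is deterministic and respects dosage bounds", {
  cfg <- sim_config(n_samples = 40, n_chromosomes = 2,
                    variants_per_chrom = 100, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$variants, g2$variants)
  expect_true(all(g1$dosage %in% c(0, 1, 2)))
  expect_true(all(diff(g1$variants$pos[g1$variants$chrom == "1"]) > 0))
  expect_true(all(g1$variants$maf >= 0 & g1$variants$maf <= 0.5))
})

test_that("adjacent-site LD matches the Markov construction", {
  adj_r <- function(g) {
    v <- g$variants
    vapply(unique(v$chrom), function(chr) {
      idx <- which(v$chrom == chr)
      r <- vapply(idx[-length(idx)], function(i) {
        suppressWarnings(cor(g$dosage[, i], g$dosage[, i + 1]))
      }, numeric(1))
      r[is.na(r)] <- 0
      mean(r^2)
    }, numeric(1))
  }
  g0 <- simulate_genotypes(sim_config(n_samples = 2000, n_chromosomes = 1,
                                      variants_per_chrom = 300, ld_rho = 0,
                                      seed = 2))
  # independence: mean |r| near zero
  expect_lt(sqrt(mean(adj_r(g0))), 3 / sqrt(2000))
  g9 <- simulate_genotypes(sim_config(n_samples = 2000, n_chromosomes = 1,
                                      variants_per_chrom = 300, ld_rho = 0.9,
                                      seed = 2))
  # oracle: realized Pearson r^2 between adjacent dosages, expectation rho^2
  expect_lt(abs(mean(adj_r(g9)) - 0.81), 0.05)
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(n_samples = 0), "positive integer")
  expect_error(sim_config(prop_egenes = 1.2), "prop_egenes")
  expect_error(sim_config(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_config(residual_corr = matrix(c(1, 2, 2, 1), 2),
                          n_traits = 2), "positive-definite")
})

test_that("planted pleiotropic variants are recorded per trait with shared ids", {
  st <- small_study()
  cv <- st$trait_truth$causal_variants
  shared_ids <- cv |>
    dplyr::count(id) |>
    dplyr::filter(n == st$cfg$n_traits) |>
    dplyr::pull(id)
  expect_length(shared_ids, st$cfg$n_causal_shared)
  expect_true(all(cv$id %in% st$geno$variants$id))
  # liability trait is binary with the configured success rate
  ps <- st$traits$preg_st
  expect_setequal(unique(ps), c(0, 1))
  expect_equal(mean(ps), 1 - st$cfg$liability_threshold, tolerance = 0.1)
})

test_that("trait simulation realizes the requested variance partition", {
  st <- small_study()
  vc <- st$trait_truth$varcomp
  # causal and polygenic parts share variants, so a small covariance term
  # keeps the total only approximately at unit variance
  expect_equal(vc$sigma_g2 + vc$sigma_e2, rep(1, 4), tolerance = 0.05)
  expect_equal(vc$h2, st$cfg$h2, tolerance = 0.08)
})

test_that("null traits produce calibrated downstream association tests", {
  cfg <- sim_config(n_samples = 400, n_chromosomes = 1,
                    variants_per_chrom = 2000, ld_rho = 0, h2 = 0,
                    n_causal_shared = 0, n_causal_private = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  tr <- simulate_traits(g, cfg)
  st <- assoc_scan(g, tr$traits$dtc, tr$traits[covar_cols], grm = NULL)
  frac <- mean(st$p < 0.01)
  # the normal reference is slightly conservative at n = 400 (the exact rate
  # is P(|t_390| > 2.576) ~ 0.0096), so test against a 99.9% binomial band
  # around that rate
  rate <- 2 * pt(qnorm(0.995), df = 400 - 8, lower.tail = FALSE)
  ci <- qbinom(c(0.0005, 0.9995), 2000, rate) / 2000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("expression truth respects cis and trans window constraints", {
  st <- small_study()
  truth <- st$expr_truth$egene_truth
  ann <- st$expr$annotation
  v <- st$geno$variants
  gi <- match(truth$gene_id, ann$gene_id)
  vi <- match(truth$id, v$id)
  expect_false(anyNA(gi) || anyNA(vi))
  d <- abs(v$pos[vi] - ann$tss[gi])
  same_chr <- v$chrom[vi] == ann$chrom[gi]
  expect_true(all(same_chr))
  expect_true(all(d[truth$scope == "cis"] <= 2e6))
  expect_true(all(d[truth$scope == "trans"] > 5e6))
})

test_that("null expression yields (almost) no eGenes", {
  cfg <- sim_config(n_samples = 120, n_chromosomes = 2,
                    variants_per_chrom = 150, n_genes = 80,
                    prop_egenes = 0, n_trans_genes = 0, seed = 3)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  expect_equal(nrow(ex$truth$egene_truth), 0)
  expr <- suppressMessages(cpm_filter(ex$expr))
  rec <- suppressMessages(map_cis_eqtl(expr, g, grm = NULL, q_pcs = 2))
  eg <- hierarchical_correction(rec, nrow(expr$annotation), alpha = 0.01)
  expect_lte(nrow(eg$egenes), 1)
})

test_that("equal library sizes with vanishing dispersion make CPM track the mean", {
  cfg <- sim_config(n_samples = 60, n_chromosomes = 1,
                    variants_per_chrom = 100, n_genes = 40,
                    prop_egenes = 0, n_trans_genes = 0, n_batch_factors = 0,
                    expr_noise_sd = 0.01, nb_dispersion = 1e-8, seed = 8)
  g <- simulate_genotypes(cfg)
  ex <- simulate_expression(g, cfg)
  counts <- ex$expr$counts
  cpm <- t(t(counts) * 1e6 / colSums(counts))
  # per-sample CPM is proportional to the gene mean count
  ratios <- cpm / rowMeans(counts)
  cv <- apply(ratios, 1, function(r) sd(r) / mean(r))
  expect_lt(median(cv), 0.25)
})
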