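test_that("GRM matches the direct formula and duplicate-identity property", {
  set.seed(1)
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0), nrow = 3)
  g <- make_geno(dos)
  G <- compute_grm(g, maf_min = 0)$values
  # brute-force evaluation of the standardized-GRM formula
  p <- colMeans(dos) / 2
  Z <- sweep(sweep(dos, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  G_oracle <- tcrossprod(Z) / 2
  expect_equal(unname(G), unname(G_oracle), tolerance = 1e-12)

  dos2 <- matrix(rbinom(20 * 8, 2, 0.4), 20, 8)
  dos2[2, ] <- dos2[1, ]  # duplicated individual
  g2 <- compute_grm(make_geno(dos2), maf_min = 0)$values
  expect_equal(g2[1, 2], g2[1, 1], tolerance = 1e-12)
})

test_that("GRM diagonal is near 1 under Hardy-Weinberg sampling", {
  set.seed(2)
  p <- runif(2000, 0.05, 0.5)
  dos <- sapply(p, function(pp) rbinom(500, 2, pp))
  g <- compute_grm(make_geno(dos), maf_min = 0)
  expect_lt(abs(mean(diag(g$values)) - 1), 0.05)
  expect_gte(min(eigen(g$values, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("monomorphic variants are excluded and all-monomorphic input errors", {
  dos <- cbind(rep(2, 10), rbinom(10, 2, 0.5))
  expect_warning(g <- compute_grm(make_geno(dos), maf_min = 0), "monomorphic")
  expect_equal(g$n_variants_used, 1)
  expect_error(suppressWarnings(
    compute_grm(make_geno(matrix(2, 10, 2)), maf_min = 0)), "no polymorphic")
})

test_that("REML maximum matches a brute-force optimisation of the restricted likelihood", {
  set.seed(3)
  n <- 8
  dos <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  g <- make_geno(dos)
  grm <- suppressWarnings(compute_grm(g, maf_min = 0))
  X <- cbind(rnorm(n))
  y <- rnorm(n) + 0.5 * drop(chol(grm$values + diag(1e-4, n)) %*% rnorm(n))
  fit <- fit_null_lmm(y, X, grm)

  # independent oracle: direct matrix form of the restricted likelihood
  Xm <- cbind(1, X)
  ll_direct <- function(sg, se) {
    V <- sg * grm$values + se * diag(n)
    Vi <- solve(V)
    XVX <- t(Xm) %*% Vi %*% Xm
    P <- Vi - Vi %*% Xm %*% solve(XVX) %*% t(Xm) %*% Vi
    -0.5 * ((n - ncol(Xm)) * log(2 * pi) +
              as.numeric(determinant(V)$modulus) +
              as.numeric(determinant(XVX)$modulus) +
              drop(t(y) %*% P %*% y))
  }
  # the fitted components reproduce the fitted log-likelihood in direct form
  expect_equal(ll_direct(fit$sigma_g2, fit$sigma_e2), fit$reml_loglik,
               tolerance = 1e-6)
  # and no point on a dense grid beats the reported maximum
  grid <- expand.grid(sg = seq(0.001, 2, length.out = 40),
                      se = seq(0.05, 2, length.out = 40))
  best_grid <- max(mapply(ll_direct, grid$sg, grid$se))
  expect_gte(fit$reml_loglik + 1e-6, best_grid)
})

test_that("REML on pure noise stays near zero heritability", {
  st <- small_study()
  set.seed(4)
  h2 <- replicate(10, {
    fit_null_lmm(rnorm(length(st$geno$sample_ids)), NULL, st$grm)$h2
  })
  expect_lt(mean(h2), 0.08)
})

test_that("assoc_scan equals ordinary least squares when sigma_g2 = 0", {
  st <- small_study()
  g <- subset_geno(st$geno, variants = 1:40)
  X <- st$traits[covar_cols]
  y <- st$traits$afc
  scan <- assoc_scan(g, y, X, grm = NULL, trait = "afc")
  Xm <- stats::model.matrix(~ year_of_birth + contemporary_group +
                              age_at_joining,
                            data = as.data.frame(lapply(X, function(c)
                              if (is.character(c)) factor(c) else c)))
  for (j in c(1, 7, 23, 40)) {
    fit <- stats::lm(y ~ Xm[, -1] + g$dosage[, j])
    co <- summary(fit)$coefficients
    k <- nrow(co)
    expect_equal(scan$beta[j], unname(co[k, 1]), tolerance = 1e-8)
    expect_equal(scan$se[j], unname(co[k, 2]), tolerance = 1e-8)
    expect_equal(scan$t[j], unname(co[k, 3]), tolerance = 1e-8)
    expect_equal(scan$p[j], 2 * pnorm(-abs(scan$t[j])))
  }
})

test_that("scan p-values are invariant under affine rescaling of the phenotype", {
  st <- small_study()
  g <- subset_geno(st$geno, variants = 1:30)
  y <- st$traits$wks_preg
  fit1 <- fit_null_lmm(y, NULL, st$grm)
  fit2 <- fit_null_lmm(3 * y + 2, NULL, st$grm)
  s1 <- assoc_scan(g, y, NULL, st$grm, fit1)
  s2 <- assoc_scan(g, 3 * y + 2, NULL, st$grm, fit2)
  expect_equal(s1$p, s2$p, tolerance = 1e-6)
  expect_equal(s2$beta, 3 * s1$beta, tolerance = 1e-6)
})

test_that("scan is calibrated under a permuted phenotype", {
  set.seed(6)
  cfg <- sim_config(n_samples = 500, n_chromosomes = 1,
                    variants_per_chrom = 10000, ld_rho = 0, seed = 12)
  g <- simulate_genotypes(cfg)
  y <- sample(rnorm(500))
  scan <- assoc_scan(g, y, NULL, grm = NULL)
  frac <- mean(scan$p < 0.01)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.01) / 10000
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("conditioning on a causal variant removes its own and proxies' signal", {
  set.seed(7)
  cfg <- sim_config(n_samples = 500, n_chromosomes = 1,
                    variants_per_chrom = 200, ld_rho = 0.97, seed = 13)
  g <- simulate_genotypes(cfg)
  focal <- 100L
  r2 <- sapply(seq_len(200), function(j)
    suppressWarnings(cor(g$dosage[, focal], g$dosage[, j]))^2)
  proxies <- setdiff(which(r2 > 0.8), focal)
  expect_gt(length(proxies), 0)
  y <- 0.8 * g$dosage[, focal] + rnorm(500)
  un <- assoc_scan(g, y, NULL, grm = NULL)
  cond <- assoc_scan(g, y, NULL, grm = NULL,
                     conditioning_set = g$variants$id[focal])
  own <- cond[focal, ]
  expect_true(own$flagged)
  expect_equal(own$beta, 0)
  expect_equal(own$p, 1)
  expect_gt(min(cond$p[proxies]) / min(un$p[proxies]), 1e3)
})

test_that("the closed-form FDR reproduces its worked examples and monotonicity", {
  expect_equal(truncate_decimals(fdr_from_counts(5e-8, 3, 31140417), 2), 0.51)
  expect_equal(fdr_from_counts(0.002, 11, 225), 0.03899, tolerance = 1e-4)
  expect_equal(fdr_from_counts(0.5, 10, 10), 0)
  expect_message(expect_equal(fdr_from_counts(0.01, 0, 100), 1), "convention")
  expect_error(fdr_from_counts(0.01, 5, 0), "n_tested")
  # increasing in P, decreasing in A at fixed T
  ps <- c(1e-8, 1e-6, 1e-4, 1e-2)
  expect_true(all(diff(sapply(ps, fdr_from_counts,
                              n_significant = 5, n_tested = 1e5)) >= 0))
  as <- c(1, 5, 20, 80)
  expect_true(all(diff(sapply(as, function(a)
    fdr_from_counts(1e-4, a, 1e5))) <= 0))
})
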