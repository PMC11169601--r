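test_that("interval membership uses 1-based points against converted BED", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tpeak", bed)
  iv <- read_intervals(bed)
  v <- tibble::tibble(chrom = "chr1", pos = c(10L, 11L, 20L, 21L),
                      id = sprintf("v%d", 1:4))
  fl <- annotate_variants(v, iv)
  expect_equal(fl$peak, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("interval index agrees with a brute-force scan on random data", {
  set.seed(51)
  v <- tibble::tibble(chrom = sample(c("1", "2"), 1000, replace = TRUE),
                      pos = sample.int(1e5, 1000, replace = TRUE),
                      id = sprintf("v%04d", 1:1000))
  iv <- tibble::tibble(category = sample(c("a", "b"), 200, replace = TRUE),
                       chrom = sample(c("1", "2"), 200, replace = TRUE),
                       start = sample.int(9e4, 200, replace = TRUE))
  iv$end <- iv$start + sample.int(5000, 200, replace = TRUE)
  fl <- annotate_variants(v, iv)
  for (cat in c("a", "b")) {
    sub <- iv[iv$category == cat, ]
    oracle <- vapply(seq_len(nrow(v)), function(i) {
      any(sub$chrom == v$chrom[i] & sub$start <= v$pos[i] &
            v$pos[i] <= sub$end)
    }, logical(1))
    expect_identical(fl[[cat]], oracle)
  }
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  # background of 20, 5 in category, 4 leads, 3 in category
  bg <- c(rep(TRUE, 5), rep(FALSE, 15))
  lead <- c(rep(TRUE, 3), FALSE)
  rec <- hypergeometric_enrichment(lead, bg, "cat")
  tail_oracle <- sum(vapply(3:4, function(k) {
    choose(5, k) * choose(15, 4 - k) / choose(20, 4)
  }, numeric(1)))
  expect_equal(rec$p_hyper, tail_oracle, tolerance = 1e-12)
  expect_equal(rec$fold, (3 / 4) / (5 / 20))
  expect_gt(rec$fold, 1)

  # saturation: category covers the whole background
  sat <- hypergeometric_enrichment(rep(TRUE, 4), rep(TRUE, 20), "all")
  expect_equal(sat$fold, 1)
  expect_equal(sat$p_hyper, 1)

  # zero overlap with a nonempty category
  zero <- hypergeometric_enrichment(rep(FALSE, 4), bg, "none")
  expect_equal(zero$fold, 0)
  expect_equal(zero$p_hyper, 1)

  # direction agreement: fold > 1 iff overlap above expectation
  expect_true(xor(rec$fold <= 1, rec$n_lead_in / rec$n_lead >
                    rec$n_background_in / rec$n_background))
})

test_that("Fisher overlap matches brute-force enumeration over fixed margins", {
  # enumerate all tables with the same margins as (3,2,1,14) and sum the
  # probabilities of those at most as probable (two-sided exact test)
  tab <- c(3, 2, 1, 14)
  margins <- list(r1 = 5, r2 = 15, c1 = 4, n = 20)
  hyper_p <- function(a) {
    choose(margins$r1, a) * choose(margins$r2, margins$c1 - a) /
      choose(margins$n, margins$c1)
  }
  probs <- vapply(0:4, hyper_p, numeric(1))
  p_oracle <- sum(probs[probs <= hyper_p(3) * (1 + 1e-7)])
  universe <- sprintf("g%02d", 1:20)
  setA <- universe[1:5]
  setB <- universe[c(1:3, 6)]
  res <- fisher_gene_overlap(setA, setB, universe)
  expect_equal(res$n_both, 3)
  expect_equal(res$n_a_only, 2)
  expect_equal(res$n_b_only, 1)
  expect_equal(res$n_neither, 14)
  expect_equal(res$p_fisher, p_oracle, tolerance = 1e-10)

  # identical halves of the universe: overlap is maximal, p tiny
  half <- universe[1:10]
  same <- fisher_gene_overlap(half, half, universe)
  expect_equal(same$n_both, 10)
  expect_lt(same$p_fisher, 1e-4)

  # disjoint sets covering the universe
  disj <- fisher_gene_overlap(universe[1:10], universe[11:20], universe)
  expect_equal(disj$n_both, 0)
  expect_true(disj$haldane || disj$odds_ratio == 0)
  expect_error(fisher_gene_overlap("x", "y", character()), "universe")
})

test_that("validation retest reproduces the printed FDR and handles edge cases", {
  stats <- tibble::tibble(id = sprintf("v%03d", 1:225),
                          p = c(rep(0.0001, 11), runif(214, 0.01, 1)))
  res <- validation_retest(stats$id, stats, p_threshold = 0.002)
  expect_equal(res$n_validated, 11)
  expect_equal(truncate_decimals(100 * res$fdr, 1), 3.8)

  none <- validation_retest(stats$id,
                            dplyr::mutate(stats, p = 0.5), 0.002)
  expect_equal(none$fdr, 1)
  expect_warning(
    missing_hit <- validation_retest(c(stats$id, "absent"), stats, 0.002),
    "absent")
  expect_equal(missing_hit$n_tested, 225)

  # under a uniform null, validated counts stay within Poisson-like bounds
  set.seed(52)
  a_null <- replicate(200, {
    pv <- runif(225)
    sum(pv < 0.002)
  })
  expect_lt(abs(mean(a_null) - 0.45), 0.2)
})

test_that("ePercent truncates to the printed one-decimal value", {
  expect_equal(truncate_decimals(epercent(4376, 10455), 1), 41.8)
  expect_equal(epercent(0, 100), 0)
  expect_equal(epercent(100, 100), 100)
  expect_error(epercent(5, 4), "exceed")
})

test_that("a planted variant subset explains more variance than random subsets", {
  set.seed(53)
  cfg <- sim_config(n_samples = 500, n_chromosomes = 1,
                    variants_per_chrom = 400, ld_rho = 0, seed = 54)
  g <- simulate_genotypes(cfg)
  subset_ids <- g$variants$id[1:20]
  w <- g$dosage[, 1:20]
  eff <- rnorm(20)
  gval <- drop(w %*% eff)
  gval <- gval * sqrt(0.2 / var(gval))     # subset explains 20%
  y <- gval + rnorm(500, sd = sqrt(0.8))
  res <- suppressWarnings(
    variance_explained_subset(g, subset_ids, y, NULL,
                              n_random_reps = 3, seed = 55))
  expect_gt(res$h2_subset, res$h2_random_mean)
  expect_lt(abs(res$h2_subset - 0.2), 0.1)
  # determinism of the random baseline
  res2 <- suppressWarnings(
    variance_explained_subset(g, subset_ids, y, NULL,
                              n_random_reps = 3, seed = 55))
  expect_equal(res$h2_random_mean, res2$h2_random_mean)
})
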