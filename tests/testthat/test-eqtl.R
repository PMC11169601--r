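toy_expr <- function(counts, chrom = NULL, tss = NULL, strand = NULL) {
  ngene <- nrow(counts)
  n <- ncol(counts)
  ann <- tibble::tibble(
    gene_id = rownames(counts) %||% sprintf("G%02d", seq_len(ngene)),
    chrom = chrom %||% rep("1", ngene),
    tss = as.integer(tss %||% (seq_len(ngene) * 1e6)),
    strand = strand %||% rep("+", ngene),
    start = 1L, end = 300000000L)
  samples <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)),
                            contemporary_group = rep("cg1", n),
                            lactation = 0, weeks_pregnant = 0)
  rownames(counts) <- ann$gene_id
  colnames(counts) <- samples$sample_id
  pleioqtl:::new_expr_matrix(counts, ann, samples)
}

test_that("CPM filter matches hand enumeration and boundary convention", {
  lib_scale <- c(1, 1, 2, 4)
  counts <- rbind(
    g1 = c(0, 0, 0, 0),          # all zero -> excluded
    g2 = c(10, 10, 20, 40),      # CPM = 3.03 everywhere -> kept
    g3 = c(9, 10, 20, 40),       # CPM < 3 in exactly 25% -> excluded
    g4 = c(100, 100, 200, 400))  # high everywhere -> kept
  # library sizes: make each sample total 3.3e6 * scale so CPM(10) ~ 3.03
  pad <- pmax(0, round(3.3e6 * lib_scale) - colSums(counts))
  counts <- rbind(counts, pad = pad)
  ex <- toy_expr(counts)
  kept <- suppressMessages(cpm_filter(ex, min_cpm = 3, max_low_prop = 0.25))
  expect_setequal(setdiff(rownames(kept$counts), "pad"),
                  c("g2", "g4"))
  expect_error(cpm_filter(toy_expr(matrix(0, 2, 3))), "zero library")
})

test_that("expression PCs recover a planted batch factor with fixed signs", {
  set.seed(31)
  n <- 60; ngene <- 120
  batch <- rnorm(n)
  load <- rnorm(ngene)
  lc <- outer(load, batch) + matrix(rnorm(ngene * n, sd = 0.1), ngene)
  pcs <- expression_pcs(lc, q = 2)
  expect_gt(abs(cor(pcs[, 1], batch)), 0.99)
  # duplicated samples get identical scores
  lc2 <- cbind(lc, lc[, 1])
  pcs2 <- expression_pcs(lc2, q = 2)
  expect_equal(pcs2[n + 1, ], pcs2[1, ], tolerance = 1e-8)
  # q = 0 is a no-op block; q >= n errors
  expect_equal(ncol(expression_pcs(lc, q = 0)), 0)
  expect_error(expression_pcs(lc, q = n), "smaller")
})

test_that("cis window is closed and trans distance rule is strict", {
  set.seed(32)
  n <- 40
  pos <- c(1e6, 3e6 - 2e6, 3e6 + 2e6, 3e6 + 2e6 + 1, 3e6 + 4.9e6, 3e6 + 5e6 + 1)
  dos <- matrix(rbinom(n * length(pos), 2, 0.4), n)
  g <- make_geno(dos, pos = pos)
  counts <- matrix(rnbinom(2 * n, mu = 200, size = 10), 2)
  ex <- toy_expr(counts, tss = c(3e6, 3e6))
  ex <- suppressMessages(cpm_filter(ex, min_cpm = 0.001))
  rec <- suppressWarnings(suppressMessages(
    map_cis_eqtl(ex, g, grm = NULL, q_pcs = 0, maf_min = 0)))
  cis_pos <- unique(rec$pos)
  # variants at exactly TSS +/- 2 Mb are included; one beyond is not
  expect_true(all(c(1e6, 5e6) %in% cis_pos))
  expect_false((3e6 + 2e6 + 1) %in% cis_pos)

  tsel <- g$variants
  trx <- suppressWarnings(suppressMessages(
    map_trans_eqtl(tsel, ex, g, grm = NULL, q_pcs = 0, maf_min = 0)))
  trans_pos <- unique(trx$records$pos)
  expect_false((3e6 + 4.9e6) %in% trans_pos)   # 4.9 Mb: not tested
  expect_true((3e6 + 5e6 + 1) %in% trans_pos)  # > 5 Mb: tested
})

test_that("tss_distance is signed and strand-oriented", {
  set.seed(33)
  n <- 30
  dos <- matrix(rbinom(n * 2, 2, 0.4), n)
  g <- make_geno(dos, pos = c(900000, 1100000))
  counts <- matrix(rnbinom(2 * n, mu = 100, size = 10), 2)
  ex <- toy_expr(counts, tss = c(1e6, 1e6), strand = c("+", "-"))
  ex <- suppressMessages(cpm_filter(ex, min_cpm = 0.001))
  rec <- suppressWarnings(suppressMessages(
    map_cis_eqtl(ex, g, grm = NULL, q_pcs = 0, maf_min = 0)))
  plus <- rec[rec$gene_id == "G01", ]
  minus <- rec[rec$gene_id == "G02", ]
  expect_equal(sort(plus$tss_distance), c(-100000, 100000))
  expect_equal(sort(minus$tss_distance), c(-100000, 100000))
  expect_equal(plus$tss_distance[plus$pos == 900000], -100000)
  expect_equal(minus$tss_distance[minus$pos == 900000], 100000)
})

test_that("hierarchical correction applies both Bonferroni steps with caps", {
  base <- tibble::tibble(gene_id = "G1", chrom = "1", pos = 100L, id = "1:100",
                         a1 = "C", a2 = "A", freq = 0.3, beta = 1, se = 0.1,
                         t = 10, tss_distance = 50L, scope = "cis", n = 100L)
  n_genes <- 50
  rec <- dplyr::mutate(base, p = 0.01 / (2 * n_genes))
  eg <- hierarchical_correction(rec, n_genes, alpha = 0.01)
  expect_equal(nrow(eg$egenes), 1)        # single gene, single variant
  expect_equal(eg$egenes$p_local, rec$p)  # m_g = 1
  expect_equal(eg$egenes$p_global, rec$p * n_genes)

  rec2 <- base[rep(1, 30), ] |>
    dplyr::mutate(id = sprintf("1:%d", 1:30), pos = 1:30, p = 0.2)
  adj <- hierarchical_correction(rec2, n_genes, alpha = 2)
  expect_true(all(adj$eqtls$p_local == 1))  # 0.2 * 30 capped at 1

  expect_error(
    hierarchical_correction(
      dplyr::bind_rows(rec, dplyr::mutate(rec, gene_id = "G2")), 1),
    "smaller")

  # invariants: p_local >= p and p_global >= p_local
  st <- small_study()
  expr <- suppressMessages(cpm_filter(st$expr))
  recs <- suppressMessages(map_cis_eqtl(expr, st$geno, st$grm, q_pcs = 2))
  res <- hierarchical_correction(recs, nrow(expr$annotation))
  expect_true(all(res$eqtls$p_local >= res$eqtls$p))
  expect_true(all(res$egenes$p_global >= res$egenes$p_local))
  expect_true(all(res$egenes$p_global < res$alpha))
  expect_true(all(abs(res$eqtls$tss_distance[res$eqtls$scope == "cis"]) <= 2e6))
  expect_equal(sum(res$eqtls$lead), nrow(res$egenes))
})

test_that("trans test-set construction unions seeds and flanks without duplicates", {
  set.seed(34)
  pos <- c(1000, 1080, 1150, 5000)
  dos <- matrix(rbinom(20 * 4, 2, 0.4), 20)
  g <- make_geno(dos, pos = pos)
  seeds <- g$variants$id[c(1, 3)]  # 150 bp apart, middle variant 80 bp away
  ts <- select_trans_test_set(tibble::tibble(id = seeds), character(), g,
                              flank_bp = 100)
  expect_setequal(ts$id, g$variants$id[1:3])
  expect_equal(nrow(ts), 3)
  ts0 <- select_trans_test_set(tibble::tibble(id = seeds), character(), g,
                               flank_bp = 0)
  expect_setequal(ts0$id, seeds)
  empty <- select_trans_test_set(tibble::tibble(id = character()),
                                 character(), g)
  expect_equal(nrow(empty), 0)
})

test_that("TSS-distance profile bins by hand and normalizes", {
  leads <- tibble::tibble(gene_id = c("G1", "G2", "G3"),
                          tss_distance = c(10e3, 150e3, 3e6),
                          pos = c(1L, 2L, 3L))
  prof <- tss_distance_profile(leads)
  expect_equal(sum(prof$bins$proportion), 1)
  expect_equal(prof$bins$n[1], 1)                       # 10 kb in [0, 50 kb]
  expect_equal(prof$bins$n[3], 1)                       # 150 kb in (100, 200]
  expect_equal(prof$bins$n[length(prof$bins$n)], 1)     # 3 Mb overflow
  all_at_tss <- tibble::tibble(gene_id = "G1", tss_distance = 0, pos = 1L)
  p0 <- tss_distance_profile(all_at_tss)
  expect_equal(p0$bins$proportion[1], 1)
})

test_that("split-half reproducibility is deterministic given the seed", {
  st <- small_study()
  expr <- suppressMessages(cpm_filter(st$expr))
  r1 <- suppressMessages(split_half_reproducibility(expr, st$geno, grm = NULL,
                                                    seed = 5, q_pcs = 2))
  r2 <- suppressMessages(split_half_reproducibility(expr, st$geno, grm = NULL,
                                                    seed = 5, q_pcs = 2))
  expect_identical(r1, r2)
  expect_true(is.na(r1$lead_effect_correlation) ||
                abs(r1$lead_effect_correlation) <= 1)
})
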