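# Enrichment and validation statistics: interval annotation of variants,
# hypergeometric enrichment of lead eQTLs, Fisher gene-set overlap, variance
# explained by a variant subset with a random baseline, and re-testing of
# discovery variants in a validation cohort.

#' Annotate variants with interval-category membership
#'
#' Point-in-interval test of 1-based variant positions against 1-based
#' inclusive intervals (converted from BED at read time). A variant may
#' belong to several categories.
#'
#' @param variants Variant tibble with chrom, pos, id columns.
#' @param intervals Interval tibble from [read_intervals()].
#' @return Tibble: id plus one logical column per category.
#' @export
annotate_variants <- function(variants, intervals) {
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  out <- tibble(id = variants$id)
  for (cat in unique(intervals$category)) {
    iv <- intervals[intervals$category == cat, ]
    igr <- GenomicRanges::GRanges(iv$chrom,
                                  IRanges::IRanges(iv$start, iv$end))
    out[[cat]] <- IRanges::overlapsAny(vgr, igr)
  }
  out
}

#' Hypergeometric enrichment of a lead set within a category
#'
#' Upper-tail hypergeometric p for drawing at least the observed number of
#' category members among the leads, from the background composition, plus
#' the fold enrichment (lead in-category rate over background in-category
#' rate).
#'
#' @param lead_flags Logical vector: category membership of the lead set.
#' @param background_flags Logical vector: membership over the background
#'   (the lead set must be drawn from this background).
#' @param category Category label for the output.
#' @return One-row tibble: category, n_lead_in, n_lead, n_background_in,
#'   n_background, fold, p_hyper. `fold` is NA when the category is empty
#'   in the background.
#' @export
hypergeometric_enrichment <- function(lead_flags, background_flags,
                                      category = "category") {
  k <- sum(lead_flags)
  n_lead <- length(lead_flags)
  K <- sum(background_flags)
  N <- length(background_flags)
  if (n_lead > N) abort("lead set larger than background")
  fold <- if (K == 0) NA_real_ else (k / n_lead) / (K / N)
  p <- if (K == 0) NA_real_ else phyper(k - 1, K, N - K, n_lead,
                                        lower.tail = FALSE)
  tibble(category = category, n_lead_in = k, n_lead = n_lead,
         n_background_in = K, n_background = N, fold = fold, p_hyper = p)
}

#' Fisher's exact test of gene-set overlap
#'
#' Builds the 2x2 membership table of two gene sets over an explicit
#' universe and applies Fisher's exact test (two-sided by default). The
#' odds ratio uses the Haldane 0.5 correction when a cell is zero (flagged).
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector defining the tested gene universe.
#' @param alternative Sidedness passed to [fisher.test()].
#' @return One-row tibble: n_both, n_a_only, n_b_only, n_neither,
#'   odds_ratio, haldane (logical), p_fisher.
#' @export
fisher_gene_overlap <- function(set_a, set_b, universe,
                                alternative = "two.sided") {
  if (!length(universe)) abort("empty gene universe")
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                2, 2, byrow = TRUE)
  ft <- fisher.test(tab, alternative = alternative)
  haldane <- any(tab == 0)
  tc <- if (haldane) tab + 0.5 else tab
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  tibble(n_both = tab[1, 1], n_a_only = tab[1, 2], n_b_only = tab[2, 1],
         n_neither = tab[2, 2], odds_ratio = or, haldane = haldane,
         p_fisher = ft$p.value)
}

#' Variance explained by a variant subset, with a random-subset baseline
#'
#' Builds a GRM from the given variants only, estimates by REML the
#' proportion of phenotypic variance it captures, and contrasts it with the
#' average over `n_random_reps` equally sized random variant subsets.
#'
#' @param geno A `geno_matrix`.
#' @param subset Character vector of variant ids forming the focal subset.
#' @param y Phenotype vector aligned with `geno` samples.
#' @param X Covariates (as in [fit_null_lmm()]).
#' @param n_random_reps Number of random baseline subsets (default 5).
#' @param seed Integer seed for the random subsets.
#' @return One-row tibble: h2_subset, h2_random_mean, h2_random_sd,
#'   n_random_reps, n_subset.
#' @export
variance_explained_subset <- function(geno, subset, y, X = NULL,
                                      n_random_reps = 5, seed = 1) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!length(subset)) abort("`subset` is empty")
  if (!all(subset %in% geno$variants$id)) abort("unknown variant id in `subset`")
  h2_of <- function(ids) {
    g <- compute_grm(subset_geno(geno, variants = ids), maf_min = 0)
    fit <- tryCatch(fit_null_lmm(y, X, g), error = function(e) NULL)
    if (is.null(fit)) NA_real_ else fit$h2
  }
  h2_subset <- h2_of(subset)
  pool <- setdiff(geno$variants$id, subset)
  h2_rand <- withr::with_seed(seed, {
    vapply(seq_len(n_random_reps), function(i) {
      h2_of(sample(pool, length(subset)))
    }, numeric(1))
  })
  failed <- sum(is.na(h2_rand))
  if (failed > 0) {
    warn(sprintf("%d random-baseline replicate(s) failed REML and were skipped",
                 failed))
  }
  tibble(h2_subset = h2_subset,
         h2_random_mean = mean(h2_rand, na.rm = TRUE),
         h2_random_sd = sd(h2_rand, na.rm = TRUE),
         n_random_reps = n_random_reps - failed,
         n_subset = length(subset))
}

#' Re-test discovery variants in a validation cohort
#'
#' Counts discovery hits that reach `p_threshold` in the validation summary
#' statistics and attaches the closed-form FDR for that count.
#'
#' @param discovery_hits Character vector of discovery variant ids.
#' @param validation_stats Summary-statistics tibble for the validation
#'   cohort (id and p columns).
#' @param p_threshold Validation significance threshold (default 0.002).
#' @return One-row tibble: n_tested, n_validated, fdr.
#' @export
validation_retest <- function(discovery_hits, validation_stats,
                              p_threshold = 0.002) {
  present <- discovery_hits %in% validation_stats$id
  if (any(!present)) {
    warn(sprintf("%d discovery hit(s) absent from validation stats, excluded",
                 sum(!present)))
  }
  hits <- discovery_hits[present]
  if (!length(hits)) abort("no discovery hits present in validation stats")
  pv <- validation_stats$p[match(hits, validation_stats$id)]
  a <- sum(pv < p_threshold)
  fdr <- suppressMessages(fdr_from_counts(p_threshold, a, length(hits)))
  tibble(n_tested = length(hits), n_validated = a, fdr = fdr)
}

#' Percentage of tested genes that are eGenes
#'
#' @param n_egenes Number of eGenes.
#' @param n_tested Number of genes tested.
#' @return 100 * n_egenes / n_tested at full precision (reports truncate to
#'   one decimal: 4376 of 10455 prints as 41.8).
#' @export
epercent <- function(n_egenes, n_tested) {
  if (n_tested < 1) abort("`n_tested` must be at least 1")
  if (n_egenes > n_tested) abort("`n_egenes` cannot exceed `n_tested`")
  100 * n_egenes / n_tested
}
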