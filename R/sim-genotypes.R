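#' Simulate biallelic dosages with block LD
#'
#' Draws two haplotypes per individual. Within a chromosome each haplotype is
#' a first-order Markov chain over sites: the allele at site i+1 is copied
#' from site i with probability `ld_rho`, otherwise drawn fresh at that
#' site's target frequency. Adjacent-dosage correlation is therefore close to
#' `ld_rho` and decays geometrically with distance in sites, which is enough
#' structure to exercise r^2-based clumping and cis/trans windows. Dosage =
#' haplotype sum, so values are in {0, 1, 2}. Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @param template Optional `geno_matrix` whose variant panel (positions,
#'   ids, target frequencies) is reused, drawing fresh haplotypes — an
#'   independent cohort genotyped on the same panel (e.g. a validation
#'   population).
#' @return A `geno_matrix`: list with `dosage` (n_samples x n_variants numeric
#'   matrix), `variants` (tibble: chrom, pos, id, ref, alt, freq, maf,
#'   accuracy) and `sample_ids`. Variant `freq` is the realized alt-allele
#'   frequency and `maf` its folded value; `accuracy` emulates an
#'   imputation-quality score (Beta(9,1), so mostly high).
#' @export
#' @examples
#' g <- simulate_genotypes(sim_config(n_samples = 20, n_chromosomes = 1,
#'                                    variants_per_chrom = 50))
#' dim(g$dosage)
simulate_genotypes <- function(config, template = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, 1L), {
    n <- config$n_samples
    n_hap <- 2L * n
    chrom_set <- if (is.null(template)) {
      as.character(seq_len(config$n_chromosomes))
    } else {
      unique(template$variants$chrom)
    }
    dosage_chunks <- vector("list", length(chrom_set))
    var_chunks <- vector("list", length(chrom_set))
    for (ci in seq_along(chrom_set)) {
      chr <- chrom_set[ci]
      if (is.null(template)) {
        m_chr <- config$variants_per_chrom
        p <- runif(m_chr, config$maf_range[1], config$maf_range[2])
        pos <- sort(sample.int(config$chrom_length_bp, m_chr))
      } else {
        tv <- template$variants[template$variants$chrom == chr, ]
        m_chr <- nrow(tv)
        p <- tv$freq
        pos <- tv$pos
      }
      hap <- matrix(0L, n_hap, m_chr)
      hap[, 1] <- rbinom(n_hap, 1L, p[1])
      if (m_chr > 1) {
        for (i in 2:m_chr) {
          copy <- runif(n_hap) < config$ld_rho
          fresh <- rbinom(n_hap, 1L, p[i])
          hap[, i] <- ifelse(copy, hap[, i - 1], fresh)
        }
      }
      dos <- hap[seq_len(n), , drop = FALSE] +
        hap[n + seq_len(n), , drop = FALSE]
      freq <- colMeans(dos) / 2
      var_chunks[[ci]] <- tibble(
        chrom = chr,
        pos = as.integer(pos),
        id = sprintf("%s:%d", chr, pos),
        ref = "A", alt = "C",
        freq = freq,
        maf = fold_maf(freq),
        accuracy = rbeta(m_chr, 9, 1)
      )
      dosage_chunks[[ci]] <- dos
    }
    dosage <- do.call(cbind, dosage_chunks)
    storage.mode(dosage) <- "double"
    variants <- dplyr::bind_rows(var_chunks)
    sample_ids <- sprintf("id%04d", seq_len(n))
    dimnames(dosage) <- list(sample_ids, variants$id)
    new_geno_matrix(dosage, variants, sample_ids)
  })
}

new_geno_matrix <- function(dosage, variants, sample_ids) {
  stopifnot(nrow(dosage) == length(sample_ids),
            ncol(dosage) == nrow(variants),
            !anyDuplicated(sample_ids))
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    abort("dosages must lie in [0, 2]")
  }
  ord <- order(as_chrom_order(variants$chrom), variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, ]
    dosage <- dosage[, ord, drop = FALSE]
  }
  structure(list(dosage = dosage, variants = variants,
                 sample_ids = sample_ids),
            class = "geno_matrix")
}

# numeric chromosome order where possible, lexicographic otherwise
as_chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  if (anyNA(num)) rank(chrom, ties.method = "min") else num
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$sample_ids), " samples x ",
      nrow(x$variants), " variants on ",
      dplyr::n_distinct(x$variants$chrom), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or variants
#'
#' @param geno A `geno_matrix`.
#' @param samples Sample ids or indices to keep (default all).
#' @param variants Variant ids or indices to keep (default all).
#' @return A `geno_matrix` restricted to the requested rows/columns.
#' @export
subset_geno <- function(geno, samples = NULL, variants = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  si <- if (is.null(samples)) seq_along(geno$sample_ids) else {
    if (is.character(samples)) match(samples, geno$sample_ids) else samples
  }
  vi <- if (is.null(variants)) seq_len(nrow(geno$variants)) else {
    if (is.character(variants)) match(variants, geno$variants$id) else variants
  }
  if (anyNA(si)) abort("unknown sample id in `samples`")
  if (anyNA(vi)) abort("unknown variant id in `variants`")
  new_geno_matrix(geno$dosage[si, vi, drop = FALSE],
                  geno$variants[vi, ], geno$sample_ids[si])
}
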