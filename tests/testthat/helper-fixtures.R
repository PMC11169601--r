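# Shared fixtures, generated in code and cached per test run.

small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 150, n_chromosomes = 3,
                        variants_per_chrom = 250, n_genes = 60, seed = 42)
      geno <- simulate_genotypes(cfg)
      tr <- simulate_traits(geno, cfg)
      ex <- simulate_expression(geno, cfg)
      grm <- compute_grm(geno)
      cache <<- list(cfg = cfg, geno = geno,
                     traits = tr$traits, trait_truth = tr$truth,
                     expr = ex$expr, expr_truth = ex$truth, grm = grm)
    }
    cache
  }
})

# hand-built genotype container for exact-oracle tests
make_geno <- function(dosage, chrom = NULL, pos = NULL, ids = NULL) {
  m <- ncol(dosage)
  chrom <- chrom %||% rep("1", m)
  pos <- as.integer(pos %||% (seq_len(m) * 1000L))
  ids <- ids %||% sprintf("%s:%d", chrom, pos)
  freq <- colMeans(dosage) / 2
  variants <- tibble::tibble(chrom = chrom, pos = as.integer(pos), id = ids,
                             ref = "A", alt = "C", freq = freq,
                             maf = pmin(freq, 1 - freq), accuracy = 1)
  pleioqtl:::new_geno_matrix(dosage, variants,
                             sprintf("s%03d", seq_len(nrow(dosage))))
}

covar_cols <- c("year_of_birth", "contemporary_group", "age_at_joining")

# genomic-control lambda from two-sided normal-reference p-values
gc_lambda <- function(t) median(t^2) / qchisq(0.5, 1)
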