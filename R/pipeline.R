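# End-to-end orchestration: synthetic study -> GRM -> single-trait GWAS ->
# conditional multi-trait selection -> cis/trans eQTL -> SMR -> enrichment
# and validation, with one config, stage toggles, a JSON manifest and
# structured logs.

#' Default pipeline configuration (bundled synthetic demo)
#'
#' Thresholds default to the study design: GWAS GRM MAF 0.01, eQTL MAF 0.05,
#' imputation accuracy 0.4, cis window 2 Mb, trans distance 5 Mb, 100 bp
#' flanks, stepwise p 5e-6 at LD r^2 0.1, eGene alpha 0.01, SMR instrument
#' thresholds 5e-8 (eQTL) and 5e-3 (GWAS), CPM 3 in 25%, 4 expression PCs.
#' The demo simulation is 500 samples, 5 chromosomes x 2,000 variants, 300
#' genes.
#'
#' @param out_dir Output directory for stage files and the manifest.
#' @param seed Integer master seed.
#' @param ... Overrides for any configuration entry (including `sim`, a
#'   [sim_config()]).
#' @return A named list, the `config` argument of [run_pipeline()].
#' @export
demo_config <- function(out_dir = tempfile("pleioqtl_demo_"), seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir,
    seed = as.integer(seed),
    sim = sim_config(seed = seed),
    stages = c("simulate", "grm", "gwas", "cmt", "eqtl_cis", "eqtl_trans",
               "smr", "enrich", "validate"),
    gwas_maf = 0.01, eqtl_maf = 0.05, acc_min = 0.4,
    cis_window_bp = 2e6, trans_min_bp = 5e6, flank_bp = 100,
    stepwise_p = 5e-6, r2_max = 0.1, max_cycles = 10,
    egene_alpha = 0.01, smr_p_eqtl = 5e-8, smr_p_gwas = 5e-3,
    smr_alpha = 0.05,
    cpm_min = 3, cpm_low_prop = 0.25, q_pcs = 4,
    gwas_sig_p = 5e-8, validation_p = 0.002,
    n_random_reps = 5
  )
  modifyList(cfg, list(...))
}

#' Read a pipeline configuration from YAML
#'
#' Scalar entries override [demo_config()] defaults; a `sim` block is passed
#' to [sim_config()].
#'
#' @param path YAML file path.
#' @return A pipeline configuration list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  raw$sim <- NULL
  cfg <- do.call(demo_config, raw)
  cfg$sim <- do.call(sim_config, modifyList(list(seed = cfg$seed), sim_args))
  cfg
}

pipeline_deps <- list(
  simulate = character(), grm = "simulate", gwas = c("simulate", "grm"),
  cmt = c("simulate", "grm", "gwas"),
  eqtl_cis = c("simulate", "grm"),
  eqtl_trans = c("eqtl_cis", "gwas", "cmt"),
  smr = c("eqtl_cis", "gwas"),
  enrich = "eqtl_cis",
  validate = c("gwas", "cmt")
)

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs as
#' plain-text files under `config$out_dir` plus a JSON manifest (seed, stage
#' timings, file digests, filter counts). Any missing stage dependency is
#' reported before any compute. Rerunning with an identical config
#' reproduces every output byte-for-byte.
#'
#' @param config A configuration list from [demo_config()] /
#'   [read_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = demo_config(), quiet = FALSE) {
  stages <- config$stages
  for (st in stages) {
    missing_dep <- setdiff(pipeline_deps[[st]], stages)
    if (length(missing_dep)) {
      abort(sprintf("stage '%s' requires disabled stage(s): %s",
                    st, paste(missing_dep, collapse = ", ")))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(paste0("[pleioqtl] ", sprintf(...)))
  res <- list()
  manifest <- list(seed = config$seed, stages = stages, timing_s = list(),
                   files = list(), counts = list())
  tick <- function(st, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    manifest$timing_s[[st]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say("stage %s done in %.1fs", st, manifest$timing_s[[st]])
    out
  }
  outfile <- function(name) file.path(config$out_dir, name)

  if ("simulate" %in% stages) {
    res$sim <- tick("simulate", {
      geno <- simulate_genotypes(config$sim)
      tr <- simulate_traits(geno, config$sim)
      ex <- simulate_expression(geno, config$sim,
                                cis_window_bp = config$cis_window_bp,
                                trans_min_bp = config$trans_min_bp)
      write_dosage_tsv(geno, outfile("genotypes.tsv"))
      write_traits(tr$traits, outfile("traits.tsv"))
      write_counts(ex$expr, outfile("counts.tsv"))
      write_annotation(ex$expr$annotation, outfile("annotation.tsv"))
      write_truth(tr$truth, outfile("truth.traits"))
      write_truth(ex$truth, outfile("truth.expression"))
      list(geno = geno, traits = tr$traits, trait_truth = tr$truth,
           expr = ex$expr, expr_truth = ex$truth)
    })
  }
  geno <- res$sim$geno
  trait_cols <- config$sim$trait_names

  if ("grm" %in% stages) {
    res$grm <- tick("grm", {
      g <- compute_grm(geno, maf_min = config$gwas_maf)
      write_grm(g, outfile("grm"))
      g
    })
  }

  if ("gwas" %in% stages) {
    res$gwas <- tick("gwas", {
      X <- res$sim$traits[c("year_of_birth", "contemporary_group",
                            "age_at_joining")]
      ctx <- scan_context(geno, res$grm)
      stats <- purrr::map_dfr(trait_cols, function(tc) {
        assoc_scan(geno, res$sim$traits[[tc]], X, res$grm, trait = tc,
                   context = ctx)
      })
      for (tc in trait_cols) {
        write_summary_stats(dplyr::filter(stats, .data$trait == tc),
                            outfile(paste0(tc, ".sumstats.tsv")))
      }
      fdr <- stats |>
        dplyr::group_by(.data$trait) |>
        dplyr::summarise(
          n_sig = sum(.data$p < config$gwas_sig_p),
          n_tested = dplyr::n(),
          fdr = suppressMessages(
            fdr_from_counts(config$gwas_sig_p, max(.data$n_sig, 0), dplyr::n())))
      readr::write_tsv(fdr, outfile("gwas_fdr.tsv"))
      list(stats = stats, fdr = fdr)
    })
  }

  if ("cmt" %in% stages) {
    res$cmt <- tick("cmt", {
      sel <- stepwise_conditional_selection(
        geno, res$sim$traits, res$grm, trait_cols = trait_cols,
        covar_cols = c("year_of_birth", "contemporary_group", "age_at_joining"),
        p_threshold = config$stepwise_p, r2_max = config$r2_max,
        max_cycles = config$max_cycles)
      readr::write_tsv(sel$causal_set, outfile("causal_set.tsv"))
      readr::write_tsv(sel$mgwas, outfile("mgwas.tsv"))
      sel
    })
    manifest$counts$causal_selected <- nrow(res$cmt$causal_set)
  }

  if ("eqtl_cis" %in% stages) {
    res$eqtl_cis <- tick("eqtl_cis", {
      expr <- cpm_filter(res$sim$expr, config$cpm_min, config$cpm_low_prop)
      rec <- map_cis_eqtl(expr, geno, res$grm,
                          window_bp = config$cis_window_bp,
                          q_pcs = config$q_pcs, maf_min = config$eqtl_maf)
      eg <- hierarchical_correction(rec, n_genes_tested = nrow(expr$annotation),
                                    alpha = config$egene_alpha)
      readr::write_tsv(eg$egenes, outfile("cis_egenes.tsv"))
      readr::write_tsv(eg$eqtls, outfile("cis_eqtls.tsv"))
      list(expr = expr, records = rec, egenes = eg,
           epercent = epercent(nrow(eg$egenes), nrow(expr$annotation)))
    })
    manifest$counts$cis_egenes <- nrow(res$eqtl_cis$egenes$egenes)
    manifest$counts$genes_tested <- nrow(res$eqtl_cis$expr$annotation)
  }

  if ("eqtl_trans" %in% stages) {
    res$eqtl_trans <- tick("eqtl_trans", {
      gwas_hits <- unique(c(
        res$gwas$stats$id[res$gwas$stats$p <= config$gwas_sig_p],
        res$cmt$mgwas$id[res$cmt$mgwas$p <= config$gwas_sig_p]))
      ts <- select_trans_test_set(res$eqtl_cis$egenes, gwas_hits, geno,
                                  flank_bp = config$flank_bp)
      tr <- map_trans_eqtl(ts, res$eqtl_cis$expr, geno, res$grm,
                           min_distance_bp = config$trans_min_bp,
                           q_pcs = config$q_pcs, maf_min = config$eqtl_maf,
                           alpha = config$egene_alpha)
      readr::write_tsv(tr$records, outfile("trans_records.tsv"))
      if (!is.null(tr$egenes)) {
        readr::write_tsv(tr$egenes$egenes, outfile("trans_egenes.tsv"))
      }
      c(tr, list(test_set = ts))
    })
  }

  if ("smr" %in% stages) {
    res$smr <- tick("smr", {
      inst <- select_instruments(res$eqtl_cis$egenes, res$gwas$stats,
                                 p_eqtl_max = config$smr_p_eqtl,
                                 p_gwas_max = config$smr_p_gwas)
      smr <- smr_test(inst)
      n_genes <- dplyr::n_distinct(smr$gene_id)
      thr <- if (n_genes > 0) bonferroni_threshold(config$smr_alpha, n_genes)
             else NA_real_
      readr::write_tsv(smr, outfile("smr.tsv"))
      list(results = smr, n_genes_tested = n_genes, threshold = thr)
    })
  }

  if ("enrich" %in% stages) {
    res$enrich <- tick("enrich", {
      ann <- res$sim$expr$annotation
      # synthetic regulatory map: promoter-proximal windows around each TSS
      promo <- tibble(category = "promoter", chrom = ann$chrom,
                      start = pmax(1, ann$tss - 2000), end = ann$tss + 500)
      write_intervals(promo, outfile("regulatory.bed"))
      intervals <- read_intervals(outfile("regulatory.bed"))
      leads <- res$eqtl_cis$egenes$egenes
      bg <- dplyr::distinct(res$eqtl_cis$records, .data$id,
                            .keep_all = TRUE)
      lead_fl <- annotate_variants(leads, intervals)
      bg_fl <- annotate_variants(bg, intervals)
      enr <- hypergeometric_enrichment(lead_fl$promoter, bg_fl$promoter,
                                       "promoter")
      ov <- fisher_gene_overlap(
        leads$gene_id,
        unique(res$sim$expr_truth$egene_truth$gene_id[
          res$sim$expr_truth$egene_truth$scope == "cis"]),
        universe = ann$gene_id)
      readr::write_tsv(enr, outfile("enrichment.tsv"))
      readr::write_tsv(ov, outfile("overlap.tsv"))
      list(enrichment = enr, overlap = ov)
    })
  }

  if ("validate" %in% stages) {
    res$validate <- tick("validate", {
      hits <- unique(c(
        res$gwas$stats$id[res$gwas$stats$p <= config$gwas_sig_p],
        res$cmt$causal_set$id))
      if (!length(hits)) {
        list(retest = NULL, varexp = NULL)
      } else {
        # independent cohort: fresh genotypes, same planted trait effects
        vcfg <- config$sim
        vcfg$seed <- sub_seed(config$seed, 97L)
        vgeno <- simulate_genotypes(vcfg, template = geno)
        vtr <- simulate_traits(vgeno, vcfg,
                               effects = res$sim$trait_truth$causal_variants)
        vgrm <- compute_grm(vgeno, maf_min = config$gwas_maf)
        X <- vtr$traits[c("year_of_birth", "contemporary_group",
                          "age_at_joining")]
        tc1 <- trait_cols[1]
        vstats <- assoc_scan(vgeno, vtr$traits[[tc1]], X, vgrm, trait = tc1)
        hits_in <- intersect(hits, vgeno$variants$id)
        rt <- validation_retest(hits_in, vstats,
                                p_threshold = config$validation_p)
        ve <- variance_explained_subset(vgeno, hits_in, vtr$traits[[tc1]], X,
                                        n_random_reps = config$n_random_reps,
                                        seed = sub_seed(config$seed, 98L))
        readr::write_tsv(rt, outfile("validation_retest.tsv"))
        readr::write_tsv(ve, outfile("variance_explained.tsv"))
        list(retest = rt, varexp = ve)
      }
    })
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(setNames(unname(tools::md5sum(files)),
                                     basename(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  say("pipeline complete: %d stage(s), outputs in %s",
      length(stages), config$out_dir)
  invisible(res)
}
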