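# Genotype IO: VCF v4.2 (GT + DS, imputation accuracy in INFO) and the
# package's dosage-TSV dialect. Internal coordinates are 1-based inclusive
# (VCF convention) throughout.

vcf_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT (rounded dosage) and DS (dosage) per sample, with the
#' imputation-accuracy score in an INFO key (default `DR2`).
#'
#' @param geno A `geno_matrix`.
#' @param path Output path (`.gz` writes gzip).
#' @param accuracy_key INFO key carrying imputation accuracy.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, accuracy_key = "DR2") {
  stopifnot(inherits(geno, "geno_matrix"))
  v <- geno$variants
  con <- vcf_connection(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Imputation accuracy\">",
            accuracy_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    ds <- geno$dosage[, i]
    gt <- gt_codes[pmin(pmax(round(ds), 0), 2) + 1]
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".", "PASS",
            sprintf("%s=%s", accuracy_key, format(v$accuracy[i], digits = 6)),
            "GT:DS", paste0(gt, ":", format(ds, trim = TRUE))),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV with MAF/accuracy filtering
#'
#' Accepts VCF v4.2 (dosages from the DS field when present, hard GT calls
#' otherwise) or the dosage-TSV dialect written by [write_dosage_tsv()].
#' Variants are kept when folded MAF >= `maf_min` and imputation accuracy is
#' strictly greater than `acc_min` (a score of exactly `acc_min` is
#' dropped). Multi-allelic records are skipped with a warning. Filter counts
#' are logged.
#'
#' @param path Input path (gzip transparent).
#' @param maf_min Minimum folded minor-allele frequency (inclusive).
#' @param acc_min Imputation-accuracy threshold (exclusive).
#' @param accuracy_key INFO key holding the accuracy score in VCF input.
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path, maf_min = 0.01, acc_min = 0.4,
                           accuracy_key = "DR2") {
  con <- vcf_connection(path, "r")
  first <- readLines(con, n = 1)
  close(con)
  is_vcf <- startsWith(first, "##fileformat=VCF")
  if (is_vcf) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    if (anyNA(fix$POS) || anyNA(suppressWarnings(as.integer(fix$POS)))) {
      bad <- which(is.na(suppressWarnings(as.integer(fix$POS))))[1]
      abort(sprintf("malformed VCF record at data line %d: bad POS", bad))
    }
    multi <- grepl(",", fix$ALT %||% "")
    if (any(multi)) {
      warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    }
    acc <- suppressWarnings(
      as.numeric(vcfR::extract.info(vcf, element = accuracy_key)))
    acc[is.na(acc)] <- 1
    has_ds <- any(grepl("DS", vcf@gt[, "FORMAT"]))
    if (has_ds) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- matrix(vapply(gt, function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
      }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
    }
    dosage <- t(ds)
    variants <- tibble(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, ":", fix$POS), fix$ID),
      ref = fix$REF, alt = fix$ALT, accuracy = acc
    )
    keep_allelic <- !multi
    dosage <- dosage[, keep_allelic, drop = FALSE]
    variants <- variants[keep_allelic, ]
    sample_ids <- rownames(dosage)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, na = ".",
                           col_types = readr::cols(
                             CHR = readr::col_character(),
                             ID = readr::col_character(),
                             REF = readr::col_character(),
                             ALT = readr::col_character(),
                             .default = readr::col_double()))
    need <- c("CHR", "POS", "ID", "REF", "ALT", "ACC")
    if (!all(need %in% names(tab))) {
      abort(sprintf("dosage TSV must have columns %s", paste(need, collapse = ", ")))
    }
    sample_ids <- setdiff(names(tab), need)
    dosage <- t(as.matrix(tab[sample_ids]))
    variants <- tibble(chrom = as.character(tab$CHR), pos = as.integer(tab$POS),
                       id = tab$ID, ref = tab$REF, alt = tab$ALT,
                       accuracy = tab$ACC)
    rownames(dosage) <- sample_ids
  }
  if (any(dosage < 0 | dosage > 2, na.rm = TRUE)) {
    abort("dosages outside [0, 2] in input")
  }
  freq <- colMeans(dosage, na.rm = TRUE) / 2
  variants$freq <- freq
  variants$maf <- fold_maf(freq)
  n0 <- nrow(variants)
  keep <- variants$maf >= maf_min & variants$accuracy > acc_min
  inform(sprintf("read %d variants; %d dropped by MAF < %g, %d by accuracy <= %g, %d retained",
                 n0, sum(variants$maf < maf_min),
                 maf_min, sum(variants$maf >= maf_min & variants$accuracy <= acc_min),
                 acc_min, sum(keep)))
  variants <- variants[keep, c("chrom", "pos", "id", "ref", "alt", "freq",
                               "maf", "accuracy")]
  dosage <- dosage[, keep, drop = FALSE]
  colnames(dosage) <- variants$id
  new_geno_matrix(dosage, variants, sample_ids)
}

#' Write / read the dosage-TSV dialect
#'
#' Tab-delimited with header: CHR, POS, ID, REF, ALT, ACC, then one column
#' per sample holding dosages in [0, 2] (fractional allowed, '.' missing).
#'
#' @param geno A `geno_matrix`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "geno_matrix"))
  tab <- tibble(CHR = geno$variants$chrom, POS = geno$variants$pos,
                ID = geno$variants$id, REF = geno$variants$ref,
                ALT = geno$variants$alt, ACC = geno$variants$accuracy)
  dos <- as.data.frame(t(geno$dosage))
  names(dos) <- geno$sample_ids
  readr::write_tsv(dplyr::bind_cols(tab, dos), path, na = ".")
  invisible(path)
}
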