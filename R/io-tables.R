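# Tabular IO: BED intervals (0-based half-open at the boundary, 1-based
# inclusive internally), gene annotation, trait tables, summary statistics,
# expression counts. TSVs are tab-delimited, header, UTF-8, '.' for missing.

#' Read labeled regulatory intervals from BED
#'
#' BED is 0-based half-open; internally intervals are 1-based inclusive, so
#' the line `chr1 10 20 H3K4me1` covers 1-based positions 11..20. The BED
#' name column is the interval category. Overlapping intervals of one
#' category are retained as-is (overlap is resolved at query time).
#'
#' @param path BED file path (gzip transparent).
#' @return Tibble: category, chrom, start, end (1-based inclusive).
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  cat_col <- gr$name
  if (is.null(cat_col) || any(is.na(cat_col) | cat_col == "")) {
    abort("BED intervals must carry a non-empty name (category) column")
  }
  out <- tibble(category = as.character(cat_col),
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr))
  if (any(out$start > out$end)) abort("interval with start > end")
  out
}

#' Write intervals back to BED (1-based inclusive -> 0-based half-open)
#'
#' @param intervals Tibble as returned by [read_intervals()].
#' @param path Output BED path.
#' @return `path` invisibly.
#' @export
write_intervals <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    name = intervals$category)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write gene annotation
#'
#' TSV schema: gene_id, chrom, tss (1-based), strand (+/-), start, end
#' (1-based inclusive).
#'
#' @param path File path.
#' @return Tibble of gene annotation.
#' @export
read_annotation <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = ".",
                         col_types = readr::cols(chrom = readr::col_character()))
  need <- c("gene_id", "chrom", "tss", "strand", "start", "end")
  if (!all(need %in% names(tab))) {
    abort(sprintf("annotation must have columns %s", paste(need, collapse = ", ")))
  }
  if (any(tab$start > tab$end)) abort("gene with start > end")
  if (!all(tab$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  tab[need]
}

#' @rdname read_annotation
#' @param annotation Annotation tibble.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path, na = ".")
  invisible(path)
}

# fixed external schema for per-trait summary statistics
SUMSTATS_COLS <- c(CHR = "chrom", POS = "pos", ID = "id", A1 = "a1",
                   A2 = "a2", FREQ = "freq", BETA = "beta", SE = "se",
                   T = "t", P = "p", N = "n")

#' Write / read per-trait GWAS summary statistics
#'
#' External schema (one file per trait): CHR, POS, ID, A1, A2, FREQ, BETA,
#' SE, T, P, N. Doubles survive a round trip at full (15+ significant digit)
#' precision.
#'
#' @param stats Association tibble from [assoc_scan()] (one trait).
#' @param path Output path.
#' @return `write_summary_stats`: `path` invisibly. `read_summary_stats`:
#'   the association tibble (internal lower-case names), with the `trait`
#'   label attached.
#' @export
write_summary_stats <- function(stats, path) {
  missing_cols <- setdiff(unname(SUMSTATS_COLS), names(stats))
  if (length(missing_cols)) {
    abort(sprintf("summary stats missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- stats[unname(SUMSTATS_COLS)]
  names(out) <- names(SUMSTATS_COLS)
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_summary_stats
#' @param trait Trait label to attach on read.
#' @export
read_summary_stats <- function(path, trait = "trait") {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = ".",
                         col_types = readr::cols(
                           CHR = readr::col_character(),
                           ID = readr::col_character(),
                           A1 = readr::col_character(),
                           A2 = readr::col_character()))
  if (!all(names(SUMSTATS_COLS) %in% names(tab))) {
    abort(sprintf("summary stats must have columns %s",
                  paste(names(SUMSTATS_COLS), collapse = ", ")))
  }
  out <- tab[names(SUMSTATS_COLS)]
  names(out) <- unname(SUMSTATS_COLS)
  dplyr::bind_cols(tibble(trait = trait), out)
}

#' Write / read a trait/covariate table ('.' for missing)
#'
#' @param traits Trait tibble (sample_id, trait and covariate columns).
#' @param path File path.
#' @return `path` invisibly / the tibble.
#' @export
write_traits <- function(traits, path) {
  readr::write_tsv(traits, path, na = ".")
  invisible(path)
}

#' @rdname write_traits
#' @export
read_traits <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, na = ".")
}

#' Write / read an expression count matrix (gene x sample TSV)
#'
#' @param expr An `expr_matrix` (write) or file path (read).
#' @param path File path.
#' @param annotation,samples For `read_counts`: annotation tibble and sample
#'   covariate tibble to attach.
#' @return `path` invisibly / an `expr_matrix`.
#' @export
write_counts <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  tab <- dplyr::bind_cols(tibble(gene_id = rownames(expr$counts)),
                          as_tibble(expr$counts))
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, annotation, samples) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  counts <- as.matrix(tab[-1])
  rownames(counts) <- tab$gene_id
  annotation <- annotation[match(tab$gene_id, annotation$gene_id), ]
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  new_expr_matrix(counts, annotation, samples)
}

#' Write simulation ground truth as TSVs
#'
#' @param truth A `sim_truth`.
#' @param path Output path prefix; one TSV per truth component.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  for (nm in names(truth)) {
    readr::write_tsv(truth[[nm]], paste0(path, ".", nm, ".tsv"), na = ".")
  }
  invisible(path)
}
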