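# ggplot2 views of the main result types.

#' Manhattan plot of association results
#'
#' Works for single-trait summary statistics (uses `p`; one panel per trait
#' when several are present) and for multi-trait chi-squared records joined
#' to variant positions.
#'
#' @param stats Tibble with chrom, pos, p (and optionally trait) columns.
#' @param sig_p Significance line (default 5e-8).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(stats, sig_p = 5e-8) {
  stats <- dplyr::mutate(stats, chrom = factor(.data$chrom,
                                               levels = unique(.data$chrom)))
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data$pos,
                                           y = -log10(.data$p),
                                           colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(sig_p), colour = "red",
                        linetype = 2) +
    ggplot2::facet_grid(
      rows = if ("trait" %in% names(stats)) ggplot2::vars(.data$trait) else NULL,
      cols = ggplot2::vars(.data$chrom),
      scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
  p
}

#' Quantile-quantile plot of association p-values
#'
#' The diagnostic for test-statistic inflation: well-calibrated scans track
#' the diagonal (genomic-control lambda near 1).
#'
#' @param stats Tibble with a `p` column (and optionally `trait`).
#' @return A ggplot object.
#' @export
plot_qq <- function(stats) {
  qq <- stats |>
    dplyr::group_by(dplyr::across(dplyr::any_of("trait"))) |>
    dplyr::arrange(.data$p, .by_group = TRUE) |>
    dplyr::mutate(expected = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup()
  ggplot2::ggplot(qq, ggplot2::aes(x = -log10(.data$expected),
                                   y = -log10(.data$p))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.4,
                        ggplot2::aes(colour = if ("trait" %in% names(qq))
                          .data$trait else NULL)) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  colour = "trait") +
    ggplot2::theme_minimal()
}

#' Bar chart of the lead-eQTL TSS-distance profile
#'
#' @param profile Output of [tss_distance_profile()].
#' @return A ggplot object.
#' @export
plot_tss_distance <- function(profile) {
  bins <- dplyr::mutate(profile$bins,
                        bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|distance to TSS| (bp)", y = "proportion of leads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Fold-enrichment bar chart for interval categories
#'
#' @param enrichment Row-bound [hypergeometric_enrichment()] records.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = stats::reorder(.data$category, .data$fold),
                               y = .data$fold)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fold enrichment over background") +
    ggplot2::theme_minimal()
}
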