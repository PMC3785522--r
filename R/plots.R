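#' Probe-level log2-ratio track for one sample
#'
#' Scatter of probe log2 ratios along the genome, faceted by chromosome,
#' with dashed guides at the expected one-copy and homozygous-deletion
#' levels for the given purity and any focal candidates shaded.
#'
#' @param probes Probe tibble (`chrom`, `start`, `log2_ratio`, optionally
#'   `sample_id`).
#' @param sample Sample to plot when `probes` holds several.
#' @param purity Purity used for the guide lines (default 0.8).
#' @param candidates Optional candidate tibble from
#'   [detect_focal_deletions()].
#' @return A ggplot object.
#' @export
plot_probe_track <- function(probes, sample = NULL, purity = 0.8,
                             candidates = NULL) {
  df <- probes
  if (!is.null(sample) && "sample_id" %in% names(df)) {
    df <- df[df$sample_id == sample, , drop = FALSE]
    if (!is.null(candidates) && nrow(candidates) > 0) {
      candidates <- candidates[candidates$sample_id == sample, , drop = FALSE]
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = expected_log2(c(1, 0), purity),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio")
  if (!is.null(candidates) && nrow(candidates) > 0) {
    p <- p + ggplot2::geom_rect(
      data = candidates,
      ggplot2::aes(xmin = .data$inner_start / 1e6,
                   xmax = .data$inner_end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "red", alpha = 0.2
    )
  }
  p
}

#' Per-sample expression of one gene against the cohort
#'
#' Column plot of RPKM across samples with the cohort median marked, the
#' display used to spot marked down-regulation.
#'
#' @param rpkm_mat RPKM tibble from [rpkm()].
#' @param gene Gene to plot.
#' @return A ggplot object.
#' @export
plot_gene_expression <- function(rpkm_mat, gene) {
  row <- rpkm_mat[rpkm_mat$gene == gene, , drop = FALSE]
  if (nrow(row) == 0) stop("gene '", gene, "' absent from matrix",
                           call. = FALSE)
  long <- tidyr::pivot_longer(row[setdiff(names(row), "length")], -"gene",
                              names_to = "sample_id", values_to = "rpkm")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$rpkm)) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::geom_hline(yintercept = stats::median(long$rpkm),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "RPKM", title = gene) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Delta-Ct profile of a classified qPCR tiling
#'
#' @param classified Tibble from [classify_qpcr_copies()].
#' @return A ggplot object.
#' @export
plot_qpcr_profile <- function(classified) {
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$delta_ct,
                               colour = factor(.data$copy_class))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "amplicon midpoint (bp)", y = expression(Delta * Ct),
                  colour = "copy class")
}
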