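#' RPKM normalization of a gene-by-sample count matrix
#'
#' Reads Per Kilobase of exon model per Million mapped reads:
#' `RPKM(g, s) = counts(g, s) * 1e9 / (length(g) * libsize(s))`. Library
#' sizes default to the column sums of the count columns, matching the
#' definition "gene counts / total counts of each sample". The result is
#' invariant under uniform scaling of all counts in a sample and halves when
#' a gene's exon-model length doubles.
#'
#' @param counts Wide tibble: `gene`, `length` (exon-model bp, > 0), one
#'   numeric column per sample.
#' @param library_sizes Optional named numeric vector of per-sample mapped
#'   read totals; defaults to column sums.
#' @return Tibble of the same shape with counts replaced by RPKM.
#' @export
rpkm <- function(counts, library_sizes = NULL) {
  stopifnot(all(c("gene", "length") %in% names(counts)))
  if (any(counts$length <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  samples <- setdiff(names(counts), c("gene", "length"))
  if (length(samples) == 0) stop("no sample columns in `counts`", call. = FALSE)
  m <- as.matrix(counts[samples])
  if (is.null(library_sizes)) {
    library_sizes <- colSums(m)
  } else {
    library_sizes <- library_sizes[samples]
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop("library sizes must be positive and finite", call. = FALSE)
  }
  r <- m * 1e9 / outer(counts$length, library_sizes)
  dplyr::bind_cols(counts[c("gene", "length")], tibble::as_tibble(r))
}

#' Flag samples with outlying low expression of a gene
#'
#' A sample is flagged when its RPKM lies more than `threshold_fold` below
#' the cohort median for that gene, the median being computed with the
#' tested sample left out so a single extreme value cannot mask itself in a
#' small cohort. The 2.5-fold default follows the convention used to screen
#' public glioma cohorts for marked mRNA down-regulation; at 75% purity a
#' homozygously deleted gene retains only the stromal quarter of its diploid
#' dosage and clears the threshold comfortably.
#'
#' @param rpkm_mat RPKM tibble from [rpkm()].
#' @param genes Genes to test (default: all).
#' @param threshold_fold Fold-below-median cutoff (default 2.5, strict).
#' @return Long tibble: `gene`, `sample_id`, `value`, `cohort_median`
#'   (leave-one-out), `fold_below_median`, `flagged`.
#' @export
flag_low_outliers <- function(rpkm_mat, genes = NULL, threshold_fold = 2.5) {
  samples <- setdiff(names(rpkm_mat), c("gene", "length"))
  if (length(samples) < 4) {
    stop("outlier flagging needs at least 4 samples", call. = FALSE)
  }
  if (is.null(genes)) genes <- rpkm_mat$gene
  missing <- setdiff(genes, rpkm_mat$gene)
  if (length(missing) > 0) {
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- rpkm_mat[match(genes, rpkm_mat$gene), c("gene", samples)]
  long <- tidyr::pivot_longer(sub, -"gene", names_to = "sample_id",
                              values_to = "value")
  long |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      cohort_median = purrr::map_dbl(
        seq_along(.data$value),
        function(i) stats::median(.data$value[-i])
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fold_below_median = .data$cohort_median / .data$value,
      flagged = is.finite(.data$cohort_median) & .data$cohort_median > 0 &
        (.data$value == 0 | .data$fold_below_median > threshold_fold)
    )
}

#' Compare expression between two sample groups
#'
#' Per-gene fold change as the ratio of group geometric means of RPKM, and a
#' two-sided t-test on log-scaled values (natural log of RPKM + 0.5; the
#' pseudocount keeps zeros finite). Raw p-values are Bonferroni-adjusted
#' across the tested gene set. The pooled-variance test is the default;
#' Welch is available via `var_equal = FALSE`.
#'
#' @param rpkm_mat RPKM tibble from [rpkm()].
#' @param group_a,group_b Disjoint character vectors of sample columns; the
#'   fold change is geometric-mean(a) / geometric-mean(b).
#' @param genes Genes to test (default: all).
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) t-test.
#' @param pseudocount Added to RPKM before taking logs.
#' @return Tibble: `gene`, `fold_change`, `log2_fold_change`, `p_raw`,
#'   `p_adj`, `degenerate` (TRUE when both groups had zero variance with
#'   unequal means, p reported as its limit 0).
#' @export
compare_expression <- function(rpkm_mat, group_a, group_b, genes = NULL,
                               var_equal = TRUE, pseudocount = 0.5) {
  samples <- setdiff(names(rpkm_mat), c("gene", "length"))
  if (length(intersect(group_a, group_b)) > 0) {
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), samples)
  if (length(missing) > 0) {
    stop("sample(s) absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(genes)) genes <- rpkm_mat$gene
  sub <- rpkm_mat[match(genes, rpkm_mat$gene), , drop = FALSE]
  a <- as.matrix(sub[group_a])
  b <- as.matrix(sub[group_b])
  la <- log(a + pseudocount)
  lb <- log(b + pseudocount)
  res <- purrr::map_dfr(seq_along(genes), function(i) {
    xa <- la[i, ]; xb <- lb[i, ]
    va <- stats::var(xa); vb <- stats::var(xb)
    degenerate <- (va == 0 && vb == 0)
    if (degenerate) {
      p <- if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
    } else {
      p <- stats::t.test(xa, xb, var.equal = var_equal)$p.value
    }
    gm <- function(x) exp(mean(log(x)))
    fc <- if (all(a[i, ] > 0) && all(b[i, ] > 0)) {
      gm(a[i, ]) / gm(b[i, ])
    } else {
      gm(a[i, ] + pseudocount) / gm(b[i, ] + pseudocount)
    }
    tibble::tibble(gene = genes[i], fold_change = fc,
                   log2_fold_change = log2(fc), p_raw = p,
                   degenerate = degenerate)
  })
  res$p_adj <- adjust_pvalues(res$p_raw, method = "bonferroni")
  res[c("gene", "fold_change", "log2_fold_change", "p_raw", "p_adj",
        "degenerate")]
}

#' Report genes overlapped by and adjacent to focal-deletion candidates
#'
#' Genes overlapping a candidate's inner extent (the outermost deleted
#' probes) are labeled `"deleted"` — a gene only partially inside still
#' loses the spanned exons. Genes whose only overlap is with the breakpoint
#' uncertainty gap between inner and outer extent are `"ambiguous"`; genes
#' clear of the outer extent are `"adjacent"`. When an RPKM matrix is
#' supplied, each gene additionally gets its fold-vs-leave-one-out-median in
#' the candidate's sample and a direction.
#'
#' @param candidates Tibble from [detect_focal_deletions()].
#' @param annotation Gene table: `gene`, `chrom`, `start`, `end`.
#' @param rpkm_mat Optional RPKM tibble from [rpkm()].
#' @return Tibble: candidate sample/locus, `gene`, `label`, and (with
#'   expression) `fold_vs_median`, `direction` (down/up/flat).
#' @export
neighbor_gene_report <- function(candidates, annotation, rpkm_mat = NULL) {
  if (nrow(candidates) == 0) return(tibble::tibble(
    sample_id = character(), chrom = character(), gene = character(),
    label = character()
  ))
  out <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    ann <- annotation[chrom_label(annotation$chrom) == chrom_label(cand$chrom), ]
    if (nrow(ann) == 0) return(NULL)
    outer_start <- ifelse(is.na(cand$outer_start), -Inf, cand$outer_start)
    outer_end <- ifelse(is.na(cand$outer_end), Inf, cand$outer_end)
    in_inner <- ann$start <= cand$inner_end & ann$end >= cand$inner_start
    in_outer <- ann$start <= outer_end & ann$end >= outer_start
    label <- dplyr::case_when(in_inner ~ "deleted",
                              in_outer ~ "ambiguous",
                              TRUE ~ "adjacent")
    tibble::tibble(sample_id = cand$sample_id, chrom = cand$chrom,
                   inner_start = cand$inner_start, inner_end = cand$inner_end,
                   gene = ann$gene, label = label)
  })
  if (nrow(out) == 0 || is.null(rpkm_mat)) return(out)
  flags <- flag_low_outliers(rpkm_mat, genes = intersect(out$gene, rpkm_mat$gene))
  out <- dplyr::left_join(out, flags[c("gene", "sample_id", "fold_below_median")],
                          by = c("gene", "sample_id"))
  dplyr::mutate(out,
    fold_vs_median = 1 / .data$fold_below_median,
    direction = dplyr::case_when(
      is.na(.data$fold_vs_median) ~ NA_character_,
      .data$fold_vs_median < 1 / 1.5 ~ "down",
      .data$fold_vs_median > 1.5 ~ "up",
      TRUE ~ "flat"
    )
  )
}
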