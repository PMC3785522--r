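#' Detect focal homozygous-deletion candidates on lost arms
#'
#' Scans each loss-called arm for runs of consecutive probes whose log2
#' ratio is compatible with copy state 0 at the sample's purity: probes with
#' `L <= expected_log2(0, purity) + tol` while the arm baseline sits at the
#' one-copy level. The default `min_probes = 2` deliberately goes below the
#' five-probe convention of vendor aberration callers: exon-scale deletions
#' spanning only one or two probes are exactly the events such callers miss,
#' so short candidates are admitted but marked as requiring corroboration
#' (for example by an expression outlier or qPCR).
#'
#' Extents follow the convention of printed breakpoint bounds: the inner
#' extent runs from the start of the first to the end of the last deleted
#' probe, the outer extent from the end of the innermost retained probe on
#' the 5' side to the start of the innermost retained probe on the 3' side.
#' Extent sizes in bp are coordinate differences (`end - start`), i.e.
#' breakpoint-to-breakpoint distances.
#'
#' @param probes Probe tibble with `chrom`, `start`, `end`, `probe_id`,
#'   `arm`, `log2_ratio` (optionally `sample_id`).
#' @param arm_calls Tibble from [call_arm_states()].
#' @param purity Single purity, or the tibble returned by
#'   [estimate_purity()] when probes carry multiple samples.
#' @param tol Log2 tolerance above the copy-0 expectation (default 0.3).
#' @param min_probes Minimum run length to report a candidate (default 2;
#'   set to 1 to admit single-probe events).
#' @param annotation Optional gene table (`gene`, `chrom`, `start`, `end`)
#'   used to list genes overlapping each candidate's inner extent.
#' @return Tibble of candidates: inner/outer extent coordinates, spans in
#'   bp, `n_probes`, `mean_log2`, `arm_baseline`, `requires_corroboration`
#'   (TRUE when `n_probes < 5`), and `genes` when annotated. Zero rows when
#'   nothing is found.
#' @export
detect_focal_deletions <- function(probes, arm_calls, purity, tol = 0.3,
                                   min_probes = 2, annotation = NULL) {
  stopifnot(all(c("chrom", "start", "end", "arm", "log2_ratio") %in% names(probes)))
  grp <- intersect("sample_id", names(probes))
  empty <- tibble::tibble(
    sample_id = character(), chrom = character(), arm = character(),
    inner_start = numeric(), inner_end = numeric(), inner_span_bp = numeric(),
    outer_start = numeric(), outer_end = numeric(), outer_span_bp = numeric(),
    n_probes = integer(), mean_log2 = numeric(), arm_baseline = numeric(),
    requires_corroboration = logical(), genes = character()
  )

  purity_for <- function(id) {
    if (is.data.frame(purity)) {
      if ("sample_id" %in% names(purity)) {
        p <- purity$purity[purity$sample_id == id]
        if (length(p) == 0) stop("no purity for sample ", id, call. = FALSE)
        p[1]
      } else {
        purity$purity[1]
      }
    } else {
      purity
    }
  }

  one_arm <- function(prb, baseline, f, id) {
    prb <- prb[order(prb$start), , drop = FALSE]
    thr <- expected_log2(0, f) + tol
    flag <- prb$log2_ratio <= thr
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values & r$lengths >= min_probes)
    if (length(keep) == 0) return(NULL)
    purrr::map_dfr(keep, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      inner_start <- prb$start[i0]
      inner_end <- prb$end[i1]
      outer_start <- if (i0 > 1) prb$end[i0 - 1] else NA_real_
      outer_end <- if (i1 < nrow(prb)) prb$start[i1 + 1] else NA_real_
      genes <- NA_character_
      if (!is.null(annotation)) {
        ann <- annotation[chrom_label(annotation$chrom) ==
                            chrom_label(prb$chrom[1]), , drop = FALSE]
        hit <- ann$start <= inner_end & ann$end >= inner_start
        genes <- if (any(hit)) paste(ann$gene[hit], collapse = ",") else NA_character_
      }
      tibble::tibble(
        sample_id = id, chrom = as.character(prb$chrom[1]),
        arm = as.character(prb$arm[1]),
        inner_start = inner_start, inner_end = inner_end,
        inner_span_bp = inner_end - inner_start,
        outer_start = outer_start, outer_end = outer_end,
        outer_span_bp = outer_end - outer_start,
        n_probes = i1 - i0 + 1L,
        mean_log2 = mean(prb$log2_ratio[i0:i1]),
        arm_baseline = baseline,
        requires_corroboration = (i1 - i0 + 1L) < 5L,
        genes = genes
      )
    })
  }

  one_sample <- function(prb, calls, id) {
    loss <- calls[calls$state == "loss", , drop = FALSE]
    if (nrow(loss) == 0) return(NULL)
    f <- purity_for(id)
    purrr::map_dfr(seq_len(nrow(loss)), function(i) {
      a <- as.character(loss$arm[i])
      res <- one_arm(prb[prb$arm == a, , drop = FALSE],
                     loss$median_log2[i], f, id)
      res
    })
  }

  out <- if (length(grp) == 1) {
    ids <- unique(probes$sample_id)
    purrr::map_dfr(ids, function(id) {
      one_sample(probes[probes$sample_id == id, , drop = FALSE],
                 arm_calls[arm_calls$sample_id == id, , drop = FALSE], id)
    })
  } else {
    one_sample(tibble::as_tibble(probes), arm_calls, NA_character_)
  }
  if (is.null(out) || nrow(out) == 0) return(empty)
  out
}
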