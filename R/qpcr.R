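#' Classify per-amplicon copy state from qPCR Ct values
#'
#' With perfect amplification efficiency the Ct difference of the tumor
#' against a two-copy reference estimates relative template dosage as
#' `2^(-dCt)`. Under the purity mixture the expected dCt for tumor copy
#' state `c` is `log2(2 / ((1 - f) * 2 + f * c))`; each amplicon is assigned
#' the class (0, 1 or 2) whose expectation is nearest the observed dCt, with
#' boundaries at the midpoints. A one-copy reference sample, when named,
#' serves as a calibration check: its observed dCt must sit within
#' `calibration_tol` cycles of the class-1 expectation, else a warning is
#' raised. Missing Ct values ("no amplification") are classified 0 and
#' flagged.
#'
#' @param qpcr Tibble: `sample_id`, `amplicon_id`, `chrom`, `start`, `end`,
#'   `ct` (NA = no amplification).
#' @param sample Tumor sample to classify.
#' @param ref2 Sample id of the two-copy reference.
#' @param ref1 Optional sample id of a one-copy reference (consistency
#'   check only; its own purity is assumed equal to `purity` unless
#'   `ref1_purity` is given).
#' @param purity Tumor purity of `sample`, in `(0, 1]`.
#' @param ref1_purity Purity assumed for the one-copy reference.
#' @param calibration_tol Allowed deviation (cycles) of the one-copy
#'   reference from its model prediction.
#' @return Tibble of the tumor's amplicons with `delta_ct`, `copy_class`
#'   (integer 0/1/2) and `no_amplification` flag, ordered by position.
#' @export
classify_qpcr_copies <- function(qpcr, sample, ref2, ref1 = NULL,
                                 purity, ref1_purity = purity,
                                 calibration_tol = 0.5) {
  need <- c("sample_id", "amplicon_id", "chrom", "start", "end", "ct")
  stopifnot(all(need %in% names(qpcr)))
  check_purity(purity)
  ref2_ct <- qpcr[qpcr$sample_id == ref2, c("amplicon_id", "ct")]
  if (nrow(ref2_ct) == 0) stop("two-copy reference '", ref2,
                               "' absent from qPCR table", call. = FALSE)
  if (any(!is.finite(ref2_ct$ct))) {
    stop("two-copy reference Ct values must be finite", call. = FALSE)
  }
  names(ref2_ct)[2] <- "ref2_ct"

  expected_dct <- function(c, f) log2(2 / ((1 - f) * 2 + f * c))

  tum <- qpcr[qpcr$sample_id == sample, , drop = FALSE]
  if (nrow(tum) == 0) stop("sample '", sample, "' absent from qPCR table",
                           call. = FALSE)
  tum <- dplyr::inner_join(tibble::as_tibble(tum), ref2_ct,
                           by = "amplicon_id")
  tum$delta_ct <- tum$ct - tum$ref2_ct
  exp_dct <- expected_dct(0:2, purity)   # class 0 may be +Inf at f = 1
  mids <- c((exp_dct[1] + exp_dct[2]) / 2, (exp_dct[2] + exp_dct[3]) / 2)
  tum$no_amplification <- !is.finite(tum$ct)
  tum$copy_class <- dplyr::case_when(
    tum$no_amplification ~ 0L,
    tum$delta_ct >= mids[1] ~ 0L,
    tum$delta_ct >= mids[2] ~ 1L,
    TRUE ~ 2L
  )

  if (!is.null(ref1)) {
    r1 <- qpcr[qpcr$sample_id == ref1, c("amplicon_id", "ct")]
    r1 <- dplyr::inner_join(r1, ref2_ct, by = "amplicon_id")
    obs <- stats::median(r1$ct - r1$ref2_ct, na.rm = TRUE)
    pred <- expected_dct(1, ref1_purity)
    if (is.finite(obs) && abs(obs - pred) > calibration_tol) {
      warning(sprintf(
        "one-copy reference dCt %.2f deviates from model prediction %.2f by > %.2f cycles",
        obs, pred, calibration_tol), call. = FALSE)
    }
  }
  tum[order(tum$start), c("sample_id", "amplicon_id", "chrom", "start",
                          "end", "ct", "delta_ct", "copy_class",
                          "no_amplification")]
}

#' Refine deletion breakpoints from classified qPCR amplicons
#'
#' For each contiguous run of deleted (class-0) amplicons along the tiling,
#' the 5' breakpoint is localized to the gap between the end of the last
#' retained amplicon and the start of the first deleted one, and the 3'
#' breakpoint symmetrically. The minimum deletion extent spans first-deleted
#' start to last-deleted end; the maximum spans the outer bounds of the two
#' uncertainty gaps. Extents are coordinate differences (`end - start`,
#' breakpoint-to-breakpoint distances). Runs touching the edge of the
#' tiling have no flanking retained amplicon on that side and are flagged
#' unbounded, with `NA` outer bounds.
#'
#' @param classified Tibble from [classify_qpcr_copies()] (one sample,
#'   single chromosome, any order; sorted internally by `start`).
#' @return Tibble with one row per deleted run: `five_prime_start/end`,
#'   `three_prime_start/end` (the uncertainty intervals), `min_extent_bp`,
#'   `max_extent_bp`, `unbounded_5p`, `unbounded_3p`, `n_deleted_amplicons`.
#'   Zero rows when no amplicon is deleted.
#' @export
refine_breakpoints <- function(classified) {
  need <- c("chrom", "start", "end", "copy_class")
  stopifnot(all(need %in% names(classified)))
  if (length(unique(classified$chrom)) > 1) {
    stop("breakpoint refinement expects amplicons on a single chromosome",
         call. = FALSE)
  }
  empty <- tibble::tibble(
    chrom = character(), five_prime_start = numeric(),
    five_prime_end = numeric(), three_prime_start = numeric(),
    three_prime_end = numeric(), min_extent_bp = numeric(),
    max_extent_bp = numeric(), unbounded_5p = logical(),
    unbounded_3p = logical(), n_deleted_amplicons = integer()
  )
  amp <- classified[order(classified$start), , drop = FALSE]
  del <- amp$copy_class == 0L
  if (!any(del)) return(empty)
  r <- rle(del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  purrr::map_dfr(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    ub5 <- i0 == 1
    ub3 <- i1 == nrow(amp)
    five_start <- if (ub5) NA_real_ else amp$end[i0 - 1]
    five_end <- amp$start[i0]
    three_start <- amp$end[i1]
    three_end <- if (ub3) NA_real_ else amp$start[i1 + 1]
    tibble::tibble(
      chrom = as.character(amp$chrom[1]),
      five_prime_start = five_start, five_prime_end = five_end,
      three_prime_start = three_start, three_prime_end = three_end,
      min_extent_bp = three_start - five_end,
      max_extent_bp = three_end - five_start,
      unbounded_5p = ub5, unbounded_3p = ub3,
      n_deleted_amplicons = i1 - i0 + 1L
    )
  })
}
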