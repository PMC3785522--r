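#' Assign chromosome-arm labels to probes
#'
#' Splits probes into p and q arms at per-chromosome centromere positions.
#' Probes whose interval starts at or before the centromere belong to the p
#' arm. Chromosome labels are normalized by stripping a leading `"chr"` so
#' that arm labels read `"1p"`, `"19q"`, ...
#'
#' @param probes Data frame with at least `chrom` and `start` columns.
#' @param centromeres Data frame with `chrom` and `centromere` (bp) columns.
#' @return `probes` with an `arm` character column appended.
#' @export
assign_arms <- function(probes, centromeres) {
  stopifnot(all(c("chrom", "start") %in% names(probes)),
            all(c("chrom", "centromere") %in% names(centromeres)))
  cen <- setNames(centromeres$centromere, chrom_label(centromeres$chrom))
  lab <- chrom_label(probes$chrom)
  missing <- setdiff(unique(lab), names(cen))
  if (length(missing) > 0) {
    stop("no centromere position for chromosome(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  side <- ifelse(probes$start <= cen[lab], "p", "q")
  dplyr::mutate(tibble::as_tibble(probes), arm = paste0(lab, side))
}

chrom_label <- function(chrom) sub("^chr", "", as.character(chrom))

#' Call per-arm copy-number states from probe log2 ratios
#'
#' The median log2 ratio of each chromosome arm is thresholded into
#' loss / neutral / gain. With tumor purity of 0.8 or more, a true one-copy
#' arm sits near -0.7 or below, so the default loss cutoff of -0.3 is
#' conservative; both cutoffs are exposed. Arms covered by fewer than
#' `min_probes` probes are dropped with a warning rather than called.
#'
#' @param probes Probe data frame with `arm` and `log2_ratio` columns
#'   (see [assign_arms()]); an optional `sample_id` column groups calls.
#' @param loss_threshold Call loss when the arm median is at or below this.
#' @param gain_threshold Call gain when the arm median is at or above this.
#' @param min_probes Minimum probes required to call an arm.
#' @return Tibble with one row per (sample,) arm: `n_probes`, `median_log2`,
#'   `state` (factor loss/neutral/gain).
#' @export
call_arm_states <- function(probes, loss_threshold = -0.3,
                            gain_threshold = 0.25, min_probes = 5) {
  stopifnot(all(c("arm", "log2_ratio") %in% names(probes)))
  stopifnot(loss_threshold < gain_threshold)
  grp <- intersect("sample_id", names(probes))
  calls <- probes |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "arm")))) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      median_log2 = stats::median(.data$log2_ratio),
      .groups = "drop"
    )
  thin <- calls$n_probes < min_probes
  if (any(thin)) {
    warning(sprintf("%d arm(s) with fewer than %d probes left uncalled",
                    sum(thin), min_probes), call. = FALSE)
    calls <- calls[!thin, , drop = FALSE]
  }
  calls |>
    dplyr::mutate(state = factor(
      dplyr::case_when(
        .data$median_log2 <= loss_threshold ~ "loss",
        .data$median_log2 >= gain_threshold ~ "gain",
        TRUE ~ "neutral"
      ),
      levels = c("loss", "neutral", "gain")
    ))
}

#' Classify the genetic subtype of each sample from its arm calls
#'
#' The defining lesion of the "oligodendroglial" (oligo) subtype is combined
#' loss of 1p and 19q; it takes precedence over everything else. Samples
#' without the co-deletion but with a whole-chromosome-7 gain (with or
#' without chromosome-10 loss) are "astro"; everything else is "other".
#' Arms absent from the calls are treated as neutral, with a warning.
#'
#' @param arm_calls Tibble from [call_arm_states()].
#' @return Tibble with `subtype` (factor oligo/astro/other) per sample, or a
#'   single-row tibble when `arm_calls` carries no `sample_id`.
#' @export
classify_subtype <- function(arm_calls) {
  stopifnot(all(c("arm", "state") %in% names(arm_calls)))
  grp <- intersect("sample_id", names(arm_calls))
  one <- function(df) {
    state_of <- function(a) {
      s <- df$state[df$arm == a]
      if (length(s) == 0) "neutral" else as.character(s[1])
    }
    needed <- c("1p", "19q", "7p", "7q", "10p", "10q")
    absent <- setdiff(needed, df$arm)
    if (length(absent) > 0) {
      warning("arm(s) ", paste(absent, collapse = ", "),
              " absent from calls; treated as neutral", call. = FALSE)
    }
    oligo <- state_of("1p") == "loss" && state_of("19q") == "loss"
    chr7_gain <- state_of("7p") == "gain" && state_of("7q") == "gain"
    if (oligo) "oligo" else if (chr7_gain) "astro" else "other"
  }
  out <- if (length(grp) == 1) {
    arm_calls |>
      tibble::as_tibble() |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_modify(~ tibble::tibble(subtype = one(.x))) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(subtype = one(arm_calls))
  }
  dplyr::mutate(out, subtype = factor(.data$subtype,
                                      levels = c("oligo", "astro", "other")))
}

#' Estimate tumor purity from probes on lost arms
#'
#' Every probe on a loss-called arm is inverted through the mixture model
#' assuming one remaining copy ([infer_purity()] with `copies = 1`); the
#' per-probe purities are clipped into `(0, 1]` and summarized by their
#' median. Samples without any loss arm fall back to `default_purity` and
#' are flagged `"assumed"`.
#'
#' @param arm_calls Tibble from [call_arm_states()].
#' @param probes Probe tibble with `arm` and `log2_ratio` (and matching
#'   `sample_id` if grouped).
#' @param default_purity Fallback purity when no arm is lost; anchored to the
#'   cohorts this model targets, whose histological tumor content is >= 80%.
#' @return Tibble with `purity`, `basis` (`"estimated"` or `"assumed"`) and
#'   `n_probes` used, per sample.
#' @export
estimate_purity <- function(arm_calls, probes, default_purity = 0.8) {
  stopifnot(all(c("arm", "state") %in% names(arm_calls)),
            all(c("arm", "log2_ratio") %in% names(probes)))
  grp <- intersect("sample_id", names(arm_calls))
  one <- function(calls, prb) {
    loss_arms <- as.character(calls$arm[calls$state == "loss"])
    if (length(loss_arms) == 0) {
      return(tibble::tibble(purity = default_purity, basis = "assumed",
                            n_probes = 0L))
    }
    L <- prb$log2_ratio[prb$arm %in% loss_arms]
    # per-probe inversion at c = 1; noisy probes can imply f outside (0, 1]
    f <- (2 - 2^(L + 1)) / (2 - 1)
    f <- pmin(pmax(f, 1e-6), 1)
    tibble::tibble(purity = stats::median(f), basis = "estimated",
                   n_probes = length(L))
  }
  if (length(grp) == 1) {
    ids <- unique(arm_calls$sample_id)
    purrr::map_dfr(ids, function(id) {
      dplyr::bind_cols(
        tibble::tibble(sample_id = id),
        one(arm_calls[arm_calls$sample_id == id, , drop = FALSE],
            probes[probes$sample_id == id, , drop = FALSE])
      )
    })
  } else {
    one(arm_calls, probes)
  }
}
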