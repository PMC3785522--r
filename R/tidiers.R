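#' Tidy an association-test result
#'
#' @param x An `assoc_result` from [fisher_exact()].
#' @param ... Unused.
#' @return One-row tibble: `estimate` (odds ratio), `p.value`, `method`.
#' @export
tidy.assoc_result <- function(x, ...) {
  tibble::tibble(estimate = x$odds_ratio, p.value = x$p_value,
                 method = x$method)
}

#' @rdname tidy.assoc_result
#' @export
glance.assoc_result <- function(x, ...) tidy.assoc_result(x)

#' Tidy a Mann-Whitney U result
#'
#' @param x An `mwu_result` from [mann_whitney_u()].
#' @param ... Unused.
#' @return One-row tibble: `statistic` (U), `p.value`, `method`.
#' @export
tidy.mwu_result <- function(x, ...) {
  tibble::tibble(statistic = x$U, p.value = x$p_value, method = x$method)
}

#' Tidy methods for cohort reports
#'
#' `tidy()` returns the per-sample rows; `glance()` a one-row tibble of the
#' cohort tallies.
#'
#' @param x A `cohort_report` from [build_cohort_report()].
#' @param ... Unused.
#' @export
tidy.cohort_report <- function(x, ...) x$per_sample

#' @rdname tidy.cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  t <- x$tallies
  tibble::tibble(
    n_samples = t$n_samples,
    n_oligo = unname(t$n_by_subtype["oligo"]),
    n_astro = unname(t$n_by_subtype["astro"]),
    n_other = unname(t$n_by_subtype["other"]),
    n_idh1 = t$n_idh1,
    idh1_fraction = t$idh1_fraction,
    n_cic_somatic_snv_codeleted = t$n_cic_somatic_snv_codeleted,
    cic_somatic_snv_codeleted_fraction = t$cic_somatic_snv_codeleted_fraction,
    n_cic_protein_altering_codeleted = t$n_cic_protein_altering_codeleted,
    cic_protein_altering_codeleted_fraction =
      t$cic_protein_altering_codeleted_fraction,
    n_fubp1_somatic = t$n_fubp1_somatic,
    fubp1_somatic_fraction = t$fubp1_somatic_fraction
  )
}

#' Glance at a pipeline result
#'
#' @param x A `twohit_result` from [run_twohit_pipeline()].
#' @param ... Unused.
#' @return One-row tibble summarizing sample, candidate and call counts.
#' @export
glance.twohit_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$subtypes),
    n_oligo = sum(x$subtypes$subtype == "oligo"),
    n_candidates = nrow(x$candidates),
    n_calls_confirmed = sum(x$calls$confidence == "confirmed"),
    n_calls_total = nrow(x$calls)
  )
}
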