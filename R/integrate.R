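#' Default genes of interest for two-hit calling
#'
#' The tumor suppressors targeted by the 1p/19q co-deletion: CIC on 19q and
#' FUBP1 on 1p. The calling machinery is gene-agnostic; pass your own table
#' to target other loci.
#'
#' @return Tibble: `gene`, `arm`.
#' @export
default_genes_of_interest <- function() {
  tibble::tibble(gene = c("CIC", "FUBP1"), arm = c("19q", "1p"))
}

#' Integrate copy-number, mutation and expression evidence into two-hit calls
#'
#' For each sample and gene of interest whose chromosome arm is lost
#' (hit 1), a second hit is sought in two forms: a damaging somatic point
#' mutation, or a focal homozygous-deletion candidate overlapping the gene.
#' A mutation hit is confirmed directly; a truncating mutation accompanied
#' by a low-expression flag is annotated as consistent with
#' nonsense-mediated decay. A focal-deletion hit is confirmed when the
#' candidate spans at least `min_probes_confirm` probes or carries an
#' expression corroboration; short uncorroborated candidates stay at
#' `"candidate"` confidence. Samples without arm loss are never called on
#' that gene.
#'
#' @param arm_calls Multi-sample tibble from [call_arm_states()].
#' @param candidates Tibble from [detect_focal_deletions()].
#' @param outliers Tibble from [flag_low_outliers()].
#' @param mutations Tibble from [classify_mutations()] (may have 0 rows).
#' @param genes Genes of interest (`gene`, `arm`);
#'   see [default_genes_of_interest()].
#' @param min_probes_confirm Probe support above which a focal candidate is
#'   confirmed without corroboration.
#' @return Tibble of class `twohit_calls`: `sample_id`, `gene`, `hit1_arm`,
#'   `hit1_median_log2`, `hit2_type`, `hit2_evidence`,
#'   `expression_corroboration`, `nmd_consistent`, `confidence`.
#' @export
call_two_hits <- function(arm_calls, candidates, outliers, mutations,
                          genes = default_genes_of_interest(),
                          min_probes_confirm = 5) {
  stopifnot("sample_id" %in% names(arm_calls))
  known <- unique(arm_calls$sample_id)
  for (tbl in list(candidates, mutations)) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      stray <- setdiff(unique(tbl$sample_id), c(known, NA))
      if (length(stray) > 0) {
        stop("inputs carry sample ids absent from arm calls: ",
             paste(stray, collapse = ", "), call. = FALSE)
      }
    }
  }
  flagged <- function(id, gene) {
    if (is.null(outliers) || nrow(outliers) == 0) return(FALSE)
    any(outliers$sample_id == id & outliers$gene == gene & outliers$flagged)
  }
  rows <- purrr::map_dfr(known, function(id) {
    calls <- arm_calls[arm_calls$sample_id == id, ]
    purrr::map_dfr(seq_len(nrow(genes)), function(g) {
      gene <- genes$gene[g]; arm <- genes$arm[g]
      ac <- calls[calls$arm == arm, ]
      if (nrow(ac) == 0 || ac$state[1] != "loss") return(NULL)
      out <- NULL
      if (!is.null(mutations) && nrow(mutations) > 0) {
        mut <- mutations[mutations$sample_id == id & mutations$gene == gene &
                           mutations$somatic &
                           !is.na(mutations$damaging) & mutations$damaging &
                           mutations$consequence != "exon_spanning_deletion", ]
        if (nrow(mut) > 0) {
          corroborated <- flagged(id, gene)
          nmd <- mut$consequence[1] %in% truncating_classes && corroborated
          out <- dplyr::bind_rows(out, tibble::tibble(
            sample_id = id, gene = gene, hit1_arm = arm,
            hit1_median_log2 = ac$median_log2[1],
            hit2_type = "mutation", hit2_evidence = mut$hgvs_c[1],
            expression_corroboration = corroborated,
            nmd_consistent = nmd, confidence = "confirmed"
          ))
        }
      }
      if (!is.null(candidates) && nrow(candidates) > 0) {
        cand <- candidates[candidates$sample_id == id &
                             !is.na(candidates$genes) &
                             purrr::map_lgl(candidates$genes, function(s) {
                               gene %in% strsplit(s, ",")[[1]]
                             }), ]
        if (nrow(cand) > 0) {
          corroborated <- flagged(id, gene)
          conf <- if (cand$n_probes[1] >= min_probes_confirm || corroborated) {
            "confirmed"
          } else {
            "candidate"
          }
          out <- dplyr::bind_rows(out, tibble::tibble(
            sample_id = id, gene = gene, hit1_arm = arm,
            hit1_median_log2 = ac$median_log2[1],
            hit2_type = "focal_deletion",
            hit2_evidence = sprintf("%s:%.0f-%.0f (%d probes)",
                                    cand$chrom[1], cand$inner_start[1],
                                    cand$inner_end[1], cand$n_probes[1]),
            expression_corroboration = corroborated,
            nmd_consistent = FALSE, confidence = conf
          ))
        }
      }
      out
    })
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      sample_id = character(), gene = character(), hit1_arm = character(),
      hit1_median_log2 = numeric(), hit2_type = character(),
      hit2_evidence = character(), expression_corroboration = logical(),
      nmd_consistent = logical(), confidence = character()
    )
  }
  class(rows) <- c("twohit_calls", class(rows))
  rows
}

#' Build a Table-1-style cohort report
#'
#' Combines per-sample annotations with classified mutations into a
#' per-sample overview and the cohort tallies the field reports: subtype
#' counts, IDH1 mutation fraction, somatic CIC SNV fraction among
#' 1p/19q-codeleted tumors, protein-altering CIC event fraction (point
#' mutations plus exon-spanning deletions), somatic FUBP1 fraction, and the
#' consequence breakdown of codeleted somatic CIC SNVs.
#'
#' @param sample_info Tibble: `sample_id`, `histology` ("O"/"OA"),
#'   `who_grade`, `subtype` (oligo/astro/other), `idh1_mutant` (logical).
#' @param classified_mutations Tibble from [classify_mutations()].
#' @return Object of class `cohort_report`: list with `per_sample`,
#'   `tallies` (named list) and `consequence_breakdown` (tibble).
#' @export
build_cohort_report <- function(sample_info, classified_mutations) {
  stopifnot(all(c("sample_id", "subtype") %in% names(sample_info)))
  info <- tibble::as_tibble(sample_info)
  mut <- classified_mutations
  has_record <- function(id, gene, pred) {
    if (is.null(mut) || nrow(mut) == 0) return(FALSE)
    rows <- mut[mut$sample_id == id & mut$gene == gene, , drop = FALSE]
    nrow(rows) > 0 && any(pred(rows))
  }
  snv_classes <- c("missense", "nonsense", "frameshift", "splice_site",
                   "silent", "intronic")
  per_sample <- info |>
    dplyr::mutate(
      codeleted = .data$subtype == "oligo",
      cic_somatic_snv = purrr::map_lgl(.data$sample_id, has_record, "CIC",
        function(r) r$somatic & r$consequence %in% snv_classes),
      cic_deletion = purrr::map_lgl(.data$sample_id, has_record, "CIC",
        function(r) r$consequence == "exon_spanning_deletion"),
      cic_protein_altering = purrr::map_lgl(.data$sample_id, has_record, "CIC",
        function(r) r$somatic &
          (r$consequence == "exon_spanning_deletion" |
             (!is.na(r$damaging) & r$damaging))),
      fubp1_somatic = purrr::map_lgl(.data$sample_id, has_record, "FUBP1",
        function(r) r$somatic)
    ) |>
    dplyr::mutate(cic_somatic = .data$cic_somatic_snv | .data$cic_deletion)
  n <- nrow(per_sample)
  n_codel <- sum(per_sample$codeleted)
  codel <- per_sample[per_sample$codeleted, , drop = FALSE]
  tallies <- list(
    n_samples = n,
    n_by_subtype = table(factor(per_sample$subtype,
                                levels = c("oligo", "astro", "other"))),
    n_idh1 = if ("idh1_mutant" %in% names(per_sample)) {
      sum(per_sample$idh1_mutant)
    } else NA_integer_,
    idh1_fraction = if ("idh1_mutant" %in% names(per_sample) && n > 0) {
      sum(per_sample$idh1_mutant) / n
    } else NA_real_,
    n_cic_somatic_snv_codeleted = sum(codel$cic_somatic_snv),
    cic_somatic_snv_codeleted_fraction =
      if (n_codel > 0) sum(codel$cic_somatic_snv) / n_codel else NA_real_,
    n_cic_protein_altering_codeleted = sum(codel$cic_protein_altering),
    cic_protein_altering_codeleted_fraction =
      if (n_codel > 0) sum(codel$cic_protein_altering) / n_codel else NA_real_,
    n_fubp1_somatic = sum(per_sample$fubp1_somatic),
    fubp1_somatic_fraction = if (n > 0) sum(per_sample$fubp1_somatic) / n
      else NA_real_
  )
  breakdown <- if (!is.null(mut) && nrow(mut) > 0) {
    mut[mut$sample_id %in% codel$sample_id & mut$gene == "CIC" &
          mut$somatic & mut$consequence %in% snv_classes, , drop = FALSE] |>
      dplyr::count(.data$consequence)
  } else {
    tibble::tibble(consequence = character(), n = integer())
  }
  structure(list(per_sample = per_sample, tallies = tallies,
                 consequence_breakdown = breakdown),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  t <- x$tallies
  cat("Cohort report:", t$n_samples, "samples (",
      paste(t$n_by_subtype, names(t$n_by_subtype), collapse = ", "), ")\n")
  if (!is.na(t$n_idh1)) {
    cat(sprintf("  IDH1 mutant: %d/%d (%.1f%%)\n", t$n_idh1, t$n_samples,
                100 * t$idh1_fraction))
  }
  cat(sprintf("  somatic CIC SNVs in codeleted: %d (%.1f%%)\n",
              t$n_cic_somatic_snv_codeleted,
              100 * t$cic_somatic_snv_codeleted_fraction))
  cat(sprintf("  protein-altering CIC in codeleted: %d (%.1f%%)\n",
              t$n_cic_protein_altering_codeleted,
              100 * t$cic_protein_altering_codeleted_fraction))
  cat(sprintf("  somatic FUBP1: %d (%.1f%%)\n", t$n_fubp1_somatic,
              100 * t$fubp1_somatic_fraction))
  invisible(x)
}

#' Binary factor table for cohort association testing
#'
#' @param report A [build_cohort_report()] result.
#' @return Tibble of per-sample logicals: `codeleted`, `idh1_mutant`,
#'   `cic_somatic`, `cic_protein_altering`, `fubp1_somatic`,
#'   `histology_O`.
#' @export
report_factors <- function(report) {
  ps <- report$per_sample
  tibble::tibble(
    sample_id = ps$sample_id,
    codeleted = ps$codeleted,
    idh1_mutant = if ("idh1_mutant" %in% names(ps)) ps$idh1_mutant else NA,
    cic_somatic = ps$cic_somatic,
    cic_protein_altering = ps$cic_protein_altering,
    fubp1_somatic = ps$fubp1_somatic,
    histology_O = if ("histology" %in% names(ps)) ps$histology == "O" else NA
  )
}

#' The cohort's standard association tests
#'
#' Runs the five Fisher exact tests relating the 1p/19q co-deletion, IDH1
#' status, somatic CIC events, FUBP1 status and histology.
#'
#' @param factors Tibble from [report_factors()].
#' @return Tibble: `test`, cell counts, `odds_ratio`, `p_value`.
#' @export
cohort_association_tests <- function(factors) {
  two_by_two <- function(f1, f2) {
    keep <- !is.na(f1) & !is.na(f2)
    matrix(c(sum(f1[keep] & f2[keep]), sum(f1[keep] & !f2[keep]),
             sum(!f1[keep] & f2[keep]), sum(!f1[keep] & !f2[keep])),
           2, byrow = TRUE)
  }
  specs <- list(
    idh1_vs_codeletion = list(factors$codeleted, factors$idh1_mutant),
    cic_protein_altering_vs_codeletion =
      list(factors$codeleted, factors$cic_protein_altering),
    cic_somatic_vs_histology = list(factors$histology_O, factors$cic_somatic),
    cic_somatic_vs_histology_codeleted = local({
      sub <- factors[factors$codeleted, ]
      list(sub$histology_O, sub$cic_somatic)
    }),
    fubp1_vs_cic = list(factors$cic_somatic, factors$fubp1_somatic)
  )
  purrr::imap_dfr(specs, function(sp, nm) {
    m <- two_by_two(sp[[1]], sp[[2]])
    res <- fisher_exact(m)
    tibble::tibble(test = nm, a = m[1, 1], b = m[1, 2], c = m[2, 1],
                   d = m[2, 2], odds_ratio = res$odds_ratio,
                   p_value = res$p_value)
  })
}

#' Run the full integrative pipeline on a cohort bundle
#'
#' Orchestrates every stage on a simulated (or identically shaped) cohort:
#' arm calling, subtype classification, purity estimation, focal-deletion
#' detection, RPKM normalization and outlier flagging, mutation
#' classification, and two-hit integration. Deterministic given its inputs.
#'
#' @param cohort A `twohit_sim` bundle from [simulate_cohort()], or a list
#'   with the same `probes` / `counts` / `mutations` / `genome` layout.
#' @param genes Genes of interest (`gene`, `arm`); defaults to CIC/FUBP1.
#' @param loss_threshold,gain_threshold,min_arm_probes Arm-calling cutoffs.
#' @param tol,min_probes Focal-deletion caller parameters.
#' @param threshold_fold Expression-outlier fold cutoff (shared between
#'   outlier flagging and two-hit corroboration).
#' @param out_dir Optional directory; when given, writes `report.tsv`,
#'   `twohit_calls.tsv`, `candidates.bed`, `arm_calls.tsv` and `run.log`.
#'   Refuses to overwrite an existing non-empty output set.
#' @return List of class `twohit_result` with `arm_calls`, `subtypes`,
#'   `purity`, `candidates`, `rpkm`, `outliers`, `mutations`, `calls`.
#' @export
run_twohit_pipeline <- function(cohort, genes = default_genes_of_interest(),
                                loss_threshold = -0.3, gain_threshold = 0.25,
                                min_arm_probes = 5, tol = 0.3, min_probes = 2,
                                threshold_fold = 2.5, out_dir = NULL) {
  need <- c("probes", "counts", "mutations", "genome")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    stop("cohort bundle lacks component(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  arm_calls <- call_arm_states(cohort$probes, loss_threshold, gain_threshold,
                               min_arm_probes)
  subtypes <- classify_subtype(arm_calls)
  purity <- estimate_purity(arm_calls, cohort$probes)
  candidates <- detect_focal_deletions(cohort$probes, arm_calls, purity,
                                       tol = tol, min_probes = min_probes,
                                       annotation = cohort$genome$genes)
  rpkm_mat <- rpkm(cohort$counts)
  outliers <- flag_low_outliers(rpkm_mat,
                                genes = intersect(genes$gene, rpkm_mat$gene),
                                threshold_fold = threshold_fold)
  classified <- if (!is.null(cohort$mutations) && nrow(cohort$mutations) > 0) {
    classify_mutations(cohort$mutations)
  } else {
    NULL
  }
  calls <- call_two_hits(arm_calls, candidates, outliers, classified,
                         genes = genes)
  result <- structure(
    list(arm_calls = arm_calls, subtypes = subtypes, purity = purity,
         candidates = candidates, rpkm = rpkm_mat, outliers = outliers,
         mutations = classified, calls = calls,
         parameters = list(loss_threshold = loss_threshold,
                           gain_threshold = gain_threshold,
                           min_arm_probes = min_arm_probes, tol = tol,
                           min_probes = min_probes,
                           threshold_fold = threshold_fold)),
    class = "twohit_result"
  )
  if (!is.null(out_dir)) write_twohit_result(result, out_dir)
  result
}

#' @export
print.twohit_result <- function(x, ...) {
  cat("Two-hit pipeline result\n")
  cat("  samples:         ", nrow(x$subtypes), "\n", sep = "")
  cat("  focal candidates:", nrow(x$candidates), "\n")
  cat("  two-hit calls:   ", sum(x$calls$confidence == "confirmed"),
      "confirmed /", nrow(x$calls), "total\n")
  invisible(x)
}
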