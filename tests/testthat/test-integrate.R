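# Minimal hand-built inputs for the integration rules
toy_inputs <- function() {
  arm_calls <- tibble::tibble(
    sample_id = "T1",
    arm = c("1p", "19q", "7p", "7q", "10p", "10q", "1q", "19p"),
    n_probes = 100L,
    median_log2 = c(-0.85, -0.85, 0, 0, 0, 0, -0.85, -0.85),
    state = factor(c("loss", "loss", "neutral", "neutral", "neutral",
                     "neutral", "loss", "loss"),
                   levels = c("loss", "neutral", "gain"))
  )
  outliers <- tibble::tibble(gene = "CIC", sample_id = "T1", value = 2,
                             cohort_median = 9, fold_below_median = 4.5,
                             flagged = TRUE)
  list(arm_calls = arm_calls, outliers = outliers)
}

toy_candidate <- function(n_probes = 2L) {
  tibble::tibble(
    sample_id = "T1", chrom = "19", arm = "19q",
    inner_start = 42795949, inner_end = 42804577, inner_span_bp = 8628,
    outer_start = 42789059, outer_end = 42809000, outer_span_bp = 19941,
    n_probes = n_probes, mean_log2 = -2, arm_baseline = -0.85,
    requires_corroboration = n_probes < 5, genes = "CIC,PAFAH1B3"
  )
}

test_that("a corroborated 2-probe focal deletion confirms a two-hit call", {
  inp <- toy_inputs()
  calls <- call_two_hits(inp$arm_calls, toy_candidate(), inp$outliers,
                         mutations = NULL)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$hit2_type, "focal_deletion")
  expect_equal(calls$confidence, "confirmed")
  expect_true(calls$expression_corroboration)
})

test_that("an uncorroborated short candidate stays at candidate confidence", {
  inp <- toy_inputs()
  no_flag <- dplyr::mutate(inp$outliers, flagged = FALSE)
  calls <- call_two_hits(inp$arm_calls, toy_candidate(), no_flag,
                         mutations = NULL)
  expect_equal(calls$confidence, "candidate")
  # five or more probes confirm without corroboration
  calls5 <- call_two_hits(inp$arm_calls, toy_candidate(n_probes = 5L),
                          no_flag, mutations = NULL)
  expect_equal(calls5$confidence, "confirmed")
})

test_that("a truncating mutation with an expression flag is NMD-annotated", {
  inp <- toy_inputs()
  muts <- classify_mutations(tibble::tibble(
    sample_id = "T1", gene = "CIC", hgvs_c = "c.3347dupC",
    hgvs_p = "p.(Ser1117Lysfs*34)", tumor_present = TRUE,
    blood_present = FALSE
  ))
  calls <- call_two_hits(inp$arm_calls, NULL, inp$outliers, muts)
  expect_equal(calls$hit2_type, "mutation")
  expect_equal(calls$confidence, "confirmed")
  expect_true(calls$nmd_consistent)
})

test_that("no arm loss or a germline/benign variant yields no call", {
  inp <- toy_inputs()
  neutral <- dplyr::mutate(inp$arm_calls,
                           state = factor("neutral",
                                          levels = levels(inp$arm_calls$state)))
  muts <- classify_mutations(tibble::tibble(
    sample_id = "T1", gene = "CIC", hgvs_c = "c.3793A>G",
    hgvs_p = "p.(Met1265Val)", tumor_present = TRUE, blood_present = TRUE,
    polyphen = 0, taster_verdict = "polymorphism",
    assessor_class = "neutral", exon = 15L
  ))
  expect_equal(nrow(call_two_hits(neutral, toy_candidate(), inp$outliers,
                                  muts)), 0)
  expect_equal(nrow(call_two_hits(inp$arm_calls, NULL, inp$outliers, muts)), 0)
})

test_that("mismatched sample ids across inputs are rejected", {
  inp <- toy_inputs()
  stray <- dplyr::mutate(toy_candidate(), sample_id = "T99")
  expect_error(call_two_hits(inp$arm_calls, stray, inp$outliers, NULL),
               "T99")
})

test_that("the cohort fixture reproduces the printed tallies", {
  t1 <- load_table1()
  classified <- classify_mutations(t1$mutations)
  report <- build_cohort_report(t1$sample_info, classified)
  g <- glance(report)
  expect_equal(c(g$n_oligo, g$n_astro, g$n_other), c(12L, 3L, 2L))
  expect_equal(g$n_idh1, 14)
  expect_equal(round(100 * g$idh1_fraction, 1), 82.4)
  expect_equal(g$n_cic_somatic_snv_codeleted, 7)
  expect_equal(round(100 * g$cic_somatic_snv_codeleted_fraction, 1), 58.3)
  expect_equal(g$n_cic_protein_altering_codeleted, 8)
  expect_equal(g$n_fubp1_somatic, 3)
})

test_that("report tallies are invariant to sample order", {
  t1 <- load_table1()
  classified <- classify_mutations(t1$mutations)
  shuffled <- t1$sample_info[rev(seq_len(nrow(t1$sample_info))), ]
  g1 <- glance(build_cohort_report(t1$sample_info, classified))
  g2 <- glance(build_cohort_report(shuffled, classified))
  expect_equal(g1, g2)
})

test_that("the five cohort association tests reproduce the printed p-values", {
  t1 <- load_table1()
  report <- build_cohort_report(t1$sample_info, classify_mutations(t1$mutations))
  tests <- cohort_association_tests(report_factors(report))
  p <- setNames(tests$p_value, tests$test)
  expect_equal(round(p[["idh1_vs_codeletion"]], 4), 0.0147)
  expect_equal(round(p[["cic_protein_altering_vs_codeletion"]], 4), 0.0294)
  expect_equal(round(p[["cic_somatic_vs_histology"]], 3), 0.015)
  expect_equal(round(p[["cic_somatic_vs_histology_codeleted"]], 3), 0.067)
  expect_equal(round(p[["fubp1_vs_cic"]], 3), 0.082)
})

test_that("an empty cohort produces a zero report", {
  report <- build_cohort_report(
    tibble::tibble(sample_id = character(), histology = character(),
                   subtype = character(), idh1_mutant = logical()),
    NULL)
  expect_equal(report$tallies$n_samples, 0)
  expect_equal(sum(report$tallies$n_by_subtype), 0)
  expect_equal(nrow(report$consequence_breakdown), 0)
})

test_that("pipeline on a zero-noise cohort recovers all planted truth", {
  cfg <- sim_config(seed = 17, n_samples = 12, probe_noise_sd = 0,
                    ct_noise_sd = 0, nb_dispersion = 0, hom_del_rate = 0.4)
  sim <- simulate_cohort(cfg)
  res <- run_twohit_pipeline(sim)
  truth <- sim$truth$samples
  merged <- dplyr::inner_join(truth, res$subtypes, by = "sample_id")
  expect_equal(as.character(merged$subtype.y), as.character(merged$subtype.x))
  # every planted deletion appears as a confirmed focal two-hit call
  del_ids <- sort(sim$truth$deletions$sample_id)
  focal <- res$calls[res$calls$hit2_type == "focal_deletion" &
                       res$calls$confidence == "confirmed", ]
  expect_equal(sort(focal$sample_id), del_ids)
  # every planted damaging somatic mutation appears as a confirmed call
  planted <- classify_mutations(sim$truth$mutations)
  expected_mut <- planted[!is.na(planted$damaging) & planted$damaging, ]
  mut_calls <- res$calls[res$calls$hit2_type == "mutation", ]
  expect_setequal(paste(mut_calls$sample_id, mut_calls$gene),
                  paste(expected_mut$sample_id, expected_mut$gene))
  expect_true(all(mut_calls$confidence == "confirmed"))
})

test_that("pipeline outputs write once and refuse silent overwrites", {
  cfg <- sim_config(seed = 23, n_samples = 5)
  sim <- simulate_cohort(cfg)
  dir <- tempfile()
  res <- run_twohit_pipeline(sim, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("report.tsv", "report.json", "twohit_calls.tsv",
           "candidates.bed", "arm_calls.tsv", "run.log")))))
  expect_error(write_twohit_result(res, dir), "overwrite")
  expect_silent(write_twohit_result(res, dir, overwrite = TRUE))
  # BED export is 0-based half-open: starts shift down by one
  if (nrow(res$candidates) > 0) {
    bed <- read.table(file.path(dir, "candidates.bed"), sep = "\t")
    inner <- bed[grepl("_inner", bed$V4), ]
    expect_equal(inner$V2, as.integer(res$candidates$inner_start) - 1L)
    expect_equal(inner$V3, as.integer(res$candidates$inner_end))
  }
})

test_that("rerunning the pipeline on the same cohort is deterministic", {
  sim <- simulate_cohort(sim_config(seed = 29, n_samples = 6))
  r1 <- run_twohit_pipeline(sim)
  r2 <- run_twohit_pipeline(sim)
  expect_identical(r1$calls, r2$calls)
  expect_identical(r1$candidates, r2$candidates)
})
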