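test_that("config validation catches bad inputs", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(subtype_mix = c(oligo = 0.5, astro = 0.2)),
               "sum to 1")
  expect_error(sim_config(subtype_mix = setNames(1, NULL)), "named")
  expect_error(sim_config(purity_range = c(0, 0.9)), "purity")
  expect_error(sim_config(probe_noise_sd = -1), ">= 0")
  expect_error(sim_config(nmd_knockdown = 1.5), "0, 1")
})

test_that("a pure-oligo mix forces 1p/19q loss in every sample", {
  sim <- simulate_cohort(sim_config(seed = 1, n_samples = 6,
                                    subtype_mix = c(oligo = 1)))
  expect_equal(nrow(sim$truth$samples), 6)
  expect_true(all(sim$truth$samples$subtype == "oligo"))
  st <- sim$truth$arm_states
  expect_true(all(st$copies[st$arm %in% c("1p", "19q")] == 1))
  expect_true(all(st$copies[st$arm %in% c("7p", "7q")] == 2))
})

test_that("zero probe noise collapses log2 ratios onto the mixture model", {
  sim <- simulate_cohort(sim_config(seed = 2, n_samples = 3,
                                    subtype_mix = c(oligo = 1),
                                    probe_noise_sd = 0, hom_del_rate = 0))
  tr <- sim$truth$samples
  for (id in tr$sample_id) {
    f <- tr$purity[tr$sample_id == id]
    arm19q <- sim$probes[sim$probes$sample_id == id &
                           sim$probes$arm == "19q", ]
    expect_equal(arm19q$log2_ratio,
                 rep(expected_log2(1, f), nrow(arm19q)))
    neutral <- sim$probes[sim$probes$sample_id == id &
                            sim$probes$arm == "7p", ]
    expect_equal(neutral$log2_ratio, rep(0, nrow(neutral)))
  }
})

test_that("a fixed seed reproduces the cohort byte-for-byte", {
  cfg <- sim_config(seed = 7, n_samples = 8)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$probes, s2$probes)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$mutations, s2$mutations)
  expect_identical(s1$qpcr, s2$qpcr)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_probe_tsv(s1$probes, f1)
  write_probe_tsv(s2$probes, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("adding a sample never perturbs existing samples' substreams", {
  small <- simulate_cohort(sim_config(seed = 5, n_samples = 5))
  big <- simulate_cohort(sim_config(seed = 5, n_samples = 6))
  ids <- sprintf("S%03d", 1:5)
  expect_identical(small$probes,
                   big$probes[big$probes$sample_id %in% ids, ])
  expect_identical(small$truth$samples,
                   big$truth$samples[big$truth$samples$sample_id %in% ids, ])
})

test_that("counts are non-negative integers and library sizes are column sums", {
  sim <- simulate_cohort(sim_config(seed = 3, n_samples = 5))
  m <- as.matrix(sim$counts[setdiff(names(sim$counts), c("gene", "length"))])
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  # rpkm() derives library sizes as column sums by construction
  r <- rpkm(sim$counts)
  expect_true(all(as.matrix(r[setdiff(names(r), c("gene", "length"))]) >= 0))
})

test_that("expression multipliers follow the mixture and NMD arithmetic", {
  cfg <- sim_config(seed = 11)
  genome <- sim_genome(cfg)
  # copy-0 gene at purity 0.75 retains the stromal quarter
  tr <- list(
    sample = tibble::tibble(sample_id = "X", subtype = "oligo", purity = 0.75),
    arm_states = tibble::tibble(sample_id = "X",
                                arm = unique(genome$probes$arm),
                                copies = ifelse(unique(genome$probes$arm) %in%
                                                  c("1p", "19q"), 1L, 2L)),
    deletion = tibble::tibble(sample_id = "X", gene = "CIC", chrom = "19",
                              start = genome$genes$start[genome$genes$gene == "CIC"],
                              end = genome$genes$end[genome$genes$gene == "CIC"],
                              probe_ids = "", n_probes = 2L, copies = 0L),
    mutations = NULL
  )
  mult <- oligotwohit:::sim_multipliers(cfg, genome, tr)
  expect_equal(mult$multiplier[mult$gene == "CIC"], 0.25)
  # wild-type diploid gene keeps multiplier 1
  expect_equal(mult$multiplier[mult$gene == "G_7p_1"], 1)
  # heterozygous frameshift in a diploid background: 0.5 + 0.5 * 0.2
  tr2 <- list(
    sample = tibble::tibble(sample_id = "Y", subtype = "other", purity = 1),
    arm_states = tibble::tibble(sample_id = "Y",
                                arm = unique(genome$probes$arm), copies = 2L),
    deletion = NULL,
    mutations = tibble::tibble(sample_id = "Y", gene = "FUBP1",
                               hgvs_c = "c.100dupC",
                               hgvs_p = "p.(Ser34Lysfs*10)")
  )
  mult2 <- oligotwohit:::sim_multipliers(cfg, genome, tr2)
  expect_equal(mult2$multiplier[mult2$gene == "FUBP1"], 0.6)
})

test_that("expected counts scale with multiplier, length and depth", {
  cfg <- sim_config(seed = 4, nb_dispersion = 0)
  gene_model <- tibble::tibble(gene = c("a", "b"), length = c(1000, 2000),
                               base_rpkm = c(50, 50))
  mult <- tibble::tibble(sample_id = "s", gene = c("a", "b"),
                         copies = 2L, multiplier = c(1, 1))
  set.seed(99)
  draws <- purrr::map_dfr(1:200, ~ simulate_expression(mult, gene_model, cfg))
  means <- tapply(draws$count, draws$gene, mean)
  expect_equal(unname(means[["b"]] / means[["a"]]), 2, tolerance = 0.05)
  expect_error(
    simulate_expression(dplyr::mutate(mult, multiplier = -1), gene_model, cfg),
    ">= 0")
})

test_that("simulated qPCR follows the log2 dosage model", {
  cfg <- sim_config(seed = 6, ct_noise_sd = 0)
  amps <- tibble::tibble(amplicon_id = c("a", "b", "c"), chrom = "19",
                         start = c(1, 100, 200), end = c(80, 180, 280),
                         copies = c(0L, 1L, 2L))
  out <- simulate_qpcr(amps, purity = 0.75, cfg)
  expect_equal(out$ct, c(27, 25 + log2(2 / 1.25), 25))
  # purity 1, copy 1: exactly one cycle late
  out1 <- simulate_qpcr(amps[2, ], purity = 1, cfg)
  expect_equal(out1$ct, 26)
  # dosage zero without stroma: sentinel, not a number
  out0 <- simulate_qpcr(amps[1, ], purity = 1, cfg)
  expect_true(is.na(out0$ct))
})

test_that("every planted event is covered by a truth record", {
  sim <- simulate_cohort(sim_config(seed = 13, n_samples = 20,
                                    hom_del_rate = 0.3))
  # probes carrying copy-0 signal exist iff a deletion truth record exists
  del_ids <- sim$truth$deletions$sample_id
  for (id in del_ids) {
    del <- sim$truth$deletions[sim$truth$deletions$sample_id == id, ]
    prb <- sim$probes[sim$probes$sample_id == id, ]
    lowest <- prb[which.min(prb$log2_ratio), ]
    expect_true(lowest$start >= del$start - 1e5 & lowest$end <= del$end + 1e5)
  }
  # qPCR tables exist exactly for deletion carriers
  expect_setequal(setdiff(unique(sim$qpcr$sample_id),
                          c("ref_two_copy", "ref_one_copy")), del_ids)
})

test_that("cohort files round-trip through the module readers", {
  sim <- simulate_cohort(sim_config(seed = 21, n_samples = 4,
                                    hom_del_rate = 1,
                                    subtype_mix = c(oligo = 1)))
  dir <- tempfile(); dir.create(dir)
  p <- file.path(dir, "probes.tsv")
  write_probe_tsv(sim$probes, p)
  back_p <- read_probe_tsv(p)
  expect_equal(back_p$probe_id, sim$probes$probe_id)
  expect_equal(back_p$chrom, sim$probes$chrom)
  expect_equal(back_p$start, as.numeric(sim$probes$start))
  expect_equal(back_p$log2_ratio, sim$probes$log2_ratio, tolerance = 1e-12)
  cpath <- file.path(dir, "counts.tsv")
  write_counts_tsv(sim$counts, cpath)
  back_c <- read_counts_tsv(cpath)
  expect_equal(back_c$gene, sim$counts$gene)
  samples <- setdiff(names(sim$counts), c("gene", "length"))
  expect_equal(as.matrix(back_c[samples]) * 1.0,
               as.matrix(sim$counts[samples]) * 1.0)
  mpath <- file.path(dir, "muts.tsv")
  write_mutation_tsv(sim$mutations, mpath)
  back <- read_mutation_tsv(mpath)
  expect_equal(back$hgvs_c, sim$mutations$hgvs_c)
  qpath <- file.path(dir, "qpcr.csv")
  write_qpcr_csv(sim$qpcr, qpath)
  expect_equal(as.data.frame(read_qpcr_csv(qpath))[, 1:5],
               as.data.frame(sim$qpcr)[, 1:5])
})
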