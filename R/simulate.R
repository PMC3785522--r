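#' Configuration for the synthetic oligodendroglial cohort generator
#'
#' The defaults emulate the study conditions the analysis assumes: a cohort
#' of 17 tumors mixing the three genetic subtypes 12:3:2
#' (oligo : astro : other), histological tumor content of at least 80%
#' (purity uniform on `[0.80, 0.95]`), arm-level 1p/19q loss in oligo
#' samples, chromosome-7 gain with optional chromosome-10 loss in astro
#' samples, focal 2-3-probe homozygous deletions of CIC inside the 19q loss,
#' dosage-coupled negative-binomial expression with NMD knockdown of
#' truncating alleles, and qPCR Ct values following a log2 dosage model.
#' The genome is a configurable miniature (chromosomes 1, 7, 10, 19; two
#' arms each; 500 probes per arm) so full cohorts remain desk-scale.
#'
#' @param seed Top-level integer seed. Per-sample substreams are derived by
#'   a stable FNV-1a hash of the sample id combined with this seed, so
#'   adding a sample never perturbs the others.
#' @param n_samples Number of tumor samples.
#' @param subtype_mix Named proportions over `oligo`, `astro`, `other`
#'   (must sum to 1).
#' @param purity_range Tumor-cell fraction interval within `(0, 1]`.
#' @param probes_per_arm,probe_spacing_bp Miniature-genome probe layout.
#' @param probe_noise_sd Per-probe log2 noise SD (aCGH measurement noise).
#' @param nb_dispersion Shared negative-binomial dispersion of counts.
#' @param nmd_knockdown Fraction of a truncating allele's transcript
#'   removed by nonsense-mediated decay, in `[0, 1]`.
#' @param hom_del_rate Probability that an oligo sample carries a focal
#'   homozygous CIC deletion.
#' @param cic_snv_rate Probability of a somatic CIC point mutation in an
#'   oligo sample without the focal deletion.
#' @param fubp1_snv_rate Probability of a somatic FUBP1 variant in an oligo
#'   sample.
#' @param ct_noise_sd qPCR Ct noise SD in cycles.
#' @param qpcr_ref_ct Two-copy reference Ct (cycles).
#' @param target_depth Depth scale converting baseline RPKM to expected
#'   counts (`mu = base_rpkm * length_kb * target_depth / 1e6`); the default
#'   emulates a 25-million-read sequencing run.
#' @param genes_per_arm Background genes per arm (CIC and FUBP1 replace one
#'   each on 19q and 1p).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 17L,
                       subtype_mix = c(oligo = 12 / 17, astro = 3 / 17,
                                       other = 2 / 17),
                       purity_range = c(0.80, 0.95),
                       probes_per_arm = 500L,
                       probe_spacing_bp = 10000L,
                       probe_noise_sd = 0.15,
                       nb_dispersion = 0.05,
                       nmd_knockdown = 0.8,
                       hom_del_rate = 0.1,
                       cic_snv_rate = 7 / 12,
                       fubp1_snv_rate = 0.25,
                       ct_noise_sd = 0.1,
                       qpcr_ref_ct = 25,
                       target_depth = 2.5e7,
                       genes_per_arm = 5L) {
  if (n_samples <= 0) stop("`n_samples` must be positive", call. = FALSE)
  if (length(subtype_mix) == 0 || is.null(names(subtype_mix))) {
    stop("`subtype_mix` must be a named vector of proportions", call. = FALSE)
  }
  if (!all(names(subtype_mix) %in% c("oligo", "astro", "other"))) {
    stop("`subtype_mix` names must be oligo/astro/other", call. = FALSE)
  }
  if (abs(sum(subtype_mix) - 1) > 1e-8) {
    stop("`subtype_mix` proportions must sum to 1", call. = FALSE)
  }
  stopifnot(length(purity_range) == 2, purity_range[1] <= purity_range[2])
  check_purity(purity_range)
  if (probe_noise_sd < 0 || ct_noise_sd < 0 || nb_dispersion < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (nmd_knockdown < 0 || nmd_knockdown > 1) {
    stop("`nmd_knockdown` must lie in [0, 1]", call. = FALSE)
  }
  mix <- setNames(rep(0, 3), c("oligo", "astro", "other"))
  mix[names(subtype_mix)] <- subtype_mix
  structure(
    list(seed = as.integer(seed), n_samples = as.integer(n_samples),
         subtype_mix = mix, purity_range = purity_range,
         probes_per_arm = as.integer(probes_per_arm),
         probe_spacing_bp = as.integer(probe_spacing_bp),
         probe_noise_sd = probe_noise_sd, nb_dispersion = nb_dispersion,
         nmd_knockdown = nmd_knockdown, hom_del_rate = hom_del_rate,
         cic_snv_rate = cic_snv_rate, fubp1_snv_rate = fubp1_snv_rate,
         ct_noise_sd = ct_noise_sd, qpcr_ref_ct = qpcr_ref_ct,
         target_depth = target_depth, genes_per_arm = as.integer(genes_per_arm)),
    class = "sim_config"
  )
}

# Stable 32-bit FNV-1a hash, exact in double arithmetic (16-bit split
# multiply), so per-sample substreams survive R version changes.
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (byte in utf8ToInt(s)) {
    h <- bitwXor_dbl(h, byte)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # bitwXor works on 32-bit signed ints; keep everything in [0, 2^31)
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer((a %/% 65536) %% 65536),
                as.integer((b %/% 65536) %% 65536))
  hi * 65536 + lo
}

sample_seed <- function(config, sample_id, stream = 0) {
  (bitwXor_dbl(fnv1a_hash(sample_id), config$seed * 2654435761 %% 4294967296) +
     stream) %% 2147483647
}

#' Miniature genome backing the simulator
#'
#' Four chromosomes (1, 7, 10, 19), two arms each, `probes_per_arm` evenly
#' spaced 60-mer probes per arm, and a small gene panel with CIC on 19q and
#' FUBP1 on 1p. Gene exon-model lengths and baseline expression levels are
#' drawn once from the top-level seed.
#'
#' @param config A [sim_config()].
#' @return List with `probes` (template without log2 ratios), `centromeres`,
#'   and `genes` (`gene`, `chrom`, `arm`, `start`, `end`, `length`,
#'   `base_rpkm`).
#' @export
sim_genome <- function(config) {
  chroms <- c("1", "7", "10", "19")
  arm_span <- config$probes_per_arm * config$probe_spacing_bp
  probes <- purrr::map_dfr(chroms, function(ch) {
    purrr::map_dfr(c("p", "q"), function(side) {
      offset <- if (side == "p") 0 else arm_span + config$probe_spacing_bp
      i <- seq_len(config$probes_per_arm)
      start <- offset + (i - 1) * config$probe_spacing_bp + 1
      tibble::tibble(
        chrom = ch, start = start, end = start + 59,
        probe_id = sprintf("P_%s%s_%04d", ch, side, i),
        arm = paste0(ch, side)
      )
    })
  })
  centromeres <- tibble::tibble(chrom = chroms,
                                centromere = arm_span + config$probe_spacing_bp / 2)
  set.seed(config$seed %% 2147483647)
  arms <- unique(probes$arm)
  genes <- purrr::map_dfr(arms, function(a) {
    prb <- probes[probes$arm == a, ]
    n <- config$genes_per_arm
    # each gene spans three consecutive probes, spread across the arm
    anchor <- floor(seq(2, nrow(prb) - 4, length.out = n))
    tibble::tibble(
      gene = sprintf("G_%s_%d", a, seq_len(n)),
      chrom = prb$chrom[1], arm = a,
      start = prb$start[anchor],
      end = prb$end[anchor + 2]
    )
  })
  genes$gene[genes$arm == "19q"][ceiling(config$genes_per_arm / 2)] <- "CIC"
  genes$gene[genes$arm == "1p"][ceiling(config$genes_per_arm / 2)] <- "FUBP1"
  genes$length <- round(runif(nrow(genes), 1000, 4000))
  genes$base_rpkm <- round(exp(rnorm(nrow(genes), log(30), 0.5)), 2)
  list(probes = probes, centromeres = centromeres, genes = genes)
}

sim_truth_sample <- function(config, genome, sample_id) {
  set.seed(sample_seed(config, sample_id, stream = 0))
  subtype <- sample(names(config$subtype_mix), 1, prob = config$subtype_mix)
  f <- runif(1, config$purity_range[1], config$purity_range[2])
  arms <- unique(genome$probes$arm)
  copies <- setNames(rep(2L, length(arms)), arms)
  if (subtype == "oligo") {
    copies[c("1p", "19q")] <- 1L
  } else if (subtype == "astro") {
    copies[c("7p", "7q")] <- 3L
    if (runif(1) < 0.5) copies[c("10p", "10q")] <- 1L
  }

  deletion <- NULL
  mutations <- NULL
  if (subtype == "oligo") {
    if (runif(1) < config$hom_del_rate) {
      cic <- genome$genes[genome$genes$gene == "CIC", ]
      prb <- genome$probes[genome$probes$arm == "19q", ]
      inside <- which(prb$start >= cic$start & prb$end <= cic$end)
      width <- sample(2:3, 1)
      first <- inside[sample(length(inside) - width + 1, 1)]
      idx <- first:(first + width - 1)
      deletion <- tibble::tibble(
        sample_id = sample_id, gene = "CIC", chrom = cic$chrom,
        start = prb$start[idx[1]], end = prb$end[idx[width]],
        probe_ids = paste(prb$probe_id[idx], collapse = ","),
        n_probes = width, copies = 0L
      )
    } else if (runif(1) < config$cic_snv_rate) {
      mutations <- dplyr::bind_rows(mutations,
                                    sim_mutation(sample_id, "CIC"))
    }
    if (runif(1) < config$fubp1_snv_rate) {
      mutations <- dplyr::bind_rows(
        mutations, sim_mutation(sample_id, "FUBP1", fubp1 = TRUE))
    }
  }
  list(sample = tibble::tibble(sample_id = sample_id, subtype = subtype,
                               purity = f),
       arm_states = tibble::tibble(sample_id = sample_id, arm = arms,
                                   copies = unname(copies)),
       deletion = deletion, mutations = mutations)
}

# one synthetic HGVS-annotated variant; class mix mirrors the observed
# codeleted spectrum for CIC (4:1:1:1) and the silent/intronic/nonsense
# trio for FUBP1
sim_mutation <- function(sample_id, gene, fubp1 = FALSE) {
  cls <- if (fubp1) {
    sample(c("nonsense", "silent", "intronic"), 1)
  } else {
    sample(c("missense", "nonsense", "frameshift", "splice_site"), 1,
           prob = c(4, 1, 1, 1))
  }
  pos <- sample(300:4400, 1)
  aa <- ceiling(pos / 3)
  rec <- switch(cls,
    missense = tibble::tibble(
      hgvs_c = sprintf("c.%dC>T", pos), hgvs_p = sprintf("p.(Arg%dTrp)", aa),
      exon = sample(c(5L, 19L), 1),
      polyphen = round(runif(1, 0.96, 1), 3),
      taster_verdict = "disease causing",
      assessor_class = sample(c("low", "medium"), 1)
    ),
    nonsense = tibble::tibble(
      hgvs_c = sprintf("c.%dC>A", pos), hgvs_p = sprintf("p.(Ser%d*)", aa),
      exon = NA_integer_, polyphen = NA_real_,
      taster_verdict = NA_character_, assessor_class = NA_character_
    ),
    frameshift = tibble::tibble(
      hgvs_c = sprintf("c.%ddupC", pos),
      hgvs_p = sprintf("p.(Ser%dLysfs*%d)", aa, sample(5:40, 1)),
      exon = NA_integer_, polyphen = NA_real_,
      taster_verdict = NA_character_, assessor_class = NA_character_
    ),
    splice_site = tibble::tibble(
      hgvs_c = sprintf("c.%d-1G>A", pos), hgvs_p = NA_character_,
      exon = NA_integer_, polyphen = NA_real_,
      taster_verdict = NA_character_, assessor_class = NA_character_
    ),
    silent = tibble::tibble(
      hgvs_c = sprintf("c.%dG>A", pos), hgvs_p = sprintf("p.(Gln%d=)", aa),
      exon = NA_integer_, polyphen = NA_real_,
      taster_verdict = NA_character_, assessor_class = NA_character_
    ),
    intronic = tibble::tibble(
      hgvs_c = sprintf("c.%d+14T>G", pos), hgvs_p = NA_character_,
      exon = NA_integer_, polyphen = NA_real_,
      taster_verdict = NA_character_, assessor_class = NA_character_
    )
  )
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id, gene = gene), rec,
                   tibble::tibble(tumor_present = TRUE, blood_present = FALSE))
}

# dosage multiplier of each gene for one sample: stromal cells always
# contribute their diploid share; truncating alleles in the tumor fraction
# retain (1 - nmd_knockdown) of their transcript
sim_multipliers <- function(config, genome, truth_sample) {
  f <- truth_sample$sample$purity
  arm_copies <- setNames(truth_sample$arm_states$copies,
                         truth_sample$arm_states$arm)
  genes <- genome$genes
  copies <- unname(arm_copies[genes$arm])
  if (!is.null(truth_sample$deletion)) {
    del <- truth_sample$deletion
    hit <- genes$chrom == del$chrom & genes$start <= del$end &
      genes$end >= del$start
    copies[hit] <- 0L
  }
  tumor_share <- copies / 2
  if (!is.null(truth_sample$mutations)) {
    for (i in seq_len(nrow(truth_sample$mutations))) {
      m <- truth_sample$mutations[i, ]
      cons <- classify_consequence(m$hgvs_c, m$hgvs_p)
      if (cons %in% truncating_classes) {
        g <- which(genes$gene == m$gene)
        # one tumor allele carries the truncating change; on a one-copy arm
        # that is the only allele left
        c_g <- copies[g]
        if (c_g >= 1) {
          tumor_share[g] <- ((c_g - 1) + (1 - config$nmd_knockdown)) / 2
        }
      }
    }
  }
  tibble::tibble(sample_id = truth_sample$sample$sample_id,
                 gene = genes$gene,
                 copies = copies,
                 multiplier = (1 - f) * 1 + f * tumor_share)
}

#' Simulate per-gene RNA-seq counts for one sample
#'
#' Counts are negative binomial with shared dispersion around
#' `base_rpkm * length_kb * depth / 1e6 * multiplier`, so the expected count
#' is proportional to dosage multiplier, gene length and library size. At
#' zero dispersion counts are Poisson.
#'
#' @param multipliers Tibble from the truth bundle: `gene`, `multiplier`.
#' @param gene_model Gene table with `gene`, `length`, `base_rpkm`.
#' @param config A [sim_config()].
#' @return Tibble `gene`, `count`.
#' @export
simulate_expression <- function(multipliers, gene_model, config) {
  stopifnot(all(gene_model$length > 0))
  if (any(multipliers$multiplier < 0)) {
    stop("dosage multipliers must be >= 0", call. = FALSE)
  }
  m <- dplyr::inner_join(multipliers, gene_model, by = "gene")
  mu <- m$base_rpkm * (m$length / 1000) * (config$target_depth / 1e6) *
    m$multiplier
  count <- if (config$nb_dispersion > 0) {
    rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  tibble::tibble(gene = m$gene, count = as.integer(count))
}

#' Simulate qPCR Ct values over a set of amplicons
#'
#' `Ct = reference_Ct - log2(dosage / 2) + Normal(0, ct_noise_sd)` with
#' relative dosage `(1 - f) * 2 + f * c` and amplification efficiency fixed
#' at 2. A homozygously deleted amplicon with no stromal background
#' (dosage 0) yields the "no amplification" sentinel `NA` rather than a
#' number.
#'
#' @param amplicons Tibble `amplicon_id`, `chrom`, `start`, `end`, `copies`
#'   (tumor copy state at the amplicon).
#' @param purity Tumor purity in `(0, 1]`.
#' @param config A [sim_config()].
#' @return `amplicons` with a `ct` column (`NA` = no amplification).
#' @export
simulate_qpcr <- function(amplicons, purity, config) {
  check_purity(purity)
  dosage <- (1 - purity) * 2 + purity * amplicons$copies
  ct <- config$qpcr_ref_ct - log2(dosage / 2) +
    rnorm(nrow(amplicons), 0, config$ct_noise_sd)
  ct[dosage == 0] <- NA_real_
  dplyr::mutate(tibble::as_tibble(amplicons), ct = ct)
}

#' Simulate a matched aCGH / expression / mutation / qPCR cohort
#'
#' Generates every data layer the integrative pipeline consumes, together
#' with the ground truth needed for recovery tests. Deterministic for a
#' fixed seed; each sample draws from its own hash-derived substream.
#'
#' @param config A [sim_config()].
#' @return List of class `twohit_sim`: `config`, `genome`, `probes` (probe
#'   table across samples), `counts` (wide gene x sample count matrix with
#'   lengths), `mutations`, `qpcr` (amplicon Ct table incl. two-copy and
#'   one-copy reference samples; zero rows when no deletion was planted),
#'   and `truth` (`samples`, `arm_states`, `deletions`, `mutations`,
#'   `multipliers`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim_genome(config)
  ids <- sprintf("S%03d", seq_len(config$n_samples))

  truths <- purrr::map(ids, function(id) sim_truth_sample(config, genome, id))
  names(truths) <- ids

  probes <- purrr::map_dfr(truths, function(tr) {
    id <- tr$sample$sample_id
    set.seed(sample_seed(config, id, stream = 1))
    arm_copies <- setNames(tr$arm_states$copies, tr$arm_states$arm)
    cp <- unname(arm_copies[genome$probes$arm])
    if (!is.null(tr$deletion)) {
      del_ids <- strsplit(tr$deletion$probe_ids, ",")[[1]]
      cp[genome$probes$probe_id %in% del_ids] <- 0L
    }
    L <- expected_log2(cp, tr$sample$purity)
    L[cp == 0 & tr$sample$purity >= 1] <- -10  # floor for zero template
    L <- L + rnorm(length(L), 0, config$probe_noise_sd)
    dplyr::bind_cols(tibble::tibble(sample_id = id), genome$probes,
                     tibble::tibble(log2_ratio = L))
  })

  multipliers <- purrr::map_dfr(truths, function(tr) {
    sim_multipliers(config, genome, tr)
  })
  counts_long <- purrr::map_dfr(truths, function(tr) {
    id <- tr$sample$sample_id
    set.seed(sample_seed(config, id, stream = 2))
    mult <- multipliers[multipliers$sample_id == id, ]
    cnt <- simulate_expression(mult, genome$genes, config)
    dplyr::bind_cols(tibble::tibble(sample_id = id), cnt)
  })
  counts <- counts_long |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count") |>
    dplyr::left_join(genome$genes[c("gene", "length")], by = "gene") |>
    dplyr::relocate("gene", "length")

  mutations <- purrr::map_dfr(truths, "mutations")
  if (nrow(mutations) == 0) {
    mutations <- tibble::tibble(
      sample_id = character(), gene = character(), hgvs_c = character(),
      hgvs_p = character(), exon = integer(), polyphen = numeric(),
      taster_verdict = character(), assessor_class = character(),
      tumor_present = logical(), blood_present = logical()
    )
  }
  deletions <- purrr::map_dfr(truths, "deletion")
  if (nrow(deletions) == 0) {
    deletions <- tibble::tibble(
      sample_id = character(), gene = character(), chrom = character(),
      start = numeric(), end = numeric(), probe_ids = character(),
      n_probes = integer(), copies = integer()
    )
  }

  qpcr <- tibble::tibble(
    sample_id = character(), amplicon_id = character(), chrom = character(),
    start = numeric(), end = numeric(), ct = numeric()
  )
  if (nrow(deletions) > 0) {
    qpcr <- purrr::map_dfr(seq_len(nrow(deletions)), function(i) {
      del <- deletions[i, ]
      tr <- truths[[del$sample_id]]
      amps <- sim_amplicons(genome, del)
      set.seed(sample_seed(config, del$sample_id, stream = 3))
      tum <- simulate_qpcr(amps, tr$sample$purity, config)
      tum$sample_id <- del$sample_id
      # shared synthetic reference samples: two-copy normal and a one-copy
      # codeleted tumor without the focal event
      set.seed(sample_seed(config, paste0(del$sample_id, ":ref"), stream = 3))
      ref2 <- simulate_qpcr(dplyr::mutate(amps, copies = 2L), 1, config)
      ref2$sample_id <- "ref_two_copy"
      f1 <- mean(config$purity_range)
      ref1 <- simulate_qpcr(dplyr::mutate(amps, copies = 1L), f1, config)
      ref1$sample_id <- "ref_one_copy"
      dplyr::bind_rows(tum, ref2, ref1)[
        , c("sample_id", "amplicon_id", "chrom", "start", "end", "ct")]
    })
  }

  structure(
    list(config = config, genome = genome, probes = probes, counts = counts,
         mutations = mutations, qpcr = qpcr,
         truth = list(
           samples = purrr::map_dfr(truths, "sample"),
           arm_states = purrr::map_dfr(truths, "arm_states"),
           deletions = deletions,
           mutations = mutations,
           multipliers = multipliers
         )),
    class = "twohit_sim"
  )
}

# tile amplicons across a planted deletion: two retained flanking amplicons
# on each side plus one per deleted probe
sim_amplicons <- function(genome, del) {
  prb <- genome$probes[genome$probes$chrom == del$chrom &
                         genome$probes$arm == "19q", ]
  del_idx <- which(prb$start >= del$start & prb$end <= del$end)
  idx <- max(1, min(del_idx) - 2):min(nrow(prb), max(del_idx) + 2)
  tibble::tibble(
    amplicon_id = sprintf("amp_%02d", seq_along(idx)),
    chrom = del$chrom,
    start = prb$start[idx] + 10, end = prb$start[idx] + 90,
    copies = ifelse(idx %in% del_idx, 0L, 1L)
  )
}

#' @export
print.twohit_sim <- function(x, ...) {
  cat("Synthetic oligodendroglial cohort\n")
  cat("  samples:  ", nrow(x$truth$samples), " (",
      paste(table(x$truth$samples$subtype), collapse = "/"), " ",
      paste(names(table(x$truth$samples$subtype)), collapse = "/"), ")\n",
      sep = "")
  cat("  probes:   ", nrow(x$genome$probes), " per sample\n", sep = "")
  cat("  genes:    ", nrow(x$genome$genes), "\n", sep = "")
  cat("  planted focal deletions: ", nrow(x$truth$deletions), "\n", sep = "")
  invisible(x)
}
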