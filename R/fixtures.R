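#' Load the packaged cohort overview fixture
#'
#' A 17-sample oligodendroglial cohort overview (histology, genetic
#' subtype, IDH1 status, CIC and FUBP1 variants with predictor
#' annotations), shipped as `extdata/table1.tsv`. The loader splits it into
#' a per-sample annotation table and a long HGVS mutation table ready for
#' [classify_mutations()].
#'
#' @return List with `sample_info` (`sample_id`, `who_classification`,
#'   `histology`, `subtype`, `idh1_mutant`) and `mutations` (long tibble,
#'   one row per non-wildtype CIC/FUBP1 entry).
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1.tsv", package = "oligotwohit",
                      mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         na = "NA", col_types = readr::cols(
                           cic_polyphen = readr::col_double(),
                           cic_taster_prob = readr::col_double(),
                           cic_exon = readr::col_integer(),
                           cic_in_blood = readr::col_logical(),
                           fubp1_in_blood = readr::col_logical(),
                           .default = readr::col_character()
                         ))
  sample_info <- tibble::tibble(
    sample_id = raw$sample_id,
    who_classification = raw$who_classification,
    histology = raw$histology,
    subtype = raw$genetic_subtype,
    idh1_mutant = raw$idh1_mutation != "wt"
  )
  cic <- raw[raw$cic_hgvs_c != "wt", ]
  fubp1 <- raw[raw$fubp1_hgvs_c != "wt", ]
  mutations <- dplyr::bind_rows(
    tibble::tibble(
      sample_id = cic$sample_id, gene = "CIC",
      hgvs_c = cic$cic_hgvs_c, hgvs_p = cic$cic_hgvs_p,
      tumor_present = TRUE, blood_present = cic$cic_in_blood,
      polyphen = cic$cic_polyphen,
      taster_verdict = cic$cic_taster_verdict,
      assessor_class = cic$cic_assessor_class,
      exon = cic$cic_exon
    ),
    tibble::tibble(
      sample_id = fubp1$sample_id, gene = "FUBP1",
      hgvs_c = fubp1$fubp1_hgvs_c, hgvs_p = fubp1$fubp1_hgvs_p,
      tumor_present = TRUE, blood_present = fubp1$fubp1_in_blood,
      polyphen = NA_real_, taster_verdict = NA_character_,
      assessor_class = NA_character_, exon = NA_integer_
    )
  )
  list(sample_info = sample_info, mutations = mutations)
}

#' Load the literature missense-by-domain counts fixture
#'
#' Pooled counts of published high-PolyPhen CIC missense mutations by
#' protein domain (HMG box / GlobDom / outside).
#'
#' @return List with `missense_total` and a named `by_domain` vector.
#' @export
load_missense_domain_counts <- function() {
  path <- system.file("extdata", "s4_missense_counts.json",
                      package = "oligotwohit", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(missense_total = j$missense_total,
       by_domain = unlist(j$by_domain))
}

#' Load the static public-cohort validation counts
#'
#' Counts from a 213-case low-grade-glioma cohort (1p/19q co-deletion, CIC
#' and FUBP1 mutation margins) packaged as a static fixture; no live cohort
#' query is performed.
#'
#' @return Named list of counts.
#' @export
load_tcga_counts <- function() {
  path <- system.file("extdata", "tcga_lgg_counts.json",
                      package = "oligotwohit", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' BT1 worked example: aCGH probes around the CIC microdeletion
#'
#' Real hg19 coordinates for the two probes that exposed the exon-spanning
#' homozygous deletion (log2 ratio -2, chr19:42,795,949-42,796,008 and
#' chr19:42,804,518-42,804,577) embedded in a 19q arm sitting at the
#' one-copy level (log2 about -0.9). The flanking retained probes are a
#' minimal synthetic tiling: the array design around the locus is not
#' printed, so flanks are placed at plausible spacing purely to give the
#' focal caller retained context.
#'
#' @return Probe tibble (`sample_id` "BT1") with an `arm` column.
#' @export
bt1_probes <- function() {
  start <- c(42700000, 42730000, 42760000, 42780000, 42789000,
             42795949, 42804518, 42809000, 42830000, 42860000)
  end <- c(start[1:5] + 59, 42796008, 42804577, start[8:10] + 59)
  tibble::tibble(
    sample_id = "BT1",
    chrom = "19",
    start = start,
    end = end,
    probe_id = c("flank_1", "flank_2", "flank_3", "flank_4", "flank_5",
                 "A_16_P21013642", "A_14_P124269", "flank_6", "flank_7",
                 "flank_8"),
    arm = "19q",
    log2_ratio = c(rep(-0.9, 5), -2, -2, rep(-0.9, 3))
  )
}

#' BT1 worked example: qPCR tiling consistent with the printed breakpoints
#'
#' The deletion's 5' breakpoint was refined to chr19:42,790,756-42,790,839
#' and the 3' breakpoint to chr19:42,805,880-42,808,040: the last retained
#' amplicon ends at 42,790,756, the first deleted starts at 42,790,839, the
#' last deleted ends at 42,805,880 and the next retained starts at
#' 42,808,040. Only those four boundary coordinates are printed; the
#' amplicon count and interior positions are a minimal synthetic
#' reconstruction. Ct values follow the dosage model at 75% purity with a
#' two-copy reference Ct of 25 (so deleted amplicons sit 2 cycles late and
#' one-copy amplicons 0.68).
#'
#' @return qPCR tibble with tumor sample "BT1", two-copy reference
#'   "ref_two_copy" and one-copy reference "ref_one_copy".
#' @export
bt1_qpcr <- function() {
  layout <- tibble::tibble(
    amplicon_id = sprintf("amp_%d", 1:6),
    chrom = "19",
    start = c(42790656, 42790839, 42796000, 42801500, 42805780, 42808040),
    end = c(42790756, 42790939, 42796100, 42801600, 42805880, 42808140),
    copies = c(1L, 0L, 0L, 0L, 0L, 1L)
  )
  f <- 0.75
  dct <- log2(2 / ((1 - f) * 2 + f * layout$copies))
  dplyr::bind_rows(
    dplyr::mutate(layout, sample_id = "BT1", ct = 25 + dct),
    dplyr::mutate(layout, sample_id = "ref_two_copy", ct = 25),
    dplyr::mutate(layout, sample_id = "ref_one_copy", ct = 25 + log2(2 / 1.25))
  )[, c("sample_id", "amplicon_id", "chrom", "start", "end", "ct")]
}

#' BT1 worked example: toy gene annotation around the deletion
#'
#' Three-gene annotation of the locus: CIC and PAFAH1B3 at their
#' approximate hg19 spans, and the downstream neighbor placed just beyond
#' the 3' qPCR bound (its true start is interior to the printed uncertainty
#' interval; this synthetic placement encodes the published conclusion that
#' the gene lies outside the deletion).
#'
#' @return Tibble: `gene`, `chrom`, `start`, `end`.
#' @export
bt1_genes <- function() {
  tibble::tibble(
    gene = c("CIC", "PAFAH1B3", "PRR19"),
    chrom = "19",
    start = c(42788817, 42801407, 42808100),
    end = c(42799949, 42804517, 42813000)
  )
}
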