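#' Parse a coding-DNA HGVS string (deliberately minimal grammar)
#'
#' Supports exactly the variant vocabulary this pipeline consumes: simple
#' substitutions (`c.395G>A`), intronic-offset substitutions
#' (`c.1135-1G>A`, `c.1041+14T>G`), duplications (`c.3347dupC`) and
#' exon-spanning deletions written as `del exon N-M`. Anything else raises
#' an error naming the offending token — a silent misparse is worse than a
#' failure.
#'
#' @param hgvs_c Coding-DNA change string.
#' @return List with `kind` (substitution / dup / exon_deletion),
#'   `position`, `offset` (0 when exonic), and ref/alt bases where present.
#' @export
parse_hgvs_c <- function(hgvs_c) {
  stopifnot(length(hgvs_c) == 1)
  s <- trimws(hgvs_c)
  m <- regexec("^del exon ([0-9]+)-([0-9]+)$", s)[[1]]
  if (m[1] != -1) {
    parts <- regmatches(s, regexec("^del exon ([0-9]+)-([0-9]+)$", s))[[1]]
    return(list(kind = "exon_deletion", position = NA_integer_, offset = 0L,
                exon_from = as.integer(parts[2]), exon_to = as.integer(parts[3])))
  }
  sub_re <- "^c\\.([0-9]+)([+-][0-9]+)?([ACGT])>([ACGT])$"
  parts <- regmatches(s, regexec(sub_re, s))[[1]]
  if (length(parts) > 0) {
    off <- if (parts[3] == "") 0L else as.integer(parts[3])
    return(list(kind = "substitution", position = as.integer(parts[2]),
                offset = off, ref = parts[4], alt = parts[5]))
  }
  dup_re <- "^c\\.([0-9]+)(?:_([0-9]+))?dup([ACGT]*)$"
  parts <- regmatches(s, regexec(dup_re, s))[[1]]
  if (length(parts) > 0) {
    return(list(kind = "dup", position = as.integer(parts[2]), offset = 0L,
                bases = parts[4]))
  }
  stop("unparseable HGVS coding change: '", s, "'", call. = FALSE)
}

#' Classify the consequence of an HGVS-annotated variant
#'
#' Decision order: a protein change containing `fs` is a frameshift; a stop
#' (`*`) without `fs` is nonsense; `=` is silent. Without a decisive protein
#' change the coding change decides: an exon-spanning deletion is its own
#' class; an intronic offset within +/-2 nt of the exon boundary hits the
#' canonical splice site, larger offsets are intronic; everything else is a
#' missense substitution.
#'
#' @param hgvs_c Coding-DNA change string.
#' @param hgvs_p Protein change string, or `NA`/`""` when absent.
#' @param splice_window Offset magnitude (nt) still counted as splice site.
#' @return One of `"missense"`, `"nonsense"`, `"frameshift"`,
#'   `"splice_site"`, `"silent"`, `"intronic"`, `"exon_spanning_deletion"`.
#' @examples
#' classify_consequence("c.3131C>A", "p.(Ser1044*)")        # nonsense
#' classify_consequence("c.3347dupC", "p.(Ser1117Lysfs*34)") # frameshift
#' classify_consequence("c.1135-1G>A", NA)                   # splice_site
#' @export
classify_consequence <- function(hgvs_c, hgvs_p = NA_character_,
                                 splice_window = 2) {
  p <- if (is.na(hgvs_p) || !nzchar(hgvs_p)) "" else hgvs_p
  if (grepl("fs", p, fixed = TRUE)) return("frameshift")
  if (grepl("*", p, fixed = TRUE)) return("nonsense")
  if (grepl("=", p, fixed = TRUE)) return("silent")
  parsed <- parse_hgvs_c(hgvs_c)
  if (parsed$kind == "exon_deletion") return("exon_spanning_deletion")
  if (parsed$offset != 0) {
    if (abs(parsed$offset) <= splice_window) return("splice_site")
    return("intronic")
  }
  "missense"
}

#' Somatic status from paired tumor/blood presence
#'
#' @param tumor_present,blood_present Logical vectors.
#' @return `"somatic"` (tumor only), `"germline"` (both) or `"absent"`.
#' @export
somatic_status <- function(tumor_present, blood_present) {
  dplyr::case_when(
    tumor_present & !blood_present ~ "somatic",
    tumor_present & blood_present ~ "germline",
    TRUE ~ "absent"
  )
}

#' Default CIC protein-domain map
#'
#' The DNA-binding HMG box is encoded by exon 5 and parts of exon 6; an
#' annotated globular domain (GlobDom) containing a protein-interaction
#' region spans exons 19-20. This exon-to-domain assignment is fixture
#' knowledge, not derived annotation.
#'
#' @return Tibble: `gene`, `domain`, `exon_from`, `exon_to`.
#' @export
cic_domain_map <- function() {
  tibble::tibble(
    gene = c("CIC", "CIC"),
    domain = c("HMG_box", "GlobDom"),
    exon_from = c(5L, 19L),
    exon_to = c(6L, 20L)
  )
}

#' Assign a missense position to a protein domain by exon
#'
#' @param gene Gene symbol.
#' @param exon Exon number, or `NA`.
#' @param domain_map Tibble as from [cic_domain_map()].
#' @return Domain label, `"outside"` when no range matches, `NA` when the
#'   exon is unknown.
#' @export
assign_domain <- function(gene, exon, domain_map = cic_domain_map()) {
  if (is.na(exon)) return(NA_character_)
  hit <- domain_map$gene == gene &
    domain_map$exon_from <= exon & domain_map$exon_to >= exon
  if (any(hit)) domain_map$domain[which(hit)[1]] else "outside"
}

truncating_classes <- c("nonsense", "frameshift", "splice_site",
                        "exon_spanning_deletion")

#' Assess whether a classified variant is protein-damaging
#'
#' Truncating classes (nonsense, frameshift, splice site, exon-spanning
#' deletion) are damaging unconditionally; silent and intronic changes are
#' not. Missense changes are put to a majority vote over the available
#' predictor annotations: PolyPhen-2 votes damaging at a score of
#' `polyphen_cutoff` or more (default 0.95, the "probably damaging"
#' convention), Mutation Taster by a "disease causing" verdict, Mutation
#' Assessor by any functional-impact class other than neutral. A missense
#' with no annotations, or an exact tie, is `"undetermined"` — never
#' silently damaging.
#'
#' @param consequence Consequence class from [classify_consequence()].
#' @param polyphen PolyPhen-2 score in `[0, 1]` or `NA`.
#' @param taster_verdict Mutation Taster verdict string or `NA`.
#' @param assessor_class Mutation Assessor class string or `NA`.
#' @param polyphen_cutoff Damaging cutoff for the PolyPhen-2 score.
#' @return List with `damaging` (TRUE / FALSE / NA for undetermined) and a
#'   human-readable `rationale`.
#' @export
assess_damaging <- function(consequence, polyphen = NA_real_,
                            taster_verdict = NA_character_,
                            assessor_class = NA_character_,
                            polyphen_cutoff = 0.95) {
  if (consequence %in% truncating_classes) {
    return(list(damaging = TRUE,
                rationale = paste0("truncating class (", consequence, ")")))
  }
  if (consequence %in% c("silent", "intronic")) {
    return(list(damaging = FALSE,
                rationale = paste0("non-coding-impact class (", consequence, ")")))
  }
  votes <- c(
    polyphen = if (!is.na(polyphen)) polyphen >= polyphen_cutoff else NA,
    taster = if (!is.na(taster_verdict)) {
      grepl("disease", taster_verdict, ignore.case = TRUE)
    } else NA,
    assessor = if (!is.na(assessor_class)) {
      !grepl("neutral", assessor_class, ignore.case = TRUE)
    } else NA
  )
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) {
    return(list(damaging = NA, rationale = "missense with no predictor annotations"))
  }
  n_dam <- sum(votes)
  if (n_dam * 2 == length(votes)) {
    return(list(damaging = NA,
                rationale = sprintf("predictor tie (%d vs %d)", n_dam,
                                    length(votes) - n_dam)))
  }
  damaging <- n_dam * 2 > length(votes)
  list(damaging = damaging,
       rationale = sprintf("missense majority vote %d/%d damaging", n_dam,
                           length(votes)))
}

#' Classify a table of HGVS-annotated variants
#'
#' Applies [classify_consequence()], [somatic_status()], [assign_domain()]
#' and [assess_damaging()] row-wise to a mutation table.
#'
#' @param mutations Tibble with `sample_id`, `gene`, `hgvs_c`, `hgvs_p`,
#'   `tumor_present`, `blood_present`, and optionally `exon`, `polyphen`,
#'   `taster_verdict`, `assessor_class`.
#' @param domain_map Domain map (default: the packaged CIC map).
#' @param polyphen_cutoff Passed to [assess_damaging()].
#' @return Input tibble with `consequence`, `somatic`, `domain`, `damaging`
#'   and `evaluation` (printed-style label) columns appended.
#' @export
classify_mutations <- function(mutations, domain_map = cic_domain_map(),
                               polyphen_cutoff = 0.95) {
  need <- c("sample_id", "gene", "hgvs_c")
  stopifnot(all(need %in% names(mutations)))
  mut <- tibble::as_tibble(mutations)
  if (!"hgvs_p" %in% names(mut)) mut$hgvs_p <- NA_character_
  if (!"tumor_present" %in% names(mut)) mut$tumor_present <- TRUE
  if (!"blood_present" %in% names(mut)) mut$blood_present <- FALSE
  for (col in c("exon")) if (!col %in% names(mut)) mut[[col]] <- NA_integer_
  for (col in c("polyphen")) if (!col %in% names(mut)) mut[[col]] <- NA_real_
  for (col in c("taster_verdict", "assessor_class")) {
    if (!col %in% names(mut)) mut[[col]] <- NA_character_
  }
  mut$consequence <- purrr::map2_chr(mut$hgvs_c, mut$hgvs_p,
                                     classify_consequence)
  mut$somatic <- somatic_status(mut$tumor_present, mut$blood_present) == "somatic"
  mut$domain <- purrr::map2_chr(mut$gene, mut$exon, assign_domain,
                                domain_map = domain_map)
  assessed <- purrr::pmap(
    list(mut$consequence, mut$polyphen, mut$taster_verdict,
         mut$assessor_class),
    assess_damaging, polyphen_cutoff = polyphen_cutoff
  )
  mut$damaging <- purrr::map_lgl(assessed, "damaging")
  mut$damaging_rationale <- purrr::map_chr(assessed, "rationale")
  mut$evaluation <- evaluation_label(mut$consequence)
  mut
}

evaluation_label <- function(consequence) {
  lab <- c(missense = "Missense mutation", nonsense = "Nonsense mutation",
           frameshift = "Frameshift mutation", splice_site = "Splicesite mutation",
           silent = "Silent mutation", intronic = "Intronic mutation",
           exon_spanning_deletion = "Deletion")
  unname(lab[consequence])
}

#' Summarize a mutation spectrum
#'
#' Tallies records by gene and consequence class, and missense records by
#' domain, reporting fractions within each partition.
#'
#' @param classified Tibble from [classify_mutations()] (needs `gene`,
#'   `consequence`; `domain` used when present).
#' @return List of tibbles: `by_consequence` (gene x consequence counts and
#'   within-gene fractions) and `missense_by_domain` (counts and fractions
#'   of missense records per domain).
#' @export
spectrum_summary <- function(classified) {
  if (nrow(classified) == 0) {
    return(list(
      by_consequence = tibble::tibble(gene = character(),
                                      consequence = character(),
                                      n = integer(), fraction = numeric()),
      missense_by_domain = tibble::tibble(domain = character(), n = integer(),
                                          fraction = numeric())
    ))
  }
  by_cons <- classified |>
    dplyr::count(.data$gene, .data$consequence) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  mis <- classified[classified$consequence == "missense", , drop = FALSE]
  by_dom <- if (nrow(mis) > 0 && "domain" %in% names(mis)) {
    mis |>
      dplyr::count(.data$domain) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n))
  } else {
    tibble::tibble(domain = character(), n = integer(), fraction = numeric())
  }
  list(by_consequence = by_cons, missense_by_domain = by_dom)
}
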