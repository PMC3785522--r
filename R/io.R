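#' Read / write the pipeline's tabular formats
#'
#' Thin readr wrappers pinning the column contracts. All genomic
#' coordinates in files are 1-based inclusive, matching how breakpoints are
#' printed in the literature; BED export converts to BED's 0-based
#' half-open convention.
#'
#' @param path File path.
#' @return A tibble with the validated columns.
#' @name twohit_io
NULL

#' @rdname twohit_io
#' @export
read_probe_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(chrom = readr::col_character(),
                                                .default = readr::col_guess()))
  need <- c("chrom", "start", "end", "probe_id", "log2_ratio")
  check_columns(df, need, path)
  df
}

#' @rdname twohit_io
#' @param probes Probe tibble.
#' @export
write_probe_tsv <- function(probes, path) {
  need <- c("chrom", "start", "end", "probe_id", "log2_ratio")
  check_columns(probes, need, path)
  readr::write_tsv(probes, path)
  invisible(path)
}

#' @rdname twohit_io
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("gene", "length"), path)
  df
}

#' @rdname twohit_io
#' @param counts Wide count tibble (`gene`, `length`, sample columns).
#' @export
write_counts_tsv <- function(counts, path) {
  check_columns(counts, c("gene", "length"), path)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname twohit_io
#' @export
read_mutation_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(df, c("sample_id", "gene", "hgvs_c"), path)
  df
}

#' @rdname twohit_io
#' @param mutations Mutation tibble.
#' @export
write_mutation_tsv <- function(mutations, path) {
  check_columns(mutations, c("sample_id", "gene", "hgvs_c"), path)
  readr::write_tsv(mutations, path)
  invisible(path)
}

#' @rdname twohit_io
#' @export
read_qpcr_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(chrom = readr::col_character(),
                                                .default = readr::col_guess()))
  check_columns(df, c("sample_id", "amplicon_id", "chrom", "start", "end",
                      "ct"), path)
  df
}

#' @rdname twohit_io
#' @param qpcr qPCR tibble.
#' @export
write_qpcr_csv <- function(qpcr, path) {
  check_columns(qpcr, c("sample_id", "amplicon_id", "chrom", "start", "end",
                        "ct"), path)
  readr::write_csv(qpcr, path)
  invisible(path)
}

check_columns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("'", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Export focal-deletion candidates as BED-plus paired records
#'
#' Each candidate produces two BED records, `<sample>_inner` (outermost
#' deleted probes) and `<sample>_outer` (innermost flanking retained
#' probes). BED is 0-based half-open, so 1-based inclusive starts are
#' shifted down by one.
#'
#' @param candidates Tibble from [detect_focal_deletions()].
#' @param path Output path.
#' @export
write_candidates_bed <- function(candidates, path) {
  if (nrow(candidates) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  inner <- sprintf("%s\t%d\t%d\t%s_inner", candidates$chrom,
                   as.integer(candidates$inner_start) - 1L,
                   as.integer(candidates$inner_end),
                   candidates$sample_id)
  has_outer <- !is.na(candidates$outer_start) & !is.na(candidates$outer_end)
  outer <- sprintf("%s\t%d\t%d\t%s_outer",
                   candidates$chrom[has_outer],
                   as.integer(candidates$outer_start[has_outer]) - 1L,
                   as.integer(candidates$outer_end[has_outer]),
                   candidates$sample_id[has_outer])
  writeLines(c(inner, outer), path)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Writes `report.tsv` / `report.json` (per-sample subtype and purity),
#' `twohit_calls.tsv`, `candidates.bed`, `arm_calls.tsv` and a `run.log`
#' capturing thresholds. Refuses to overwrite a directory that already
#' holds a `run.log` unless `overwrite = TRUE`.
#'
#' @param result A `twohit_result` from [run_twohit_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @param overwrite Allow replacing a previous run's outputs.
#' @export
write_twohit_result <- function(result, out_dir, overwrite = FALSE) {
  stopifnot(inherits(result, "twohit_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (file.exists(file.path(out_dir, "run.log")) && !overwrite) {
    stop("'", out_dir, "' already holds pipeline outputs; ",
         "use overwrite = TRUE to replace them", call. = FALSE)
  }
  report <- dplyr::left_join(result$subtypes, result$purity, by = "sample_id")
  readr::write_tsv(report, file.path(out_dir, "report.tsv"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  readr::write_tsv(result$calls, file.path(out_dir, "twohit_calls.tsv"))
  write_candidates_bed(result$candidates, file.path(out_dir, "candidates.bed"))
  readr::write_tsv(result$arm_calls, file.path(out_dir, "arm_calls.tsv"))
  writeLines(c(
    "oligotwohit pipeline run",
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0(names(result$parameters), ": ",
           unlist(result$parameters))
  ), file.path(out_dir, "run.log"))
  invisible(out_dir)
}
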