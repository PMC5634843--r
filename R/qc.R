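#' QC thresholds
#'
#' Default warning thresholds for the two sample-quality metrics: overall
#' genome mapping rate below 65% or coding fraction below 40% flags a
#' sample. Warnings use strict `<` semantics.
#'
#' @param genome_min_pct Minimum acceptable overall mapping rate (0-100).
#' @param coding_min_pct Minimum acceptable coding fraction (0-100).
#' @return A `qc_thresholds` object.
#' @export
qc_thresholds <- function(genome_min_pct = 65, coding_min_pct = 40) {
  stopifnot(genome_min_pct >= 0, genome_min_pct <= 100,
            coding_min_pct >= 0, coding_min_pct <= 100)
  structure(list(genome_min_pct = genome_min_pct,
                 coding_min_pct = coding_min_pct),
            class = "qc_thresholds")
}

#' Extract the overall mapping rate from a mapper summary
#'
#' Parses the percentage of reads the mapper aligned to the genome from a
#' TopHat2 `align_summary.txt` or a HISAT2 run summary (the text HISAT2
#' prints to stderr).
#'
#' @param text Summary text: a single string or a character vector of
#'   lines.
#' @param dialect `"tophat2"` or `"hisat2"`.
#' @return The overall mapping rate as a percentage in `[0, 100]`.
#' @export
parse_mapper_summary <- function(text, dialect = c("tophat2", "hisat2")) {
  dialect <- match.arg(dialect)
  text <- paste(text, collapse = "\n")
  pattern <- switch(dialect,
    tophat2 = "([0-9]+\\.?[0-9]*)%\\s+overall read mapping rate",
    hisat2 = "([0-9]+\\.?[0-9]*)%\\s+overall alignment rate")
  m <- regmatches(text, regexec(pattern, text))[[1L]]
  if (length(m) < 2L) {
    stop("could not find a mapping-rate line matching '", pattern,
         "' in ", dialect, " summary")
  }
  as.numeric(m[2L])
}

#' Fraction of mapped reads assigned to coding genes
#'
#' `100 * sum(gene counts) / (total records - not_aligned)`. The mapped
#' denominator includes ambiguous, low-quality and multi-mapped records.
#'
#' @param counts A [count_result()].
#' @return Percentage in `[0, 100]`.
#' @export
coding_fraction <- function(counts) {
  stopifnot(inherits(counts, "count_result"))
  mapped <- counts$total_records - counts$special[["not_aligned"]]
  if (mapped == 0L) stop("no mapped reads: coding fraction undefined")
  100 * sum(counts$counts) / mapped
}

#' Flag samples against QC thresholds
#'
#' A sample is flagged `warn_genome` when its genome mapping rate is
#' strictly below the genome threshold and `warn_coding` when its coding
#' fraction is strictly below the coding threshold (both flags can apply).
#' Flagged samples are reported, never removed; exclusion is a separate
#' explicit action ([drop_samples()]).
#'
#' @param stats Data frame with columns `sample_id`, `genome_mapping_pct`,
#'   `coding_pct` (`NA` metrics never warn).
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report`: the input with logical `warn_genome` and
#'   `warn_coding` columns and a combined `flag` string (`"pass"` or the
#'   warnings joined by `";"`); thresholds kept as an attribute.
#' @export
flag_samples <- function(stats, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(stats),
            all(c("sample_id", "genome_mapping_pct", "coding_pct") %in%
                  names(stats)))
  wg <- !is.na(stats$genome_mapping_pct) &
    stats$genome_mapping_pct < thresholds$genome_min_pct
  wc <- !is.na(stats$coding_pct) &
    stats$coding_pct < thresholds$coding_min_pct
  flag <- ifelse(wg & wc, "warn_genome;warn_coding",
                 ifelse(wg, "warn_genome",
                        ifelse(wc, "warn_coding", "pass")))
  out <- cbind(stats, warn_genome = wg, warn_coding = wc, flag = flag,
               stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("qc_report", "data.frame")
  out
}

#' Write a QC report as TSV
#'
#' @param report A `qc_report` from [flag_samples()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  utils::write.table(
    report[, c("sample_id", "genome_mapping_pct", "coding_pct", "flag")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
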