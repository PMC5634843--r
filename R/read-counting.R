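#' Construct an aligned read
#'
#' A light-weight record of one SAM alignment, holding what union-mode
#' counting needs: mapping state, the reference blocks consumed by M/=/X
#' CIGAR operations (N and D split or extend blocks on the reference),
#' mapping quality, and the NH-style hit count.
#'
#' @param read_id Read name.
#' @param mapped Logical; `FALSE` for unmapped records.
#' @param chromosome Reference name (ignored when unmapped).
#' @param position 1-based leftmost mapping position.
#' @param aligned_blocks [IRanges::IRanges] of reference intervals covered
#'   by aligned bases; required (non-empty) when mapped.
#' @param mapping_quality Integer MAPQ.
#' @param hit_count Number of reported alignments for the read (NH tag);
#'   defaults to 1.
#' @param strand Read strand, `"+"` or `"-"`.
#' @return An `aligned_read` object (a list).
#' @export
aligned_read <- function(read_id, mapped, chromosome = NA_character_,
                         position = NA_integer_,
                         aligned_blocks = IRanges::IRanges(),
                         mapping_quality = 0L, hit_count = 1L,
                         strand = "+") {
  stopifnot(is.logical(mapped), hit_count >= 1L)
  if (mapped && length(aligned_blocks) == 0L) {
    stop("mapped read '", read_id, "' must have at least one aligned block")
  }
  structure(list(read_id = read_id, mapped = mapped,
                 chromosome = chromosome, position = position,
                 aligned_blocks = aligned_blocks,
                 mapping_quality = as.integer(mapping_quality),
                 hit_count = as.integer(hit_count), strand = strand),
            class = "aligned_read")
}

SPECIAL_COUNTERS <- c("no_feature", "ambiguous", "too_low_quality",
                      "not_aligned", "alignment_not_unique")

#' Construct a count result
#'
#' Per-gene read counts plus the five HTSeq-style special counters. The
#' conservation identity (gene counts + special counters == total records)
#' is enforced at construction.
#'
#' @param counts Named nonnegative integer vector of per-gene counts.
#' @param special Named integer vector over
#'   `no_feature, ambiguous, too_low_quality, not_aligned,
#'   alignment_not_unique` (missing entries default to 0).
#' @param total_records Total number of primary records; defaults to the
#'   sum of `counts` and `special`.
#' @return A `count_result` object.
#' @export
count_result <- function(counts, special = integer(), total_records = NULL) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  sp <- stats::setNames(integer(length(SPECIAL_COUNTERS)), SPECIAL_COUNTERS)
  if (length(special)) {
    stopifnot(all(names(special) %in% SPECIAL_COUNTERS))
    sp[names(special)] <- as.integer(special)
  }
  if (is.null(total_records)) total_records <- sum(counts) + sum(sp)
  stopifnot(all(counts >= 0L), all(sp >= 0L))
  if (sum(counts) + sum(sp) != total_records) {
    stop("count conservation violated: gene counts + special counters != ",
         "total records")
  }
  structure(list(counts = counts, special = sp,
                 total_records = as.integer(total_records)),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat("count_result:", length(x$counts), "genes,",
      sum(x$counts), "assigned /", x$total_records, "records\n")
  invisible(x)
}

# Per-gene segment index used by overlap queries: GRanges of the merged
# representative segments.
.annotation_index <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  annotation$segments
}

#' Classify one aligned read against a gene annotation
#'
#' Union-mode assignment with fixed precedence: unmapped records are
#' `not_aligned`; multi-hit records (`hit_count > 1`) are
#' `alignment_not_unique`; records below `min_quality` are
#' `too_low_quality`. Otherwise all genes whose representative segments
#' overlap any aligned block are collected: none gives `no_feature`, two or
#' more give `ambiguous`, exactly one gives that gene id. A chromosome
#' absent from the annotation is simply no overlap.
#'
#' @param read An [aligned_read()].
#' @param annotation A `gene_annotation` from [select_representative()].
#' @param min_quality Minimum MAPQ (default 10).
#' @param strand_mode `"unstranded"` (default), `"forward"` (gene strand
#'   must match the read strand) or `"reverse"` (must be opposite).
#' @return A single string: a gene id or one of `no_feature`, `ambiguous`,
#'   `too_low_quality`, `not_aligned`, `alignment_not_unique`.
#' @export
classify_read <- function(read, annotation, min_quality = 10L,
                          strand_mode = c("unstranded", "forward",
                                          "reverse")) {
  strand_mode <- match.arg(strand_mode)
  if (!read$mapped) return("not_aligned")
  if (read$hit_count > 1L) return("alignment_not_unique")
  if (read$mapping_quality < min_quality) return("too_low_quality")
  idx <- .annotation_index(annotation)
  blocks <- GenomicRanges::GRanges(
    seqnames = rep(read$chromosome, length(read$aligned_blocks)),
    ranges = read$aligned_blocks)
  # reads may name chromosomes the annotation lacks; that is no overlap,
  # not an error, so silence the seqlevel mismatch notice
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(blocks, idx, ignore.strand = TRUE))
  genes <- unique(S4Vectors::mcols(idx)$gene_id[S4Vectors::subjectHits(hits)])
  if (strand_mode != "unstranded" && length(genes)) {
    gstrand <- as.character(GenomicRanges::strand(
      idx[S4Vectors::subjectHits(hits)]))
    gmap <- stats::setNames(
      gstrand, S4Vectors::mcols(idx)$gene_id[S4Vectors::subjectHits(hits)])
    want <- if (strand_mode == "forward") read$strand else
      setdiff(c("+", "-"), read$strand)
    genes <- unique(names(gmap)[gmap[names(gmap)] %in% want &
                                  names(gmap) %in% genes])
  }
  if (length(genes) == 0L) return("no_feature")
  if (length(genes) >= 2L) return("ambiguous")
  genes
}

# Parse one SAM alignment line into an aligned_read, or NULL for
# secondary/supplementary records. `line_number` feeds error messages.
.parse_sam_record <- function(line, line_number) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
  if (length(f) < 11L) {
    stop("malformed SAM record at line ", line_number,
         ": expected >= 11 fields, got ", length(f))
  }
  flag <- suppressWarnings(as.integer(f[2L]))
  if (is.na(flag)) {
    stop("malformed SAM record at line ", line_number, ": bad FLAG '",
         f[2L], "'")
  }
  if (bitwAnd(flag, 256L) > 0L || bitwAnd(flag, 2048L) > 0L) return(NULL)
  mapped <- bitwAnd(flag, 4L) == 0L
  hit <- 1L
  nh <- grep("^NH:i:", f[-(1:11)], value = TRUE)
  if (length(nh)) hit <- as.integer(sub("^NH:i:", "", nh[1L]))
  if (!mapped) {
    return(aligned_read(f[1L], FALSE, hit_count = max(hit, 1L)))
  }
  pos <- as.integer(f[4L])
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    f[6L], pos = pos, ops = c("M", "=", "X"), reduce.ranges = TRUE)[[1L]]
  if (length(blocks) == 0L) {
    stop("malformed SAM record at line ", line_number,
         ": CIGAR '", f[6L], "' consumes no reference bases")
  }
  aligned_read(f[1L], TRUE, chromosome = f[3L], position = pos,
               aligned_blocks = blocks,
               mapping_quality = as.integer(f[5L]), hit_count = hit,
               strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+")
}

#' Count reads per gene over a SAM stream
#'
#' Applies [classify_read()] to every primary record of a SAM file (or
#' character vector of SAM lines). Secondary and supplementary records are
#' skipped without counting; paired-end mates are counted as independent
#' records. The result satisfies the conservation identity and is
#' independent of record order.
#'
#' @param sam Path to a SAM text file, or a character vector of SAM lines.
#' @param annotation A `gene_annotation`.
#' @inheritParams classify_read
#' @return A [count_result()] covering every annotated gene (zeros
#'   included).
#' @export
count_sample <- function(sam, annotation, min_quality = 10L,
                         strand_mode = c("unstranded", "forward",
                                         "reverse")) {
  strand_mode <- match.arg(strand_mode)
  lines <- if (length(sam) == 1L && file.exists(sam)) {
    readLines(sam, warn = FALSE)
  } else {
    as.character(sam)
  }
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  counts <- stats::setNames(integer(nrow(annotation$genes)),
                            annotation$genes$gene_id)
  special <- stats::setNames(integer(length(SPECIAL_COUNTERS)),
                             SPECIAL_COUNTERS)
  total <- 0L
  for (i in body) {
    read <- .parse_sam_record(lines[i], i)
    if (is.null(read)) next
    total <- total + 1L
    what <- classify_read(read, annotation, min_quality, strand_mode)
    if (what %in% SPECIAL_COUNTERS) {
      special[what] <- special[what] + 1L
    } else {
      counts[what] <- counts[what] + 1L
    }
  }
  count_result(counts, special, total)
}

#' Write / read HTSeq-count style per-sample count files
#'
#' Two-column tab-separated text: one row per gene (sorted by gene id)
#' followed by the five special rows `__no_feature`, `__ambiguous`,
#' `__too_low_aQual`, `__not_aligned`, `__alignment_not_unique`.
#'
#' @param result A [count_result()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_htseq_counts <- function(result, path) {
  stopifnot(inherits(result, "count_result"))
  g <- sort(names(result$counts))
  lines <- c(paste(g, result$counts[g], sep = "\t"),
             paste0("__no_feature\t", result$special[["no_feature"]]),
             paste0("__ambiguous\t", result$special[["ambiguous"]]),
             paste0("__too_low_aQual\t", result$special[["too_low_quality"]]),
             paste0("__not_aligned\t", result$special[["not_aligned"]]),
             paste0("__alignment_not_unique\t",
                    result$special[["alignment_not_unique"]]))
  writeLines(lines, path)
  invisible(path)
}
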