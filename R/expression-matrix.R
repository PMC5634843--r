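#' Read an HTSeq-count style per-sample count file
#'
#' @param path Two-column tab-separated file; special rows are prefixed
#'   `"__"` (`__too_low_aQual` maps to the `too_low_quality` counter;
#'   missing special rows default to 0).
#' @param sample_id Sample identifier to attach.
#' @return A `sample_counts` object: list of `sample_id` and a
#'   [count_result()].
#' @export
read_htseq_counts <- function(path, sample_id) {
  stopifnot(nzchar(sample_id))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty count file '", path, "'")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("count file '", path, "' line ", bad[1L],
         ": expected two tab-separated columns")
  }
  keys <- vapply(parts, `[`, character(1L), 1L)
  vals <- vapply(parts, `[`, character(1L), 2L)
  n <- suppressWarnings(as.numeric(vals))
  if (anyNA(n) || any(n != floor(n))) {
    stop("count file '", path, "': non-integer count for '",
         keys[which(is.na(n) | n != floor(n))[1L]], "'")
  }
  is_special <- startsWith(keys, "__")
  gk <- keys[!is_special]
  if (anyDuplicated(gk)) {
    stop("count file '", path, "': duplicate gene row '",
         gk[duplicated(gk)][1L], "'")
  }
  special_map <- c("__no_feature" = "no_feature",
                   "__ambiguous" = "ambiguous",
                   "__too_low_aQual" = "too_low_quality",
                   "__not_aligned" = "not_aligned",
                   "__alignment_not_unique" = "alignment_not_unique")
  sk <- keys[is_special]
  unknown <- setdiff(sk, names(special_map))
  if (length(unknown)) {
    stop("count file '", path, "': unknown special row '", unknown[1L], "'")
  }
  special <- stats::setNames(as.integer(n[is_special]), special_map[sk])
  structure(list(sample_id = sample_id,
                 result = count_result(
                   stats::setNames(as.integer(n[!is_special]), gk),
                   special)),
            class = "sample_counts")
}

#' Aggregate per-sample counts into an m x n count matrix
#'
#' @param samples List of `sample_counts`, all derived from the same
#'   annotation (identical gene sets).
#' @return A `count_matrix`: list with `counts`, an m x n integer matrix
#'   (rows sorted by gene id, columns in input sample order), and
#'   `special`, a 5 x n matrix of the special counters.
#' @export
aggregate_counts <- function(samples) {
  stopifnot(length(samples) >= 1L)
  ids <- vapply(samples, function(s) s$sample_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  gene_sets <- lapply(samples, function(s) sort(names(s$result$counts)))
  ref <- gene_sets[[1L]]
  for (i in seq_along(gene_sets)[-1L]) {
    if (!identical(gene_sets[[i]], ref)) {
      diff <- union(setdiff(ref, gene_sets[[i]]),
                    setdiff(gene_sets[[i]], ref))
      stop("gene sets differ between samples '", ids[1L], "' and '",
           ids[i], "': ", paste(sort(diff), collapse = ", "))
    }
  }
  counts <- vapply(samples, function(s) s$result$counts[ref],
                   integer(length(ref)))
  counts <- matrix(counts, nrow = length(ref),
                   dimnames = list(ref, ids))
  special <- vapply(samples, function(s) s$result$special,
                    integer(length(SPECIAL_COUNTERS)))
  special <- matrix(special, nrow = length(SPECIAL_COUNTERS),
                    dimnames = list(SPECIAL_COUNTERS, ids))
  structure(list(counts = counts, special = special),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

.lengths_for <- function(counts, annotation) {
  len <- if (inherits(annotation, "gene_annotation")) {
    gene_lengths(annotation)
  } else {
    annotation
  }
  missing <- setdiff(rownames(counts$counts), names(len))
  if (length(missing)) {
    stop("no gene length for: ", paste(utils::head(missing, 5L),
                                       collapse = ", "))
  }
  len[rownames(counts$counts)]
}

.expression_matrix <- function(values, normalization) {
  structure(list(values = values, normalization = normalization),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", x$normalization, "): ",
      nrow(x$values), " genes x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' RPKM normalization
#'
#' `value(g,s) = count(g,s) * 1e9 / (length(g) * columnTotal(s))`, where
#' `columnTotal(s)` is the sum of gene-assigned counts in sample `s` (the
#' only read total available from count files alone; tools that divide by
#' total mapped reads will give slightly smaller values).
#'
#' @param counts A [aggregate_counts()] `count_matrix`.
#' @param annotation A `gene_annotation` or a named vector of gene lengths
#'   in bases.
#' @return An `expression_matrix` tagged `"RPKM"`.
#' @export
compute_rpkm <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_matrix"))
  len <- .lengths_for(counts, annotation)
  totals <- colSums(counts$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero assigned reads: ",
         paste(colnames(counts$counts)[totals == 0], collapse = ", "))
  }
  v <- counts$counts * 1e9 / outer(as.numeric(len), totals)
  .expression_matrix(v, "RPKM")
}

#' TPM normalization
#'
#' Length-normalized rates `count/length` are rescaled per sample so each
#' column sums to one million.
#'
#' @inheritParams compute_rpkm
#' @return An `expression_matrix` tagged `"TPM"`; every column sums to
#'   `1e6` (relative tolerance `1e-6`).
#' @export
compute_tpm <- function(counts, annotation) {
  stopifnot(inherits(counts, "count_matrix"))
  len <- .lengths_for(counts, annotation)
  rate <- counts$counts / as.numeric(len)
  totals <- colSums(rate)
  if (any(totals == 0)) {
    stop("sample(s) with zero assigned reads: ",
         paste(colnames(counts$counts)[totals == 0], collapse = ", "))
  }
  v <- sweep(rate, 2L, totals, "/") * 1e6
  .expression_matrix(v, "TPM")
}

#' Write / read an expression matrix as TSV
#'
#' First line is a `# normalization: <tag>` comment; then a header row
#' (`gene` plus one column per sample) and tab-separated values with six
#' significant digits.
#'
#' @param expr An `expression_matrix`.
#' @param path File path.
#' @return `write_expression_matrix` returns `path` invisibly;
#'   `read_expression_matrix` returns an `expression_matrix`.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# normalization: ", expr$normalization), con)
  writeLines(paste(c("gene", colnames(expr$values)), collapse = "\t"), con)
  body <- apply(expr$values, 1L, function(row)
    paste(sprintf("%.6g", row), collapse = "\t"))
  writeLines(paste(rownames(expr$values), body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- if (grepl("^# normalization:", first)) {
    trimws(sub("^# normalization:", "", first))
  } else {
    "raw"
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- tab[[1L]]
  .expression_matrix(v, tag)
}

#' Drop sample columns from a count matrix
#'
#' Explicit sample exclusion (e.g. after a QC report); samples are never
#' removed implicitly.
#'
#' @param counts A `count_matrix`.
#' @param drop Character vector of sample ids to remove.
#' @return A `count_matrix` without the given columns.
#' @export
drop_samples <- function(counts, drop) {
  stopifnot(inherits(counts, "count_matrix"))
  unknown <- setdiff(drop, colnames(counts$counts))
  if (length(unknown)) {
    stop("unknown sample(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(colnames(counts$counts), drop)
  if (length(keep) == 0L) stop("cannot drop every sample")
  structure(list(counts = counts$counts[, keep, drop = FALSE],
                 special = counts$special[, keep, drop = FALSE]),
            class = "count_matrix")
}
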