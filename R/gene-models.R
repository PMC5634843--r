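#' Parse transcript models from a GFF3 annotation
#'
#' Reads a GFF3 file and collects, for every transcript, the genomic
#' segments of a given feature type (coding segments by default). Parentage
#' is resolved through the `Parent` attribute: a segment row must name a
#' declared transcript feature, and a transcript without a `Parent` of its
#' own is treated as its own gene.
#'
#' @param path Path to a 9-column GFF3 file.
#' @param feature_type Feature type whose rows become transcript segments.
#'   `"CDS"` by default; use `"exon"` for annotations lacking CDS rows.
#' @return A `transcript_models` object: a data frame with one row per
#'   segment and columns `transcript_id`, `gene_id`, `chromosome`, `strand`,
#'   `start`, `end` (1-based inclusive, copied verbatim from the file).
#' @export
parse_gff3 <- function(path, feature_type = "CDS") {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  gff <- rtracklayer::readGFF(path)
  if (nrow(gff) == 0L) {
    stop("no features found in GFF3 file '", path, "'")
  }
  # map table rows back to file line numbers for error reporting
  raw <- readLines(path, warn = FALSE)
  feature_lines <- which(!grepl("^\\s*(#|$)", raw) & !grepl("^>", raw))
  fasta <- grep("^##FASTA", raw)
  if (length(fasta)) feature_lines <- feature_lines[feature_lines < fasta[1L]]

  ids <- as.character(gff$ID)
  parents <- if ("Parent" %in% names(gff)) gff$Parent else
    rep(list(character()), nrow(gff))

  seg_rows <- which(gff$type == feature_type)
  if (length(seg_rows) == 0L) {
    stop("no features of type '", feature_type, "' in '", path, "'")
  }

  # a transcript is any feature a segment names as Parent; it must exist
  declared <- ids[!is.na(ids)]
  seg_list <- lapply(seg_rows, function(i) {
    par <- as.character(parents[[i]])
    if (length(par) == 0L || all(is.na(par))) {
      # segment with no Parent but an ID: a single-feature gene model
      if (!is.na(ids[i])) return(data.frame(
        transcript_id = ids[i], row = i, stringsAsFactors = FALSE))
      stop("GFF3 parse error at line ", feature_lines[i],
           ": ", feature_type, " row has no resolvable Parent")
    }
    missing <- setdiff(par, declared)
    if (length(missing)) {
      stop("GFF3 parse error at line ", feature_lines[i],
           ": Parent '", missing[1L], "' is not declared in the file")
    }
    data.frame(transcript_id = par, row = i, stringsAsFactors = FALSE)
  })
  seg <- do.call(rbind, seg_list)

  # transcript -> gene via the transcript row's own Parent
  tx_row <- match(seg$transcript_id, ids)
  gene_of_tx <- vapply(seq_along(tx_row), function(k) {
    i <- tx_row[k]
    par <- as.character(parents[[i]])
    if (length(par) >= 1L && !is.na(par[1L])) par[1L] else seg$transcript_id[k]
  }, character(1L))

  out <- data.frame(
    transcript_id = seg$transcript_id,
    gene_id = gene_of_tx,
    chromosome = as.character(gff$seqid[seg$row]),
    strand = as.character(gff$strand[seg$row]),
    start = as.integer(gff$start[seg$row]),
    end = as.integer(gff$end[seg$row]),
    stringsAsFactors = FALSE
  )
  bad <- out$start > out$end
  if (any(bad)) {
    stop("GFF3 parse error at line ", feature_lines[seg$row[which(bad)[1L]]],
         ": start > end")
  }
  class(out) <- c("transcript_models", "data.frame")
  out
}

#' Select the representative (longest) transcript per gene
#'
#' For every gene keeps the transcript whose merged segment union is
#' longest; overlapping segments within a transcript are merged before
#' summing so no base is counted twice in the length used as the TPM/RPKM
#' denominator. Ties are broken by the lexicographically smallest
#' transcript id, so builds are deterministic.
#'
#' @param transcripts A `transcript_models` data frame from [parse_gff3()].
#' @return A `gene_annotation` object: a list with `genes`, a data frame of
#'   `gene_id`, `transcript_id`, `chromosome`, `strand`, `length` (one row
#'   per gene, sorted by `gene_id`), and `segments`, a
#'   [GenomicRanges::GRanges] of the representatives' merged segments with a
#'   `gene_id` metadata column.
#' @export
select_representative <- function(transcripts) {
  stopifnot(inherits(transcripts, "data.frame"), nrow(transcripts) > 0L)
  key <- paste(transcripts$gene_id, transcripts$transcript_id, sep = "\r")
  union_len <- vapply(split(seq_len(nrow(transcripts)), key), function(idx) {
    r <- IRanges::reduce(IRanges::IRanges(transcripts$start[idx],
                                          transcripts$end[idx]))
    sum(IRanges::width(r))
  }, numeric(1L))
  parts <- do.call(rbind, strsplit(names(union_len), "\r", fixed = TRUE))
  tx_tab <- data.frame(gene_id = parts[, 1L], transcript_id = parts[, 2L],
                       length = as.integer(union_len),
                       stringsAsFactors = FALSE)
  tx_tab <- tx_tab[order(tx_tab$gene_id, -tx_tab$length, tx_tab$transcript_id), ]
  rep_tab <- tx_tab[!duplicated(tx_tab$gene_id), ]

  keep <- transcripts$transcript_id %in% rep_tab$transcript_id &
    transcripts$gene_id %in% rep_tab$gene_id
  seg <- transcripts[keep, , drop = FALSE]
  # merge overlapping segments of each representative
  gr <- GenomicRanges::GRanges(
    seqnames = seg$chromosome,
    ranges = IRanges::IRanges(seg$start, seg$end),
    strand = seg$strand)
  S4Vectors::mcols(gr)$gene_id <- seg$gene_id
  grl <- S4Vectors::split(gr, seg$gene_id)
  merged <- unlist(GenomicRanges::reduce(grl), use.names = TRUE)
  S4Vectors::mcols(merged)$gene_id <- names(merged)
  names(merged) <- NULL

  meta <- seg[!duplicated(seg$gene_id),
              c("gene_id", "transcript_id", "chromosome", "strand")]
  genes <- merge(rep_tab[, c("gene_id", "length")],
                 meta[, c("gene_id", "chromosome", "strand")],
                 by = "gene_id")
  genes$transcript_id <- rep_tab$transcript_id[match(genes$gene_id,
                                                     rep_tab$gene_id)]
  genes <- genes[order(genes$gene_id),
                 c("gene_id", "transcript_id", "chromosome", "strand",
                   "length")]
  rownames(genes) <- NULL
  stopifnot(all(genes$length > 0L))
  structure(list(genes = genes, segments = merged),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      length(x$segments), "merged segments\n")
  invisible(x)
}

#' Gene lengths of a gene annotation
#' @param annotation A `gene_annotation`.
#' @return Named integer vector of merged representative lengths (bases).
#' @export
gene_lengths <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  stats::setNames(annotation$genes$length, annotation$genes$gene_id)
}

#' Write / read a two-column gene-length table
#'
#' Plain `gene_id<TAB>length` text, one row per gene, no header.
#' @param annotation A `gene_annotation` (or named length vector for
#'   `write_gene_lengths`).
#' @param path Output (input) file path.
#' @return `write_gene_lengths` returns `path` invisibly;
#'   `read_gene_lengths` returns a named integer vector.
#' @export
write_gene_lengths <- function(annotation, path) {
  len <- if (inherits(annotation, "gene_annotation")) {
    gene_lengths(annotation)
  } else {
    annotation
  }
  utils::write.table(
    data.frame(gene_id = names(len), length = as.integer(len)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_lengths
#' @export
read_gene_lengths <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene_id", "length"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$length, tab$gene_id)
}
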