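#' Specification for a synthetic modular count matrix
#'
#' Describes the generative model used to emulate a bulk RNA-seq compendium
#' with planted co-expression modules: module genes share a latent
#' per-sample log-normal activity, all genes carry a log-normal baseline,
#' samples differ in library scale, and counts are negative-binomial with
#' variance `mean + mean^2 / dispersion`.
#'
#' Defaults describe a desk-scale compendium: 5 modules of 40 genes plus
#' 200 background genes over 60 samples, with strong module activity
#' spread (sd 1.5 on the log scale) and moderate overdispersion
#' (dispersion 10) — enough samples and signal for module recovery to be a
#' meaningful benchmark without approaching real-compendium sizes.
#'
#' @param n_modules Number of planted modules.
#' @param genes_per_module Genes per module.
#' @param n_background_genes Genes with no shared activity.
#' @param n_samples Number of samples.
#' @param activity_sd Standard deviation of per-module log activity across
#'   samples.
#' @param dispersion Negative-binomial size parameter.
#' @param library_scale_range Per-sample library scale, uniform in this
#'   range.
#' @param gene_length_range Gene lengths, uniform integers in this range
#'   (bases).
#' @param seed Mandatory RNG seed; generators are pure functions of spec +
#'   seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_modules = 5L, genes_per_module = 40L,
                           n_background_genes = 200L, n_samples = 60L,
                           activity_sd = 1.5, dispersion = 10,
                           library_scale_range = c(0.5, 2),
                           gene_length_range = c(500L, 5000L),
                           seed) {
  stopifnot(n_modules >= 1L, genes_per_module >= 1L,
            n_background_genes >= 0L, n_samples >= 1L,
            activity_sd >= 0, dispersion > 0,
            length(library_scale_range) == 2L,
            all(library_scale_range > 0),
            diff(library_scale_range) >= 0,
            length(gene_length_range) == 2L,
            all(gene_length_range >= 1),
            diff(gene_length_range) >= 0)
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  structure(list(n_modules = as.integer(n_modules),
                 genes_per_module = as.integer(genes_per_module),
                 n_background_genes = as.integer(n_background_genes),
                 n_samples = as.integer(n_samples),
                 activity_sd = activity_sd, dispersion = dispersion,
                 library_scale_range = library_scale_range,
                 gene_length_range = as.integer(gene_length_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a count matrix with planted co-expression modules
#'
#' For each module `m` a latent per-sample activity
#' `a_m(s) = exp(Normal(0, activity_sd))` is drawn; every gene gets a
#' log-normal baseline; the negative-binomial mean of a module gene is
#' `baseline * a_m(s) * library_scale(s)` and of a background gene
#' `baseline * library_scale(s)`. Activity is multiplicative on a shared
#' baseline, so TPM normalization (which removes the library scale)
#' preserves the planted correlation structure.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `counts` (a `count_matrix`, special counters zero),
#'   `lengths` (named integer vector of gene lengths), and `truth` (data
#'   frame `gene_id`, `module`, where background genes are labelled
#'   `"background"`).
#' @export
generate_modular_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n_mod_genes <- spec$n_modules * spec$genes_per_module
  m <- n_mod_genes + spec$n_background_genes
  n <- spec$n_samples
  gene_ids <- c(
    sprintf("MOD%02d_G%03d",
            rep(seq_len(spec$n_modules), each = spec$genes_per_module),
            rep(seq_len(spec$genes_per_module), spec$n_modules)),
    if (spec$n_background_genes > 0L)
      sprintf("BACK_G%03d", seq_len(spec$n_background_genes)))
  module <- c(rep(sprintf("module%02d", seq_len(spec$n_modules)),
                  each = spec$genes_per_module),
              rep("background", spec$n_background_genes))
  sample_ids <- sprintf("sample%03d", seq_len(n))

  baseline <- stats::rlnorm(m, meanlog = log(100), sdlog = 1)
  lib <- stats::runif(n, spec$library_scale_range[1L],
                      spec$library_scale_range[2L])
  activity <- matrix(exp(stats::rnorm(spec$n_modules * n, 0,
                                      spec$activity_sd)),
                     nrow = spec$n_modules)
  mu <- matrix(0, m, n)
  for (g in seq_len(m)) {
    act <- if (module[g] == "background") rep(1, n) else
      activity[match(module[g], sprintf("module%02d",
                                        seq_len(spec$n_modules))), ]
    mu[g, ] <- baseline[g] * act * lib
  }
  counts <- matrix(stats::rnbinom(m * n, mu = mu, size = spec$dispersion),
                   m, n, dimnames = list(gene_ids, sample_ids))
  lengths <- stats::setNames(
    sample(spec$gene_length_range[1L]:spec$gene_length_range[2L], m,
           replace = TRUE),
    gene_ids)
  cm <- structure(
    list(counts = counts,
         special = matrix(0L, length(SPECIAL_COUNTERS), n,
                          dimnames = list(SPECIAL_COUNTERS, sample_ids))),
    class = "count_matrix")
  list(counts = cm, lengths = lengths,
       truth = data.frame(gene_id = gene_ids, module = module,
                          stringsAsFactors = FALSE))
}

#' Generate a SAM fixture with a known counting ground truth
#'
#' Emits SAM text whose reads fall into requested assignment categories by
#' construction — placement inside one gene, spliced placement spanning
#' two genes (ambiguous), placement outside all genes (no_feature),
#' unmapped flag, NH:i:2 (alignment_not_unique), or MAPQ 0
#' (too_low_quality, assuming the counting quality cutoff exceeds 0) —
#' together with the exact [count_result()] that counting the fixture must
#' reproduce. Read order is shuffled under the seed.
#'
#' @param annotation A non-empty `gene_annotation`.
#' @param n_reads_per_category Named integer vector; names are gene ids of
#'   the annotation or special categories `ambiguous`, `no_feature`,
#'   `not_aligned`, `alignment_not_unique`, `too_low_quality`.
#' @param read_length Read length in bases (capped at the target segment
#'   width for in-gene placements).
#' @param seed RNG seed for the output shuffle.
#' @return A list with `sam` (character vector of SAM lines including
#'   headers) and `truth` (the expected `count_result`).
#' @export
generate_sam_fixture <- function(annotation, n_reads_per_category,
                                 read_length = 50L, seed) {
  stopifnot(inherits(annotation, "gene_annotation"),
            length(n_reads_per_category) >= 1L,
            !is.null(names(n_reads_per_category)),
            all(n_reads_per_category >= 0L), read_length >= 1L)
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  set.seed(seed)
  genes <- annotation$genes
  seg <- annotation$segments
  seg_gene <- S4Vectors::mcols(seg)$gene_id
  categories <- c("ambiguous", "no_feature", "not_aligned",
                  "alignment_not_unique", "too_low_quality")
  unknown <- setdiff(names(n_reads_per_category),
                     c(genes$gene_id, categories))
  if (length(unknown)) {
    stop("unknown category/gene: ", paste(unknown, collapse = ", "))
  }
  chrom_max <- tapply(GenomicRanges::end(seg),
                      as.character(GenomicRanges::seqnames(seg)), max)

  # a placement inside gene g that no other gene's segments touch
  place_in_gene <- function(g) {
    own <- which(seg_gene == g)
    for (i in own) {
      w <- min(read_length, GenomicRanges::width(seg)[i])
      start <- GenomicRanges::start(seg)[i]
      cand <- GenomicRanges::GRanges(GenomicRanges::seqnames(seg)[i],
                                     IRanges::IRanges(start, start + w - 1L))
      hits <- GenomicRanges::findOverlaps(cand, seg, ignore.strand = TRUE)
      touched <- unique(seg_gene[S4Vectors::subjectHits(hits)])
      if (identical(touched, g)) {
        return(list(chrom = as.character(GenomicRanges::seqnames(seg)[i]),
                    pos = start, cigar = paste0(w, "M")))
      }
    }
    stop("cannot place an unambiguous read inside gene '", g,
         "': all its segments overlap other genes")
  }

  # a spliced placement spanning two distinct genes on one chromosome
  place_ambiguous <- function() {
    for (chrom in names(chrom_max)) {
      on_chr <- which(as.character(GenomicRanges::seqnames(seg)) == chrom)
      gset <- unique(seg_gene[on_chr])
      if (length(gset) < 2L) next
      a <- on_chr[seg_gene[on_chr] == gset[1L]][1L]
      b <- on_chr[seg_gene[on_chr] == gset[2L]][1L]
      if (GenomicRanges::start(seg)[a] > GenomicRanges::start(seg)[b]) {
        tmp <- a; a <- b; b <- tmp
      }
      wa <- min(25L, GenomicRanges::width(seg)[a])
      pos <- GenomicRanges::start(seg)[a]
      block1_end <- pos + wa - 1L
      bstart <- max(GenomicRanges::start(seg)[b], block1_end + 2L)
      if (bstart + 24L > GenomicRanges::end(seg)[b]) next
      gap <- bstart - block1_end - 1L
      return(list(chrom = chrom, pos = pos,
                  cigar = paste0(wa, "M", gap, "N", 25L, "M")))
    }
    stop("ambiguous reads unachievable: no chromosome carries two genes ",
         "with a usable spliced placement")
  }

  records <- list()
  truth_counts <- stats::setNames(integer(nrow(genes)), genes$gene_id)
  truth_special <- stats::setNames(integer(length(SPECIAL_COUNTERS)),
                                   SPECIAL_COUNTERS)
  rid <- 0L
  emit <- function(chrom, pos, cigar, flag = 0L, mapq = 60L, tags = "") {
    rid <<- rid + 1L
    paste(c(sprintf("read%05d", rid), flag, chrom, pos, mapq, cigar, "*",
            0L, 0L, "A", "I", if (nzchar(tags)) tags), collapse = "\t")
  }
  for (nm in names(n_reads_per_category)) {
    k <- n_reads_per_category[[nm]]
    if (k == 0L) next
    if (nm %in% genes$gene_id) {
      p <- place_in_gene(nm)
      for (i in seq_len(k)) {
        records[[length(records) + 1L]] <- emit(p$chrom, p$pos, p$cigar)
      }
      truth_counts[nm] <- truth_counts[nm] + k
    } else if (nm == "ambiguous") {
      p <- place_ambiguous()
      for (i in seq_len(k)) {
        records[[length(records) + 1L]] <- emit(p$chrom, p$pos, p$cigar)
      }
      truth_special["ambiguous"] <- truth_special["ambiguous"] + k
    } else if (nm == "no_feature") {
      chrom <- names(chrom_max)[1L]
      pos <- chrom_max[[1L]] + 1000L
      for (i in seq_len(k)) {
        records[[length(records) + 1L]] <-
          emit(chrom, pos, paste0(read_length, "M"))
      }
      truth_special["no_feature"] <- truth_special["no_feature"] + k
    } else if (nm == "not_aligned") {
      for (i in seq_len(k)) {
        rid <- rid + 1L
        records[[length(records) + 1L]] <-
          paste(c(sprintf("read%05d", rid), 4L, "*", 0L, 0L, "*", "*",
                  0L, 0L, "A", "I"), collapse = "\t")
      }
      truth_special["not_aligned"] <- truth_special["not_aligned"] + k
    } else if (nm == "alignment_not_unique") {
      p <- place_in_gene(genes$gene_id[1L])
      for (i in seq_len(k)) {
        records[[length(records) + 1L]] <-
          emit(p$chrom, p$pos, p$cigar, tags = "NH:i:2")
      }
      truth_special["alignment_not_unique"] <-
        truth_special["alignment_not_unique"] + k
    } else if (nm == "too_low_quality") {
      p <- place_in_gene(genes$gene_id[1L])
      for (i in seq_len(k)) {
        records[[length(records) + 1L]] <-
          emit(p$chrom, p$pos, p$cigar, mapq = 0L)
      }
      truth_special["too_low_quality"] <-
        truth_special["too_low_quality"] + k
    }
  }
  body <- unlist(records)
  if (length(body) > 1L) body <- sample(body)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_max),
                      as.integer(chrom_max + 5000L)))
  list(sam = c(header, body),
       truth = count_result(truth_counts, truth_special))
}

#' Generate mapper summaries and count results with known QC metrics
#'
#' For each requested `(genome_pct, coding_pct)` profile, emits a
#' TopHat2-style `align_summary.txt` whose overall mapping rate parses to
#' `genome_pct`, and a [count_result()] over 1000 mapped records whose
#' [coding_fraction()] equals `coding_pct` to one decimal place.
#'
#' @param profiles Data frame (or list of length-2 vectors) of
#'   `genome_pct` and `coding_pct`, both in `[0, 100]`.
#' @return A list with `summaries` (character vector, one summary text per
#'   profile), `counts` (list of `count_result`), and `stats` (data frame
#'   `sample_id`, `genome_mapping_pct`, `coding_pct` as generated).
#' @export
generate_qc_fixture <- function(profiles) {
  if (!is.data.frame(profiles)) {
    profiles <- as.data.frame(do.call(rbind, profiles))
    names(profiles) <- c("genome_pct", "coding_pct")
  }
  stopifnot(all(profiles$genome_pct >= 0), all(profiles$genome_pct <= 100),
            all(profiles$coding_pct >= 0), all(profiles$coding_pct <= 100))
  n <- nrow(profiles)
  sample_ids <- sprintf("qc_sample%02d", seq_len(n))
  summaries <- character(n)
  counts <- vector("list", n)
  for (i in seq_len(n)) {
    gpct <- profiles$genome_pct[i]
    cpct <- profiles$coding_pct[i]
    input <- 1000000L
    mapped <- round(input * gpct / 100)
    summaries[i] <- paste(
      c("Reads:",
        sprintf("          Input     :  %d", input),
        sprintf("           Mapped   :  %d (%s%% of input)", mapped,
                formatC(gpct, format = "fg")),
        sprintf("%.1f%% overall read mapping rate.", gpct)),
      collapse = "\n")
    assigned <- as.integer(round(cpct * 10))
    counts[[i]] <- count_result(
      stats::setNames(assigned, "g1"),
      c(no_feature = 1000L - assigned))
  }
  list(summaries = summaries, counts = counts,
       stats = data.frame(sample_id = sample_ids,
                          genome_mapping_pct = profiles$genome_pct,
                          coding_pct = round(profiles$coding_pct * 10) / 10,
                          stringsAsFactors = FALSE))
}
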