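#' Read an INI-style pipeline configuration
#'
#' Minimal INI: `[section]` headers, `key = value` entries, `#` or `;`
#' comments. Two sections are meaningful: `[paths]` (annotation,
#' counts_dir or sam_dir, summaries_dir, output_dir) and `[parameters]`
#' (see [validate_config()] for names and defaults).
#'
#' @param path INI file path.
#' @return A nested list of sections.
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[#;].*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      out[[section]][[key]] <- trimws(paste(kv[-1L], collapse = "="))
    }
  }
  out
}

.param_defaults <- list(
  feature_type = "CDS", min_quality = 10, strand_mode = "unstranded",
  genome_min_pct = 65, coding_min_pct = 40, exclude_flagged = FALSE,
  pcc_cutoff = 0.7, neighbor_k = 1000, mcl_inflation = 2, resume = FALSE)

.as_bool <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "yes", "1")
}

#' Validate a pipeline configuration
#'
#' Checks the configuration in one pass and reports every missing field
#' and every nonexistent path together (not fail-fast). Requires an
#' `output_dir`, a gene-length source (`annotation` GFF3 or a `lengths`
#' table) and a count source (`counts_dir` of HTSeq-style files or a
#' `sam_dir` of SAM files, the latter also needing `annotation`).
#'
#' @param config Nested list as from [read_pipeline_config()], with
#'   `paths` and optional `parameters` entries.
#' @return A validated `pipeline_config` with parameter defaults filled
#'   in, or an error aggregating every problem found.
#' @export
validate_config <- function(config) {
  problems <- character()
  paths <- config$paths
  if (is.null(paths)) {
    problems <- c(problems, "missing section: [paths]")
    paths <- list()
  }
  if (is.null(paths$output_dir)) {
    problems <- c(problems, "missing field: paths.output_dir")
  }
  if (is.null(paths$annotation) && is.null(paths$lengths)) {
    problems <- c(problems,
                  "missing field: paths.annotation (or paths.lengths)")
  }
  if (is.null(paths$counts_dir) && is.null(paths$sam_dir)) {
    problems <- c(problems,
                  "missing field: paths.counts_dir (or paths.sam_dir)")
  }
  if (!is.null(paths$sam_dir) && is.null(paths$annotation)) {
    problems <- c(problems,
                  "counting from paths.sam_dir requires paths.annotation")
  }
  for (key in c("annotation", "lengths", "counts_dir", "sam_dir",
                "summaries_dir")) {
    p <- paths[[key]]
    if (!is.null(p) && !file.exists(p)) {
      problems <- c(problems,
                    sprintf("path does not exist: paths.%s = %s", key, p))
    }
  }
  params <- utils::modifyList(.param_defaults,
                              as.list(config$parameters %||% list()))
  unknown <- setdiff(names(params), names(.param_defaults))
  if (length(unknown)) {
    problems <- c(problems,
                  paste0("unknown parameter(s): ",
                         paste(unknown, collapse = ", ")))
  }
  for (key in c("min_quality", "genome_min_pct", "coding_min_pct",
                "pcc_cutoff", "neighbor_k", "mcl_inflation")) {
    params[[key]] <- suppressWarnings(as.numeric(params[[key]]))
    if (is.na(params[[key]])) {
      problems <- c(problems, paste0("parameter not numeric: ", key))
    }
  }
  for (key in c("exclude_flagged", "resume")) {
    params[[key]] <- .as_bool(params[[key]])
  }
  if (!is.na(params$pcc_cutoff) &&
      (params$pcc_cutoff <= -1 || params$pcc_cutoff >= 1)) {
    problems <- c(problems, "pcc_cutoff must be in (-1, 1)")
  }
  if (!is.na(params$mcl_inflation) && params$mcl_inflation <= 1) {
    problems <- c(problems, "mcl_inflation must be > 1")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(paths = paths, parameters = params),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full co-expression pipeline
#'
#' Executes, in order: gene lengths, per-sample read counting (when a SAM
#' directory is given), matrix aggregation, the QC report, optional
#' exclusion of QC-flagged samples (only when `exclude_flagged` is set —
#' flagged samples are otherwise processed), TPM and RPKM normalization,
#' all-pairs correlation, the top-neighbor table, the thresholded network,
#' MCL clustering, and diagnostics. Every artifact is written under
#' `output_dir` and listed in `manifest.json`; a stage failure halts with
#' the stage name and leaves earlier artifacts in place. With
#' `resume = true`, stages whose artifacts already exist are loaded
#' instead of recomputed.
#'
#' @param config A `pipeline_config` from [validate_config()] (a raw list
#'   is validated first).
#' @return Named list of artifact paths (the manifest), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  paths <- config$paths
  p <- config$parameters
  out <- paths$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(out, "pipeline.log")
  log_msg <- function(...) {
    cat(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ..., "\n",
        sep = "", file = log_file, append = TRUE)
  }
  art <- list()
  stage <- function(name, fun) {
    log_msg("stage ", name, ": start")
    res <- tryCatch(fun(), error = function(e) {
      log_msg("stage ", name, ": FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_msg("stage ", name, ": done")
    res
  }

  # --- gene lengths -------------------------------------------------
  lengths_path <- file.path(out, "gene_lengths.tsv")
  annotation <- NULL
  lengths <- stage("lengths", function() {
    if (p$resume && file.exists(lengths_path)) {
      return(read_gene_lengths(lengths_path))
    }
    if (!is.null(paths$annotation)) {
      annotation <<- select_representative(
        parse_gff3(paths$annotation, feature_type = p$feature_type))
      len <- gene_lengths(annotation)
    } else {
      len <- read_gene_lengths(paths$lengths)
    }
    write_gene_lengths(len, lengths_path)
    len
  })
  art$gene_lengths <- lengths_path

  # --- per-sample counting (optional) -------------------------------
  counts_dir <- paths$counts_dir
  if (is.null(counts_dir)) {
    counts_dir <- file.path(out, "counts")
    dir.create(counts_dir, showWarnings = FALSE)
    stage("count", function() {
      if (is.null(annotation)) {
        annotation <<- select_representative(
          parse_gff3(paths$annotation, feature_type = p$feature_type))
      }
      sams <- list.files(paths$sam_dir, pattern = "\\.sam$",
                         full.names = TRUE)
      done <- list.files(counts_dir, pattern = "\\.tsv$")
      if (length(sams) == 0L && !(p$resume && length(done))) {
        stop("no .sam files in ", paths$sam_dir)
      }
      for (f in sort(sams)) {
        dest <- file.path(counts_dir,
                          paste0(sub("\\.sam$", "", basename(f)),
                                 ".counts.tsv"))
        if (p$resume && file.exists(dest)) next
        write_htseq_counts(
          count_sample(f, annotation, min_quality = p$min_quality,
                       strand_mode = p$strand_mode),
          dest)
      }
      NULL
    })
  }
  art$counts_dir <- counts_dir

  # --- aggregation --------------------------------------------------
  samples <- stage("aggregate", function() {
    files <- sort(list.files(counts_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no count files in ", counts_dir)
    lapply(files, function(f)
      read_htseq_counts(f, sub("\\.(counts\\.)?tsv$", "", basename(f))))
  })
  counts <- aggregate_counts(samples)
  raw_path <- file.path(out, "raw_matrix.tsv")
  write_expression_matrix(.expression_matrix(counts$counts, "raw"),
                          raw_path)
  art$raw_matrix <- raw_path

  # --- QC -----------------------------------------------------------
  qc_path <- file.path(out, "qc_report.tsv")
  report <- stage("qc", function() {
    genome <- rep(NA_real_, length(samples))
    if (!is.null(paths$summaries_dir)) {
      for (i in seq_along(samples)) {
        sid <- samples[[i]]$sample_id
        cand <- list.files(paths$summaries_dir, full.names = TRUE,
                           pattern = paste0("^", sid))
        if (length(cand)) {
          txt <- readLines(cand[1L], warn = FALSE)
          genome[i] <- tryCatch(
            parse_mapper_summary(txt, "tophat2"),
            error = function(e) parse_mapper_summary(txt, "hisat2"))
        }
      }
    }
    stats_tab <- data.frame(
      sample_id = vapply(samples, function(s) s$sample_id, character(1L)),
      genome_mapping_pct = genome,
      coding_pct = vapply(samples, function(s) coding_fraction(s$result),
                          numeric(1L)),
      stringsAsFactors = FALSE)
    rep <- flag_samples(stats_tab,
                        qc_thresholds(p$genome_min_pct, p$coding_min_pct))
    write_qc_report(rep, qc_path)
    rep
  })
  art$qc_report <- qc_path

  # --- optional exclusion, normalization ----------------------------
  if (p$exclude_flagged) {
    drop <- report$sample_id[report$flag != "pass"]
    if (length(drop)) {
      if (length(drop) == length(samples)) {
        stop("pipeline stage 'normalize' failed: every sample is ",
             "QC-flagged; nothing left to normalize", call. = FALSE)
      }
      counts <- drop_samples(counts, drop)
    }
  }
  tpm_path <- file.path(out, "tpm_matrix.tsv")
  rpkm_path <- file.path(out, "rpkm_matrix.tsv")
  tpm <- stage("normalize", function() {
    tpm <- compute_tpm(counts, lengths)
    write_expression_matrix(tpm, tpm_path)
    write_expression_matrix(compute_rpkm(counts, lengths), rpkm_path)
    tpm
  })
  art$tpm_matrix <- tpm_path
  art$rpkm_matrix <- rpkm_path

  # --- correlation, neighbors, network ------------------------------
  corr <- stage("pcc", function() pcc_all(tpm))
  neighbors_path <- file.path(out, "neighbors.tsv")
  stage("neighbors", function() {
    write_neighbor_table(top_neighbors(corr, k = p$neighbor_k),
                         neighbors_path)
  })
  art$neighbor_table <- neighbors_path
  network_path <- file.path(out, "network.tsv")
  network <- stage("network", function() {
    net <- build_network(corr, cutoff = p$pcc_cutoff)
    write_edge_list(net, network_path)
    net
  })
  art$network <- network_path

  # --- clustering ---------------------------------------------------
  clusters_path <- file.path(out, "clusters.tsv")
  stage("cluster", function() {
    if (nrow(network) == 0L) {
      writeLines(character(), clusters_path)
      log_msg("stage cluster: network empty, no clusters")
    } else {
      write_clusters(
        mcl_cluster(network,
                    mcl_parameters(inflation = p$mcl_inflation)),
        clusters_path)
    }
  })
  art$clusters <- clusters_path

  # --- diagnostics --------------------------------------------------
  stage("diagnostics", function() {
    if (nrow(network) > 0L) {
      dd <- degree_distribution(network)
      write_degree_distribution(dd, file.path(out,
                                              "degree_distribution.tsv"))
      art$degree_distribution <<- file.path(out, "degree_distribution.tsv")
      if (nrow(dd) >= 3L) {
        fit <- fit_power_law(dd)
        fit_tab <- data.frame(slope = fit$slope,
                              intercept = fit$intercept,
                              r_squared = fit$r_squared,
                              n_points = fit$n_points)
        utils::write.table(fit_tab, file.path(out, "power_law.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        art$power_law <<- file.path(out, "power_law.tsv")
      }
    }
    if (ncol(tpm$values) >= 2L) {
      write_projection(pca_samples(tpm), file.path(out, "pca.tsv"))
      art$pca <<- file.path(out, "pca.tsv")
      dendrogram_newick(cluster_samples(tpm),
                        file.path(out, "samples.nwk"))
      art$sample_dendrogram <<- file.path(out, "samples.nwk")
    }
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(art, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  art$manifest <- manifest_path
  log_msg("pipeline complete")
  invisible(art)
}
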