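#' Node degree distribution of a network
#'
#' Degree is the number of incident edges; the distribution covers every
#' node present in the edge list (degree-0 genes are not represented in an
#' edge list and so are excluded).
#'
#' @param network A non-empty `coexpression_network`.
#' @return A `degree_distribution`: data frame of `degree`, `frequency`,
#'   sorted by degree.
#' @export
degree_distribution <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  if (nrow(network) == 0L) stop("network has no edges")
  deg <- table(c(network$gene_a, network$gene_b))
  tab <- table(as.integer(deg))
  out <- data.frame(degree = as.integer(names(tab)),
                    frequency = as.integer(tab))
  out <- out[order(out$degree), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Straight-line power-law fit of a degree distribution
#'
#' Scale-free networks show node frequency falling off as a power of
#' degree, i.e. a straight line in log-log space. This fits ordinary
#' least squares on `(log10 degree, log10 frequency)` over the observed
#' degrees and reports the slope (the power-law exponent), intercept and
#' r-squared as a goodness-of-straight-line diagnostic.
#'
#' @param dd A `degree_distribution` with at least 3 distinct degrees.
#' @return A `power_law_fit`: list of `slope`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
fit_power_law <- function(dd) {
  stopifnot(inherits(dd, "data.frame"),
            all(c("degree", "frequency") %in% names(dd)))
  if (nrow(dd) < 3L) {
    stop("need at least 3 distinct degrees to fit a power law, got ",
         nrow(dd))
  }
  fit <- stats::lm(log10(frequency) ~ log10(degree), data = dd)
  # exact power laws are legitimate input; silence lm's perfect-fit notice
  s <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = s$r.squared,
                 n_points = nrow(dd)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: slope %.3f, r^2 %.3f over %d degrees\n",
              x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' PCA of samples from an expression matrix
#'
#' Expression values are transformed `log2(x + 1)`, genes are centered
#' across samples, and samples are projected onto the leading principal
#' components via singular value decomposition. Each component's sign is
#' fixed so that its largest-magnitude gene loading is positive, making
#' projections deterministic.
#'
#' @param expr An `expression_matrix` with at least 2 genes and 2 samples.
#' @param n_components Number of components to return (capped at the
#'   matrix rank).
#' @return A `sample_projection`: list with `coordinates` (samples x
#'   components, named `PC1`, `PC2`, ...) and `explained_variance_ratio`
#'   (non-increasing, each in `[0, 1]`, over the returned components).
#' @export
pca_samples <- function(expr, n_components = 2L) {
  stopifnot(inherits(expr, "expression_matrix"), n_components >= 1L)
  v <- expr$values
  if (nrow(v) < 2L || ncol(v) < 2L) {
    stop("need at least 2 genes and 2 samples for PCA")
  }
  x <- log2(v + 1)
  ctr <- x - rowMeans(x)
  if (all(abs(ctr) < .Machine$double.eps * 4)) {
    stop("all genes have zero variance across samples; PCA undefined")
  }
  sv <- svd(t(ctr))  # samples as observations
  total_var <- sum(sv$d^2)
  k <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      coords[, j] <- -coords[, j]
    }
  }
  dimnames(coords) <- list(colnames(v), paste0("PC", seq_len(k)))
  structure(list(coordinates = coords,
                 explained_variance_ratio = sv$d[seq_len(k)]^2 / total_var),
            class = "sample_projection")
}

#' Hierarchical clustering of samples
#'
#' Pairwise sample distance is `1 - PCC` between `log2(x + 1)` expression
#' columns, merged with average linkage. Samples whose column has zero
#' variance (for which correlation is undefined) are flagged and placed
#' last in the leaf order rather than clustered.
#'
#' @param expr An `expression_matrix` with at least 2 samples.
#' @return A `sample_dendrogram`: list with `hclust` (the merge tree over
#'   clusterable samples), `leaf_order` (all sample ids, flagged ones
#'   last), and `flagged`.
#' @export
cluster_samples <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  if (ncol(v) < 2L) stop("need at least 2 samples to cluster")
  x <- log2(v + 1)
  sds <- apply(x, 2L, stats::sd)
  flagged <- sort(colnames(x)[sds == 0])
  usable <- setdiff(colnames(x), flagged)
  if (length(usable) < 2L) {
    stop("fewer than 2 samples with nonzero variance; cannot cluster")
  }
  d <- stats::as.dist(1 - stats::cor(x[, usable, drop = FALSE]))
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc,
                 leaf_order = c(hc$labels[hc$order], flagged),
                 flagged = flagged),
            class = "sample_dendrogram")
}

#' Serialize a sample dendrogram as Newick text
#'
#' @param dendro A `sample_dendrogram` from [cluster_samples()].
#' @param path Optional output path; omitted, the Newick string is
#'   returned.
#' @return The Newick string (invisibly when `path` is given).
#' @export
dendrogram_newick <- function(dendro, path = NULL) {
  stopifnot(inherits(dendro, "sample_dendrogram"))
  phy <- ape::as.phylo(dendro$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write diagnostics tables as TSV
#'
#' @param projection A `sample_projection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(projection, path) {
  stopifnot(inherits(projection, "sample_projection"))
  tab <- data.frame(sample = rownames(projection$coordinates),
                    projection$coordinates, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_projection
#' @param dd A `degree_distribution`.
#' @export
write_degree_distribution <- function(dd, path) {
  stopifnot(inherits(dd, "degree_distribution"))
  utils::write.table(dd, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
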