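#' All-pairs Pearson correlations, blockwise
#'
#' Computes the full symmetric Pearson correlation matrix between gene
#' expression profiles. Genes with zero variance across samples carry no
#' correlation signal and are excluded with a logged reason. The
#' computation centers and unit-normalizes each profile once and then
#' takes blockwise cross-products, so peak memory is bounded by the block
#' size while results are bitwise identical to the all-at-once product.
#'
#' @param expr An `expression_matrix`; TPM is the intended input (a
#'   warning, not an error, for other normalizations).
#' @param block_size Genes per block; purely a memory knob.
#' @return A `correlation_result`: list with `pcc`, the symmetric
#'   correlation matrix over retained genes (diagonal exactly 1), and
#'   `excluded`, a data frame of `gene_id`, `reason`.
#' @export
pcc_all <- function(expr, block_size = 1000L) {
  stopifnot(inherits(expr, "expression_matrix"), block_size >= 1L)
  v <- expr$values
  if (ncol(v) < 3L) {
    stop("need at least 3 samples to compute correlations, got ", ncol(v))
  }
  if (!identical(expr$normalization, "TPM")) {
    warning("correlations are usually computed on TPM values; input is '",
            expr$normalization, "'")
  }
  ctr <- v - rowMeans(v)
  norms <- sqrt(rowSums(ctr^2))
  keep <- norms > 0
  if (!any(keep)) stop("all genes have zero variance across samples")
  excluded <- data.frame(gene_id = rownames(v)[!keep],
                         reason = rep("zero variance", sum(!keep)),
                         stringsAsFactors = FALSE)
  z <- ctr[keep, , drop = FALSE] / norms[keep]
  m <- nrow(z)
  pcc <- matrix(NA_real_, m, m, dimnames = list(rownames(z), rownames(z)))
  starts <- seq(1L, m, by = block_size)
  for (a in starts) {
    ia <- a:min(a + block_size - 1L, m)
    for (b in starts) {
      ib <- b:min(b + block_size - 1L, m)
      pcc[ia, ib] <- tcrossprod(z[ia, , drop = FALSE],
                                z[ib, , drop = FALSE])
    }
  }
  diag(pcc) <- 1
  structure(list(pcc = pcc, excluded = excluded),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("correlation_result:", nrow(x$pcc), "genes retained,",
      nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Top co-expressed partners per gene
#'
#' For every retained gene, the up-to-`k` strongest co-expressed partners
#' by signed (not absolute) correlation, in descending order; ties are
#' broken by the lexicographically smaller partner id.
#'
#' @param corr A `correlation_result`.
#' @param k Number of partners to keep (default 1000).
#' @return A `neighbor_table`: named list of data frames with columns
#'   `partner`, `pcc`.
#' @export
top_neighbors <- function(corr, k = 1000L) {
  stopifnot(inherits(corr, "correlation_result"), k >= 1L)
  genes <- rownames(corr$pcc)
  out <- lapply(genes, function(g) {
    p <- corr$pcc[g, ]
    p <- p[setdiff(genes, g)]
    ord <- order(-p, names(p))
    top <- utils::head(ord, k)
    data.frame(partner = names(p)[top], pcc = unname(p[top]),
               stringsAsFactors = FALSE)
  })
  names(out) <- genes
  structure(out, class = "neighbor_table")
}

#' Threshold correlations into a co-expression network
#'
#' Keeps exactly the unordered gene pairs whose correlation is strictly
#' greater than the cutoff (0.7 by default, the recommended setting when
#' the network feeds MCL).
#'
#' @param corr A `correlation_result`.
#' @param cutoff Correlation cutoff, strictly exceeded; in `(-1, 1)`.
#' @return A `coexpression_network`: data frame of edges `gene_a`,
#'   `gene_b`, `pcc` with `gene_a < gene_b`, sorted; attributes `cutoff`
#'   and `nodes` (genes incident to at least one edge).
#' @export
build_network <- function(corr, cutoff = 0.7) {
  stopifnot(inherits(corr, "correlation_result"),
            cutoff > -1, cutoff < 1)
  p <- corr$pcc
  idx <- which(upper.tri(p) & p > cutoff, arr.ind = TRUE)
  a <- rownames(p)[idx[, 1L]]
  b <- colnames(p)[idx[, 2L]]
  swap <- a > b
  edges <- data.frame(gene_a = ifelse(swap, b, a),
                      gene_b = ifelse(swap, a, b),
                      pcc = p[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  .coexpression_network(edges, cutoff,
                        sort(unique(c(edges$gene_a, edges$gene_b))))
}

.coexpression_network <- function(edges, cutoff, nodes) {
  attr(edges, "cutoff") <- cutoff
  attr(edges, "nodes") <- nodes
  class(edges) <- c("coexpression_network", "data.frame")
  edges
}

#' Induced co-expression neighborhood of one gene
#'
#' Nodes are the query gene plus every partner correlated with it above
#' the cutoff; edges are all pairs among those nodes above the cutoff
#' (the induced subgraph). Raising the cutoff (e.g. to 0.925) shrinks the
#' neighborhood for visualization.
#'
#' @param corr A `correlation_result`.
#' @param gene Query gene id.
#' @param cutoff Correlation cutoff, strictly exceeded.
#' @return A `coexpression_network` whose `nodes` attribute always
#'   contains the query gene (possibly alone).
#' @export
extract_neighborhood <- function(corr, gene, cutoff) {
  stopifnot(inherits(corr, "correlation_result"))
  if (!gene %in% rownames(corr$pcc)) {
    stop("gene '", gene, "' not present in the correlation result")
  }
  p <- corr$pcc
  partners <- setdiff(colnames(p)[p[gene, ] > cutoff], gene)
  nodes <- sort(unique(c(gene, partners)))
  sub <- p[nodes, nodes, drop = FALSE]
  idx <- which(upper.tri(sub) & sub > cutoff, arr.ind = TRUE)
  edges <- data.frame(gene_a = nodes[idx[, 1L]], gene_b = nodes[idx[, 2L]],
                      pcc = sub[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  .coexpression_network(edges, cutoff, nodes)
}

#' Write a network edge list / neighbor table as TSV
#'
#' The edge list (`gene_a<TAB>gene_b<TAB>pcc`, with header) loads directly
#' into Cytoscape. The neighbor table has one row per gene:
#' `gene<TAB>partner1(pcc1);partner2(pcc2);...`.
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("gene_a\tgene_b\tpcc", con)
  if (nrow(network)) {
    writeLines(paste(network$gene_a, network$gene_b,
                     sprintf("%.6g", network$pcc), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @param neighbors A `neighbor_table`.
#' @export
write_neighbor_table <- function(neighbors, path) {
  stopifnot(inherits(neighbors, "neighbor_table"))
  lines <- vapply(names(neighbors), function(g) {
    nb <- neighbors[[g]]
    paste0(g, "\t", paste0(nb$partner, "(", sprintf("%.6g", nb$pcc), ")",
                           collapse = ";"))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list TSV back into a network
#' @param path Edge list written by [write_edge_list()].
#' @param cutoff Cutoff to record on the result.
#' @return A `coexpression_network`.
#' @export
read_edge_list <- function(path, cutoff = NA_real_) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "numeric"))
  .coexpression_network(tab, cutoff,
                        sort(unique(c(tab$gene_a, tab$gene_b))))
}
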