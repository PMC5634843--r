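# Shared fixtures, all built in code at test time.

write_gff3_fixture <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), path)
  path
}

# Two well-separated genes on one chromosome; geneB three times longer.
two_gene_gff3 <- function() {
  write_gff3_fixture(c(
    "chr1\tx\tgene\t1\t2000\t.\t+\t.\tID=geneA",
    "chr1\tx\tmRNA\t1\t2000\t.\t+\t.\tID=geneA.1;Parent=geneA",
    "chr1\tx\tCDS\t1\t100\t.\t+\t0\tID=cA1;Parent=geneA.1",
    "chr1\tx\tCDS\t201\t300\t.\t+\t0\tID=cA2;Parent=geneA.1",
    "chr1\tx\tgene\t5000\t8000\t.\t-\t.\tID=geneB",
    "chr1\tx\tmRNA\t5000\t8000\t.\t-\t.\tID=geneB.1;Parent=geneB",
    "chr1\tx\tCDS\t5000\t5599\t.\t-\t0\tID=cB1;Parent=geneB.1"))
}

two_gene_annotation <- function() {
  select_representative(parse_gff3(two_gene_gff3()))
}

# Wrap a symmetric correlation matrix as a correlation_result.
as_correlation_result <- function(p) {
  stopifnot(isSymmetric(unname(p)))
  diag(p) <- 1
  structure(list(pcc = p,
                 excluded = data.frame(gene_id = character(),
                                       reason = character())),
            class = "correlation_result")
}

# The four-gene toy correlation structure used across network tests.
toy_correlation <- function() {
  g <- c("g1", "g2", "g3", "g4")
  p <- diag(4)
  dimnames(p) <- list(g, g)
  set_pair <- function(a, b, v) {
    p[a, b] <<- v
    p[b, a] <<- v
  }
  set_pair("g1", "g2", 1.0)
  set_pair("g1", "g3", -1.0)
  set_pair("g1", "g4", 0.8)
  set_pair("g2", "g4", 0.8)
  set_pair("g3", "g4", -0.8)
  set_pair("g2", "g3", -1.0)
  as_correlation_result(p)
}

# A network straight from an edge data frame (gene_a < gene_b assumed).
as_network <- function(edges, cutoff = 0.7, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  attr(edges, "cutoff") <- cutoff
  attr(edges, "nodes") <- nodes
  class(edges) <- c("coexpression_network", "data.frame")
  edges
}

triangle_edges <- function(nodes, weight = 1) {
  pairs <- t(utils::combn(sort(nodes), 2L))
  data.frame(gene_a = pairs[, 1L], gene_b = pairs[, 2L], pcc = weight,
             stringsAsFactors = FALSE)
}

# Two triangles joined by one weak bridge edge.
bridge_network <- function(bridge_weight = 0.1) {
  e <- rbind(triangle_edges(c("a1", "a2", "a3")),
             triangle_edges(c("b1", "b2", "b3")),
             data.frame(gene_a = "a1", gene_b = "b1", pcc = bridge_weight))
  as_network(e)
}

expr_from_matrix <- function(values, normalization = "TPM") {
  structure(list(values = values, normalization = normalization),
            class = "expression_matrix")
}

count_matrix_from <- function(values) {
  structure(
    list(counts = values,
         special = matrix(0L, 5L, ncol(values),
                          dimnames = list(
                            c("no_feature", "ambiguous",
                              "too_low_quality", "not_aligned",
                              "alignment_not_unique"),
                            colnames(values)))),
    class = "count_matrix")
}
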