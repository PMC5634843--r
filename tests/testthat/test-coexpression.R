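test_that("pcc_all recovers analytic correlations", {
  v <- rbind(g1 = c(1, 2, 3, 4),
             g2 = c(2, 4, 6, 8),
             g3 = c(4, 3, 2, 1),
             g4 = c(1, 3, 2, 4))
  colnames(v) <- paste0("s", 1:4)
  corr <- pcc_all(expr_from_matrix(v))
  expect_equal(corr$pcc["g1", "g2"], 1.0)
  expect_equal(corr$pcc["g1", "g3"], -1.0)
  expect_equal(corr$pcc["g1", "g4"], 0.8)
  expect_equal(diag(corr$pcc), stats::setNames(rep(1, 4), rownames(v)))
  expect_true(isSymmetric(corr$pcc))
})

test_that("blockwise computation equals the naive per-pair oracle", {
  set.seed(41)
  for (rep in 1:3) {
    v <- matrix(rnorm(50 * 20), 50L, 20L,
                dimnames = list(sprintf("g%02d", 1:50),
                                sprintf("s%02d", 1:20)))
    expr <- expr_from_matrix(v)
    oracle <- naive_pcc(v)
    for (bs in c(1L, 7L, 50L)) {
      got <- pcc_all(expr, block_size = bs)$pcc
      expect_lt(max(abs(got - oracle)), 1e-10)
    }
  }
})

test_that("zero-variance genes are excluded with a reason", {
  v <- rbind(g1 = c(1, 2, 3), flat = c(5, 5, 5), g3 = c(3, 1, 2))
  colnames(v) <- paste0("s", 1:3)
  corr <- pcc_all(expr_from_matrix(v))
  expect_false("flat" %in% rownames(corr$pcc))
  expect_equal(corr$excluded$gene_id, "flat")
  expect_match(corr$excluded$reason, "zero variance")

  expect_error(pcc_all(expr_from_matrix(v[, 1:2])), "at least 3 samples")
  allflat <- matrix(1, 3L, 4L, dimnames = list(paste0("g", 1:3),
                                               paste0("s", 1:4)))
  expect_error(pcc_all(expr_from_matrix(allflat)), "zero variance")
  expect_warning(pcc_all(expr_from_matrix(v, "RPKM"))["pcc"], "TPM")
})

test_that("PCC is invariant under positive affine transforms", {
  set.seed(43)
  v <- matrix(rnorm(40), 8L, 5L,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  base <- pcc_all(expr_from_matrix(v))$pcc
  v2 <- v
  v2[1L, ] <- 3 * v[1L, ] + 10
  expect_equal(pcc_all(expr_from_matrix(v2))$pcc, base,
               tolerance = 1e-12)
  v3 <- v
  v3[1L, ] <- -2 * v[1L, ] + 1
  flipped <- pcc_all(expr_from_matrix(v3))$pcc
  expect_equal(flipped["g1", "g2"], -base["g1", "g2"],
               tolerance = 1e-12)
})

test_that("top_neighbors truncates, ranks by signed pcc, breaks ties", {
  corr <- toy_correlation()
  nb <- top_neighbors(corr, k = 1000L)
  expect_equal(lengths(lapply(nb, `[[`, "partner")),
               stats::setNames(rep(3L, 4L), c("g1", "g2", "g3", "g4")))
  one <- top_neighbors(corr, k = 1L)
  expect_equal(nrow(one$g1), 1L)
  expect_equal(one$g1$partner, "g2")
  # g4 sees g1 and g2 both at 0.8: lexicographically smaller first
  expect_equal(nb$g4$partner[1:2], c("g1", "g2"))
  # signed ranking: g3 at -1.0 is ranked last for g1, not first
  expect_equal(nb$g1$partner, c("g2", "g4", "g3"))
})

test_that("build_network keeps exactly the pairs above the cutoff", {
  corr <- toy_correlation()
  net <- build_network(corr, 0.7)
  expect_equal(nrow(net), 3L)
  expect_equal(net$gene_a, c("g1", "g1", "g2"))
  expect_equal(net$gene_b, c("g2", "g4", "g4"))
  expect_true(all(net$gene_a < net$gene_b))

  high <- build_network(corr, 0.999)
  expect_equal(nrow(high), 1L)
  expect_equal(c(high$gene_a, high$gene_b), c("g1", "g2"))

  # boundary: pcc exactly equal to cutoff is excluded
  boundary <- build_network(corr, 0.8)
  expect_equal(nrow(boundary), 1L)

  # edge count is non-increasing in the cutoff
  cuts <- seq(-0.9, 0.9, by = 0.2)
  sizes <- vapply(cuts, function(ct) nrow(build_network(corr, ct)),
                  integer(1L))
  expect_true(all(diff(sizes) <= 0L))
})

test_that("extract_neighborhood induces the subgraph around the query", {
  corr <- toy_correlation()
  tight <- extract_neighborhood(corr, "g1", 0.925)
  expect_equal(attr(tight, "nodes"), c("g1", "g2"))
  expect_equal(nrow(tight), 1L)

  lonely <- extract_neighborhood(corr, "g3", 0.999)
  expect_equal(attr(lonely, "nodes"), "g3")
  expect_equal(nrow(lonely), 0L)

  wide <- extract_neighborhood(corr, "g1", 0.7)
  expect_equal(attr(wide, "nodes"), c("g1", "g2", "g4"))
  expect_equal(nrow(wide), 3L)

  expect_error(extract_neighborhood(corr, "nope", 0.7), "not present")
})

test_that("edge lists and neighbor tables serialize and reload", {
  corr <- toy_correlation()
  net <- build_network(corr, 0.7)
  path <- tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_equal(back$gene_a, net$gene_a)
  expect_equal(back$pcc, net$pcc, tolerance = 1e-5)

  nbpath <- tempfile(fileext = ".tsv")
  write_neighbor_table(top_neighbors(corr, 2L), nbpath)
  lines <- readLines(nbpath)
  expect_length(lines, 4L)
  expect_match(lines[1L], "^g1\tg2\\(1\\);g4\\(0\\.8\\)$")
})
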