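test_that("read_htseq_counts transcribes gene rows and special counters", {
  path <- tempfile()
  writeLines(c("g1\t5", "g2\t0", "__no_feature\t3", "__ambiguous\t1",
               "__not_aligned\t2"), path)
  sc <- read_htseq_counts(path, "s1")
  expect_equal(sc$result$counts, c(g1 = 5L, g2 = 0L))
  expect_equal(unname(sc$result$special),
               c(3L, 1L, 0L, 2L, 0L))

  writeLines(character(), path)
  expect_error(read_htseq_counts(path, "s1"), "empty")

  writeLines(c("g1\t5", "g2\t2"), path)
  expect_true(all(read_htseq_counts(path, "s1")$result$special == 0L))

  writeLines(c("g1\t5", "g1\t2"), path)
  expect_error(read_htseq_counts(path, "s1"), "duplicate gene")
  writeLines(c("g1\tfive"), path)
  expect_error(read_htseq_counts(path, "s1"), "non-integer")
})

sample_from <- function(sample_id, counts) {
  structure(list(sample_id = sample_id, result = count_result(counts)),
            class = "sample_counts")
}

test_that("aggregate_counts assembles columns in input order", {
  s1 <- sample_from("sA", c(g2 = 1L, g1 = 5L))
  s2 <- sample_from("sB", c(g1 = 2L, g2 = 7L))
  cm <- aggregate_counts(list(s1, s2))
  expect_equal(dim(cm$counts), c(2L, 2L))
  expect_equal(colnames(cm$counts), c("sA", "sB"))
  expect_equal(rownames(cm$counts), c("g1", "g2"))  # sorted gene ids
  expect_equal(cm$counts["g1", ], c(sA = 5L, sB = 2L))

  single <- aggregate_counts(list(s1))
  expect_equal(dim(single$counts), c(2L, 1L))

  s3 <- sample_from("sC", c(g1 = 1L, g3 = 1L))
  expect_error(aggregate_counts(list(s1, s3)), "g2.*g3")
  expect_error(aggregate_counts(list(s1, sample_from("sA", c(g1 = 1L,
                                                             g2 = 1L)))),
               "duplicate sample_id")
})

test_that("RPKM matches its definition on hand-computed cases", {
  cm <- count_matrix_from(matrix(c(1L, 999999L), 2L, 1L,
                                 dimnames = list(c("g1", "g2"), "s")))
  # columnTotal = 1e6, g1: 1 * 1e9 / (1000 * 1e6) = 1
  rpkm <- compute_rpkm(cm, c(g1 = 1000L, g2 = 1000L))
  expect_equal(rpkm$values["g1", "s"], 1.0)
  expect_equal(rpkm$normalization, "RPKM")

  cm2 <- count_matrix_from(matrix(c(50L, 2e6L - 50L), 2L, 1L,
                                  dimnames = list(c("g1", "g2"), "s")))
  rpkm2 <- compute_rpkm(cm2, c(g1 = 2500L, g2 = 1000L))
  expect_equal(rpkm2$values["g1", "s"], 10.0)

  cm3 <- count_matrix_from(matrix(c(0L, 10L), 2L, 1L,
                                  dimnames = list(c("g1", "g2"), "s")))
  expect_equal(compute_rpkm(cm3, c(g1 = 500L, g2 = 500L))$values["g1", "s"],
               0.0)

  zero <- count_matrix_from(matrix(0L, 2L, 1L,
                                   dimnames = list(c("g1", "g2"), "bad")))
  expect_error(compute_rpkm(zero, c(g1 = 1L, g2 = 1L)), "bad")
})

test_that("TPM matches hand evaluation and a per-gene loop oracle", {
  cm <- count_matrix_from(matrix(c(10L, 90L), 2L, 1L,
                                 dimnames = list(c("g1", "g2"), "s")))
  len <- c(g1 = 1000L, g2 = 2000L)
  tpm <- compute_tpm(cm, len)
  expect_equal(tpm$values[, "s"],
               c(g1 = 0.01 / 0.055 * 1e6, g2 = 0.045 / 0.055 * 1e6))
  expect_equal(unname(tpm$values["g1", "s"]), 181818.18, tolerance = 1e-7)

  # independent per-gene loop oracle on a random matrix
  set.seed(11)
  v <- matrix(rpois(60, 40), 10L, 6L,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  lens <- stats::setNames(sample(500:3000, 10L), rownames(v))
  tpm2 <- compute_tpm(count_matrix_from(v), lens)
  for (s in colnames(v)) {
    rates <- vapply(rownames(v), function(g) v[g, s] / lens[[g]],
                    numeric(1L))
    expect_equal(tpm2$values[, s], rates / sum(rates) * 1e6)
  }
})

test_that("TPM invariants: column sums, RPKM identity, depth invariance", {
  set.seed(21)
  for (rep in 1:5) {
    v <- matrix(rpois(80, 30) + 1L, 16L, 5L,
                dimnames = list(sprintf("g%02d", 1:16), paste0("s", 1:5)))
    lens <- stats::setNames(sample(200:5000, 16L), rownames(v))
    cm <- count_matrix_from(v)
    tpm <- compute_tpm(cm, lens)
    expect_equal(unname(colSums(tpm$values)), rep(1e6, 5L),
                 tolerance = 1e-6)
    # TPM == column-renormalized RPKM
    rpkm <- compute_rpkm(cm, lens)
    renorm <- sweep(rpkm$values, 2L, colSums(rpkm$values), "/") * 1e6
    expect_equal(tpm$values, renorm, tolerance = 1e-10)
    # doubling one column's counts leaves its TPM unchanged
    v2 <- v
    v2[, 2L] <- v2[, 2L] * 2L
    tpm2 <- compute_tpm(count_matrix_from(v2), lens)
    expect_equal(tpm2$values[, 2L], tpm$values[, 2L], tolerance = 1e-12)
    # gene-row permutation invariance / sample-column equivariance
    perm <- sample(nrow(v))
    tpm3 <- compute_tpm(count_matrix_from(v[perm, ]), lens)
    expect_equal(tpm3$values, tpm$values[perm, ])
  }
})

test_that("expression matrices round-trip through TSV", {
  v <- matrix(c(1.5, 0, 12345.678, 3), 2L, 2L,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expr <- expr_from_matrix(v, "TPM")
  path <- tempfile(fileext = ".tsv")
  write_expression_matrix(expr, path)
  back <- read_expression_matrix(path)
  expect_equal(back$normalization, "TPM")
  expect_equal(back$values, v, tolerance = 1e-5)  # 6 significant digits
})

test_that("drop_samples removes exactly the named columns", {
  v <- matrix(1:6, 2L, 3L, dimnames = list(c("g1", "g2"),
                                           c("s1", "s2", "s3")))
  cm <- count_matrix_from(v)
  out <- drop_samples(cm, "s2")
  expect_equal(colnames(out$counts), c("s1", "s3"))
  expect_error(drop_samples(cm, "nope"), "unknown sample")
})
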