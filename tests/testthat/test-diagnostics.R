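test_that("degree distributions count incident edges per node", {
  tri <- as_network(triangle_edges(c("a", "b", "c")))
  expect_equal(degree_distribution(tri),
               structure(data.frame(degree = 2L, frequency = 3L),
                         class = c("degree_distribution", "data.frame")))
  star <- as_network(data.frame(gene_a = "hub",
                                gene_b = c("l1", "l2", "l3", "l4"),
                                pcc = 1))
  dd <- degree_distribution(star)
  expect_equal(dd$degree, c(1L, 4L))
  expect_equal(dd$frequency, c(4L, 1L))
  single <- as_network(data.frame(gene_a = "a", gene_b = "b", pcc = 1))
  expect_equal(degree_distribution(single)$frequency, 2L)
  # frequencies sum to the node count of the edge list
  expect_equal(sum(dd$frequency), 5L)
})

test_that("exact power laws are fit exactly", {
  dd <- dd_from_degrees(rep(c(1, 2, 4, 8), c(64, 16, 4, 1)))
  fit <- fit_power_law(dd)
  expect_equal(fit$slope, -2.0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(fit$n_points, 4L)

  flat <- dd_from_degrees(rep(c(1, 2, 4), each = 5))
  expect_equal(fit_power_law(flat)$slope, 0.0, tolerance = 1e-12)

  expect_error(fit_power_law(dd_from_degrees(c(1, 1, 2))),
               "at least 3 distinct degrees")
})

test_that("sampled power-law degree sequences recover their exponent", {
  # degrees drawn over support 1..15 so every bin stays populated enough
  # for the straight-line diagnostic
  for (seed in 1:3) {
    set.seed(seed)
    probs <- (1:15)^(-2.5)
    deg <- sample(1:15, 2000L, replace = TRUE, prob = probs / sum(probs))
    fit <- fit_power_law(dd_from_degrees(deg))
    expect_lt(abs(fit$slope - (-2.5)), 0.3)
  }
})

test_that("PCA separates duplicated sample groups deterministically", {
  set.seed(61)
  a <- rpois(30, 20)
  b <- rpois(30, 20)
  v <- cbind(a1 = a, a2 = a, b1 = b, b2 = b)
  rownames(v) <- sprintf("g%02d", 1:30)
  proj <- pca_samples(expr_from_matrix(v), n_components = 2L)
  co <- proj$coordinates
  expect_equal(co["a1", ], co["a2", ])
  expect_equal(co["b1", ], co["b2", ])
  expect_true(sign(co["a1", "PC1"]) != sign(co["b1", "PC1"]))
  # rank-1 structure: everything beyond PC1 explains nothing
  expect_lt(proj$explained_variance_ratio[2L], 1e-9)
  # ratios are non-increasing, within [0, 1], and sum to <= 1
  evr <- proj$explained_variance_ratio
  expect_true(all(diff(evr) <= 1e-12))
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-9)
  # identical samples -> no variance -> error
  same <- cbind(s1 = a, s2 = a)
  rownames(same) <- rownames(v)
  expect_error(pca_samples(expr_from_matrix(same)), "zero variance")
})

test_that("PC1 separates two planted activity regimes", {
  spec <- synthetic_spec(n_modules = 1L, genes_per_module = 40L,
                         n_background_genes = 10L, n_samples = 20L,
                         activity_sd = 1.5, dispersion = 10, seed = 62)
  sim <- generate_modular_counts(spec)
  tpm <- compute_tpm(sim$counts, sim$lengths)
  proj <- pca_samples(tpm)
  # with one dominant module, PC1 tracks its activity; samples split by
  # the module's mean TPM must have disjoint PC1 ranges
  mod_genes <- sim$truth$gene_id[sim$truth$module != "background"]
  activity <- colMeans(tpm$values[mod_genes, ])
  hi <- names(sort(activity, decreasing = TRUE))[1:5]
  lo <- names(sort(activity))[1:5]
  r_hi <- range(proj$coordinates[hi, "PC1"])
  r_lo <- range(proj$coordinates[lo, "PC1"])
  expect_true(r_hi[1L] > r_lo[2L] || r_lo[1L] > r_hi[2L])
})

test_that("sample clustering merges duplicates first, outliers last", {
  set.seed(63)
  base <- rpois(40, 30)
  v <- cbind(a1 = base + rpois(40, 2), a2 = base + rpois(40, 2),
             b1 = base * 3 + rpois(40, 2), b2 = base * 3 + rpois(40, 2),
             out = rpois(40, 30))
  rownames(v) <- sprintf("g%02d", 1:40)
  dendro <- cluster_samples(expr_from_matrix(v))
  hc <- dendro$hclust
  # brute-force distance oracle: the outlier joins last
  x <- log2(v + 1)
  d <- 1 - cor(x)
  expect_true(all(d["out", setdiff(colnames(v), "out")] >
                    max(d["a1", "a2"], d["b1", "b2"])))
  last_merge <- hc$merge[nrow(hc$merge), ]
  singles <- -last_merge[last_merge < 0]
  expect_true(which(colnames(v) == "out") %in% singles)

  # duplicated columns merge at distance ~0 first
  dup <- cbind(s1 = base, s2 = base, s3 = base * 2, s4 = base * 2)
  rownames(dup) <- rownames(v)
  hc2 <- cluster_samples(expr_from_matrix(dup))$hclust
  expect_lt(hc2$height[1L], 1e-10)

  # two samples: a single merge
  two <- cluster_samples(expr_from_matrix(v[, 1:2]))
  expect_equal(nrow(two$hclust$merge), 1L)
})

test_that("zero-variance samples are flagged and placed last", {
  set.seed(64)
  v <- cbind(s1 = rpois(20, 10), s2 = rpois(20, 15), s3 = rpois(20, 5),
             flat = rep(7, 20))
  rownames(v) <- sprintf("g%02d", 1:20)
  dendro <- cluster_samples(expr_from_matrix(v))
  expect_equal(dendro$flagged, "flat")
  expect_equal(utils::tail(dendro$leaf_order, 1L), "flat")
  nwk <- dendrogram_newick(dendro)
  expect_match(nwk, "^\\(.*\\);$")
})
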