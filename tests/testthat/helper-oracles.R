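# Independent oracles, deliberately naive and code-path independent of
# the package implementation.

# Per-pair two-pass Pearson correlation.
naive_pcc <- function(m) {
  g <- nrow(m)
  out <- diag(g)
  dimnames(out) <- list(rownames(m), rownames(m))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (i == j) next
      x <- m[i, ] - mean(m[i, ])
      y <- m[j, ] - mean(m[j, ])
      out[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    }
  }
  out
}

# Per-base interval union size.
brute_union_length <- function(starts, ends) {
  length(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
}

# Minimal dense MCL: no pruning, naive column loops, clusters read as
# connected components of the limit matrix's support.
reference_mcl <- function(adj, inflation = 2, self_loop = 1,
                          iterations = 200, tol = 1e-9) {
  diag(adj) <- diag(adj) + self_loop
  m <- apply(adj, 2L, function(col) col / sum(col))
  for (it in seq_len(iterations)) {
    e <- m %*% m
    p <- e^inflation
    p <- apply(p, 2L, function(col) col / sum(col))
    if (max(abs(p - m)) < tol) {
      m <- p
      break
    }
    m <- p
  }
  support <- (m > 1e-6) | (t(m) > 1e-6)
  n <- nrow(m)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      if (comp[i] > 0L) next
      comp[i] <- cid
      queue <- c(queue, which(support[i, ] & comp == 0L))
    }
  }
  lapply(seq_len(cid), function(k) sort(rownames(adj)[comp == k]))
}

# Cluster labels for a gene universe: genes absent from every cluster get
# their own fresh label (singletons).
cluster_labels <- function(clusters, genes) {
  lab <- rep(NA_integer_, length(genes))
  names(lab) <- genes
  for (i in seq_along(clusters)) {
    hit <- intersect(clusters[[i]], genes)
    lab[hit] <- i
  }
  lab[is.na(lab)] <- length(clusters) + seq_len(sum(is.na(lab)))
  lab
}

# Degree distribution from a sampled degree sequence.
dd_from_degrees <- function(deg) {
  tab <- table(deg)
  out <- data.frame(degree = as.integer(names(tab)),
                    frequency = as.integer(tab))
  class(out) <- c("degree_distribution", "data.frame")
  out
}
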