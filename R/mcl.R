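#' MCL parameters
#'
#' Parameters of the Markov Cluster algorithm: inflation (the entrywise
#' power; larger values give more, smaller clusters), the expansion power
#' (fixed at 2, i.e. one matrix squaring per iteration), the pruning
#' threshold below which flow entries are zeroed, the convergence
#' tolerance on the maximum entry change, an iteration cap, and the
#' self-loop weight added to every node. The self-loop weight of 1 equals
#' the maximum possible correlation weight and guarantees aperiodicity.
#'
#' @param inflation Inflation power `r > 1` (default 2).
#' @param pruning_threshold Entries below this are zeroed each iteration.
#' @param convergence_tol Stop when the largest entry change falls below
#'   this.
#' @param max_iterations Iteration cap.
#' @param self_loop_weight Weight of the self-loop added to each node.
#' @return An `mcl_parameters` object.
#' @export
mcl_parameters <- function(inflation = 2, pruning_threshold = 1e-5,
                           convergence_tol = 1e-6, max_iterations = 100L,
                           self_loop_weight = 1) {
  stopifnot(inflation > 1, pruning_threshold > 0, convergence_tol > 0,
            max_iterations >= 1L, self_loop_weight >= 0)
  structure(list(inflation = inflation, expansion = 2L,
                 pruning_threshold = pruning_threshold,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 self_loop_weight = self_loop_weight),
            class = "mcl_parameters")
}

#' Inflation step of MCL
#'
#' Raises every entry of a column-stochastic matrix to the power `r` and
#' renormalizes each column to sum to one. Inflation sharpens the flow
#' distribution within columns, favouring strong transitions.
#'
#' @param m Column-stochastic matrix (columns sum to 1).
#' @param r Inflation power.
#' @return A column-stochastic matrix of the same shape.
#' @export
inflate <- function(m, r) {
  p <- m^r
  cs <- colSums(p)
  if (any(cs == 0)) {
    stop("column(s) ", paste(which(cs == 0), collapse = ", "),
         " sum to zero after inflation; cannot renormalize")
  }
  sweep(p, 2L, cs, "/")
}

#' Markov clustering of a co-expression network
#'
#' Builds the weighted adjacency matrix from the edge list, adds
#' self-loops, column-normalizes, and iterates expansion (matrix
#' squaring), inflation, and pruning until the flow matrix stops changing
#' or the iteration cap is reached. Clusters are read off the limit
#' matrix's attractor structure: rows with positive diagonal are
#' attractors, attractors connected through positive flow form one
#' attractor system, and each node joins the system holding the largest
#' share of its column's flow (ties go to the smaller cluster index).
#' The result is always a partition of the network's node set; genes that
#' end up unattached are emitted as singleton clusters.
#'
#' @param network A non-empty `coexpression_network`.
#' @param params An [mcl_parameters()] object.
#' @return A `cluster_set`: list with `clusters` (list of character
#'   vectors, ordered by decreasing size then first member), `converged`
#'   (logical) and `iterations`.
#' @export
mcl_cluster <- function(network, params = mcl_parameters()) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(params, "mcl_parameters"))
  nodes <- attr(network, "nodes")
  if (is.null(nodes) || length(nodes) == 0L) {
    nodes <- sort(unique(c(network$gene_a, network$gene_b)))
  }
  n <- length(nodes)
  if (n == 0L) stop("network has no nodes")
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network)) {
    ia <- match(network$gene_a, nodes)
    ib <- match(network$gene_b, nodes)
    w <- abs(network$pcc)
    adj[cbind(ia, ib)] <- w
    adj[cbind(ib, ia)] <- w
  }
  diag(adj) <- diag(adj) + params$self_loop_weight
  m <- sweep(adj, 2L, colSums(adj), "/")

  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    nxt <- inflate(m %*% m, params$inflation)
    nxt[nxt < params$pruning_threshold] <- 0
    cs <- colSums(nxt)
    dead <- cs == 0
    if (any(dead)) {
      # pruning wiped a column: pin the node on itself
      nxt[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    nxt <- sweep(nxt, 2L, cs, "/")
    delta <- max(abs(nxt - m))
    m <- nxt
    if (delta < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }

  clusters <- .read_clusters(m, nodes)
  ord <- order(-lengths(clusters),
               vapply(clusters, `[`, character(1L), 1L))
  structure(list(clusters = clusters[ord], converged = converged,
                 iterations = iter),
            class = "cluster_set")
}

# Interpret the (near-)limit flow matrix as a partition.
.read_clusters <- function(m, nodes) {
  n <- length(nodes)
  attractors <- which(diag(m) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  # attractor systems: connected components of positive flow among
  # attractor rows
  sys_id <- integer(n)
  next_id <- 0L
  for (a in attractors) {
    if (sys_id[a] > 0L) next
    next_id <- next_id + 1L
    queue <- a
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      if (sys_id[i] > 0L) next
      sys_id[i] <- next_id
      linked <- attractors[m[i, attractors] > 0 | m[attractors, i] > 0]
      queue <- c(queue, linked[sys_id[linked] == 0L])
    }
  }
  systems <- lapply(seq_len(next_id), function(s) which(sys_id == s))
  # assign every node to the system holding most of its column flow;
  # ties -> smallest system index
  assignment <- integer(n)
  for (c in seq_len(n)) {
    support <- vapply(systems, function(s) sum(m[s, c]), numeric(1L))
    if (all(support == 0)) {
      assignment[c] <- 0L  # unattached; becomes a singleton below
    } else {
      assignment[c] <- which.max(support)
    }
  }
  clusters <- lapply(seq_len(next_id), function(s)
    sort(nodes[assignment == s]))
  clusters <- clusters[lengths(clusters) > 0L]
  loose <- which(assignment == 0L)
  clusters <- c(clusters, lapply(loose, function(i) nodes[i]))
  clusters
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "clusters, sizes ",
      paste(utils::head(lengths(x$clusters), 10L), collapse = " "),
      if (length(x$clusters) > 10L) "..." else "", "\n")
  if (!x$converged) cat("  (not converged)\n")
  invisible(x)
}

#' Write clusters in MCL's line-oriented format
#'
#' One line per cluster, tab-separated gene ids.
#'
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @param drop_singletons Drop size-1 clusters on export.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path, drop_singletons = FALSE) {
  stopifnot(inherits(clusters, "cluster_set"))
  cl <- clusters$clusters
  if (drop_singletons) cl <- cl[lengths(cl) > 1L]
  writeLines(vapply(cl, paste, character(1L), collapse = "\t"), path)
  invisible(path)
}
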