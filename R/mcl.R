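#' Markov clustering parameters
#'
#' @param expansion integer >= 2, power to which the column-stochastic flow
#'   matrix is raised each iteration (default 2). Expansion lets flow reach
#'   further along paths.
#' @param inflation real > 1, entrywise power applied after expansion
#'   (default 2.0). Inflation strengthens strong flows and starves weak
#'   ones; larger values give finer clusterings.
#' @param self_loop non-negative weight added on the diagonal before
#'   normalization (default 1.0); guarantees aperiodicity.
#' @param prune_below entries below this are zeroed after each inflation for
#'   numerical hygiene and speed (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the maximum entrywise change
#'   (default 1e-8).
#' @return a list of class `mcl_params`.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2.0, self_loop = 1.0,
                       prune_below = 1e-6, max_iter = 100L, tol = 1e-8) {
  expansion <- as.integer(expansion)
  stopifnot(expansion >= 2, inflation > 1, self_loop >= 0,
            prune_below >= 0, max_iter >= 1, tol > 0)
  structure(list(expansion = expansion, inflation = inflation,
                 self_loop = self_loop, prune_below = prune_below,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_params")
}

#' Inflate a probability vector
#'
#' Raises each entry of a non-negative vector to the power `r` and
#' renormalizes to sum 1. This is MCL's flow-sharpening primitive: mass
#' moves toward the largest entries.
#'
#' @param column non-negative numeric vector with positive sum.
#' @param r inflation exponent, > 1 in MCL proper (any positive value is
#'   accepted here).
#' @return the inflated vector, summing to 1.
#' @export
inflate <- function(column, r) {
  if (any(column < 0)) stop("vector must be non-negative")
  s <- sum(column)
  if (s <= 0) stop("vector must have positive sum")
  x <- column^r
  x / sum(x)
}

# Column-normalize a non-negative matrix; all-zero columns get a unit
# self-entry so the result stays column-stochastic.
normalize_columns <- function(m) {
  cs <- colSums(m)
  dead <- cs == 0
  if (any(dead)) {
    m[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(m, 2, cs, "/")
}

#' Markov clustering with attractor extraction
#'
#' From-scratch MCL on a non-negative symmetric weight matrix. The
#' algorithm simulates flow on the graph: starting from the column-
#' normalized weight matrix (with self-loops added), it alternates
#' expansion (matrix power, flow spreads along paths) and inflation
#' (entrywise power + renormalization, flow sharpens) until the matrix
#' stops changing. At convergence flow concentrates in a few rows — the
#' *attractors*; every node is assigned to the attractor that receives most
#' of its flow, and attractors that exchange flow form one cluster. The
#' attractor with the largest converged diagonal entry in each cluster is
#' reported as the cluster's *leader*.
#'
#' @param weights non-negative symmetric numeric matrix with zero diagonal
#'   (self-loops are added internally per `params$self_loop`). Dimnames, if
#'   present, label the nodes.
#' @param params an [mcl_params] object.
#' @return an `mcl_result`: list with `clusters` (list of integer node-index
#'   vectors partitioning the nodes), `attractors` (list, per cluster),
#'   `leaders` (integer, per cluster), `membership` (integer vector, cluster
#'   id per node), `converged_matrix`, `iterations`, `converged` (logical),
#'   `node_names`.
#' @export
mcl_cluster <- function(weights, params = mcl_params()) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("weight matrix must be square")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("weight matrix must be symmetric")
  if (any(weights < 0)) stop("weights must be non-negative")
  node_names <- rownames(weights)
  if (is.null(node_names)) node_names <- as.character(seq_len(n))

  M <- weights
  diag(M) <- params$self_loop
  M <- normalize_columns(M)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    E <- E^params$inflation
    E[E < params$prune_below] <- 0
    E <- normalize_columns(E)
    delta <- max(abs(E - M))
    M <- E
    if (delta < params$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", params$max_iter, " iterations")

  attractor_idx <- which(diag(M) > params$tol)
  if (!length(attractor_idx)) attractor_idx <- which.max(diag(M))
  # attractors exchanging flow belong to one attractor system (= one cluster)
  sys_adj <- (M[attractor_idx, attractor_idx, drop = FALSE] > params$tol) |
    t(M[attractor_idx, attractor_idx, drop = FALSE] > params$tol)
  sys_id <- components_from_adjacency(sys_adj)

  membership <- integer(n)
  flows <- M[attractor_idx, , drop = FALSE]
  for (j in seq_len(n)) {
    f <- flows[, j]
    if (max(f) <= 0) {
      # stranded node (pruned flow): keep it alone with itself as attractor
      attractor_idx <- c(attractor_idx, j)
      sys_id <- c(sys_id, max(sys_id) + 1L)
      flows <- M[attractor_idx, , drop = FALSE]
      membership[j] <- sys_id[length(sys_id)]
    } else {
      membership[j] <- sys_id[which.max(f)]  # ties: lowest attractor index
    }
  }
  # relabel clusters deterministically by lowest member index
  first <- vapply(sort(unique(membership)),
                  function(cl) min(which(membership == cl)), integer(1))
  ord <- sort(unique(membership))[order(first)]
  membership <- match(membership, ord)
  sys_id <- match(sys_id, ord)

  k <- max(membership)
  clusters <- lapply(seq_len(k), function(cl) which(membership == cl))
  attractors <- lapply(seq_len(k), function(cl)
    sort(attractor_idx[sys_id == cl]))
  d <- diag(M)
  leaders <- vapply(attractors, function(a) {
    a[which.max(d[a])]  # which.max ties -> first, i.e. lowest index
  }, integer(1))

  structure(
    list(clusters = clusters, attractors = attractors, leaders = leaders,
         membership = membership, converged_matrix = M, iterations = iter,
         converged = converged, node_names = node_names),
    class = "mcl_result")
}

# connected components of a logical adjacency matrix (self-contained BFS;
# kept independent of igraph so the clustering core has no dependencies)
components_from_adjacency <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.mcl_result <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("mcl_result: %d clusters over %d nodes (%d iterations%s)\n",
              length(x$clusters), length(x$membership), x$iterations,
              if (x$converged) "" else ", NOT converged"))
  cat("cluster sizes:", paste(sort(sizes, decreasing = TRUE), collapse = ", "),
      "\n")
  invisible(x)
}
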