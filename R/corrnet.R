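#' Pearson correlations with BH-FDR significance masking
#'
#' Computes all pairwise Pearson correlations between OTUs across samples,
#' their two-sided p-values from the t-distribution with n - 2 degrees of
#' freedom, and Benjamini-Hochberg adjusted values over the set of distinct
#' OTU pairs (the upper triangle). Correlations whose adjusted value exceeds
#' `mask_alpha` are set to zero in the masked matrix; the mask is what both
#' the network construction and the Markov clustering consume, so spurious
#' correlations neither draw edges nor steer the clustering. The default
#' `mask_alpha = 0.25` is deliberately permissive: correlations that miss a
#' 0.05 alpha can still carry real ecological signal.
#'
#' OTUs with zero variance have no defined Pearson correlation; their
#' entries are reported as r = 0, p = 1 with a warning rather than aborting.
#'
#' @param x a `normalized_matrix` (from [normalize_and_log()]) or a plain
#'   numeric samples x OTUs matrix; at least 3 samples and 2 OTUs.
#' @param mask_alpha FDR threshold above which correlations are zeroed
#'   (default 0.25).
#' @return a `correlation_result`: list with symmetric matrices `r`, `p`,
#'   `q`, the masked matrix `r_masked`, `mask_alpha`, and `n_samples`.
#' @export
correlation_with_significance <- function(x, mask_alpha = 0.25) {
  vals <- if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
  n <- nrow(vals); m <- ncol(vals)
  if (n < 3) stop("need at least 3 samples")
  if (m < 2) stop("need at least 2 OTUs")
  sds <- apply(vals, 2, stats::sd)
  const <- sds == 0
  if (any(const))
    warning("zero-variance OTU(s), correlations set to 0: ",
            paste(colnames(vals)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(vals))
  r[const, ] <- 0; r[, const] <- 0
  diag(r) <- 1
  # two-sided p from t = r * sqrt((n-2)/(1-r^2)); p = 0 at |r| = 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  p[const, ] <- 1; p[, const] <- 1
  diag(p) <- 0
  ut <- upper.tri(r)
  q <- matrix(0, m, m, dimnames = dimnames(r))
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q <- q + t(q)
  diag(q) <- 0
  r_masked <- r
  r_masked[q > mask_alpha] <- 0
  structure(
    list(r = r, p = p, q = q, r_masked = r_masked,
         mask_alpha = mask_alpha, n_samples = n),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  kept <- sum(x$r_masked[upper.tri(x$r_masked)] != 0)
  tot <- sum(upper.tri(x$r))
  cat(sprintf(
    "correlation_result: %d OTUs, %d samples; %d/%d pairs pass FDR <= %.2f\n",
    ncol(x$r), x$n_samples, kept, tot, x$mask_alpha))
  invisible(x)
}

#' Build the co-occurrence network from masked correlations
#'
#' One undirected edge per nonzero masked correlation. Nodes carry the mean
#' log10 abundance (drawn as node size) and a differential-abundance heat
#' scalar (drawn as node colour); edges carry the correlation magnitude
#' (edge thickness) and sign (green positive / red negative in renderings).
#'
#' @param corr a `correlation_result`.
#' @param mean_abundance numeric vector, per-OTU mean log10 relative
#'   abundance; defaults to 0 for all nodes.
#' @param heat numeric vector in `[0, 1]`, per-OTU heat scalar; defaults to
#'   0 (coolest).
#' @return a `cooccurrence_network`: list with `nodes` (data frame: otu_id,
#'   mean_abundance, heat), `edges` (data frame: from, to, weight, sign,
#'   q), and the masked correlation matrix `r_masked`.
#' @export
build_network <- function(corr, mean_abundance = NULL, heat = NULL) {
  stopifnot(inherits(corr, "correlation_result"))
  ids <- colnames(corr$r)
  m <- length(ids)
  if (is.null(mean_abundance)) mean_abundance <- rep(0, m)
  if (is.null(heat)) heat <- rep(0, m)
  if (length(mean_abundance) != m || length(heat) != m)
    stop("node annotation length (", length(mean_abundance), ", ",
         length(heat), ") does not match correlation dimension (", m, ")")
  idx <- which(upper.tri(corr$r_masked) & corr$r_masked != 0, arr.ind = TRUE)
  w <- corr$r_masked[idx]
  edges <- data.frame(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    weight = abs(w),
    sign = ifelse(w > 0, "positive", "negative"),
    q = corr$q[idx],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = data.frame(otu_id = ids,
                            mean_abundance = unname(mean_abundance),
                            heat = unname(heat),
                            stringsAsFactors = FALSE),
         edges = edges,
         r_masked = corr$r_masked),
    class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%d negative)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Export a network as GraphML plus TSV node and edge tables
#'
#' @param net a `cooccurrence_network`.
#' @param prefix output path prefix; writes `<prefix>.graphml`,
#'   `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return character vector of the three paths, invisibly.
#' @export
export_network <- function(net, prefix) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "weight", "sign", "q")],
    directed = FALSE, vertices = net$nodes)
  paths <- paste0(prefix, c(".graphml", "_edges.tsv", "_nodes.tsv"))
  igraph::write_graph(g, paths[1], format = "graphml")
  utils::write.table(net$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
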