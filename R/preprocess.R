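#' Filter OTUs by total read count and prevalence
#'
#' Applies the two abundance filters used before network construction,
#' evaluated on the samples of one study group: an OTU is discarded when its
#' total read count across the group is below `min_reads`, or when it is
#' present (count > 0) in fewer than `min_prevalence` of the group's samples.
#' Both inequalities are strict, so an OTU with exactly `min_reads` total
#' reads and exactly `min_prevalence` prevalence is retained.
#'
#' @param m an [abundance_matrix], already restricted to a single group.
#' @param min_reads minimum total read count (default 100).
#' @param min_prevalence minimum fraction of samples with a nonzero count
#'   (default 0.20).
#' @return the filtered [abundance_matrix]; attribute `"discarded"` holds a
#'   data frame (otu_id, total_reads, prevalence, reason) describing dropped
#'   OTUs.
#' @export
filter_otus <- function(m, min_reads = 100, min_prevalence = 0.20) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (nrow(m$counts) == 0 || ncol(m$counts) == 0)
    stop("empty abundance matrix")
  totals <- colSums(m$counts)
  prev <- colMeans(m$counts > 0)
  low_reads <- totals < min_reads
  low_prev <- prev < min_prevalence
  drop <- low_reads | low_prev
  reason <- ifelse(low_reads & low_prev, "low_reads;low_prevalence",
                   ifelse(low_reads, "low_reads", "low_prevalence"))
  log <- data.frame(otu_id = m$otu_ids[drop],
                    total_reads = unname(totals[drop]),
                    prevalence = unname(prev[drop]),
                    reason = reason[drop],
                    stringsAsFactors = FALSE)
  out <- abundance_matrix(m$counts[, !drop, drop = FALSE], m$groups)
  attr(out, "discarded") <- log
  out
}

#' Convert counts to log10 relative abundances
#'
#' Each sample's counts are divided by the sample total (relative
#' abundance), zeros are replaced by a pseudocount, and values are log10
#' transformed. The default pseudocount is half the smallest nonzero
#' relative abundance in the matrix, which preserves the ordering of values
#' while keeping the transform finite.
#'
#' @param m an [abundance_matrix]; every sample must have total count > 0.
#' @param pseudocount positive value substituted for zero relative
#'   abundances before the log, or `"auto"` (the default policy above).
#' @return a `normalized_matrix`: list with `values` (samples x OTUs matrix
#'   of log10 relative abundances), `sample_ids`, `otu_ids`, `groups`,
#'   `pseudocount`.
#' @export
normalize_and_log <- function(m, pseudocount = "auto") {
  stopifnot(inherits(m, "abundance_matrix"))
  totals <- rowSums(m$counts)
  if (any(totals == 0))
    stop("all-zero sample(s): ",
         paste(m$sample_ids[totals == 0], collapse = ", "))
  rel <- m$counts / totals
  if (identical(pseudocount, "auto")) {
    nz <- rel[rel > 0]
    if (!length(nz)) stop("matrix has no nonzero counts")
    pseudocount <- min(nz) / 2
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be positive")
  rel[rel == 0] <- pseudocount
  structure(
    list(values = log10(rel),
         sample_ids = m$sample_ids,
         otu_ids = m$otu_ids,
         groups = m$groups,
         pseudocount = pseudocount),
    class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d samples x %d OTUs (log10, pseudocount %.3g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  invisible(x)
}

#' Per-OTU differential abundance between two groups
#'
#' Runs a two-sided Welch (unequal-variance) t-test per OTU on log10
#' relative abundances and converts the p-value to a "heat" colour scalar,
#' `1 - p`, so 1 means most differentiable (hottest) and 0 least.
#'
#' @param a,b `normalized_matrix` objects for the two groups; same OTU set,
#'   each with at least two samples.
#' @return data frame with columns `otu_id`, `t`, `p`, `heat`.
#' @export
differential_abundance <- function(a, b) {
  stopifnot(inherits(a, "normalized_matrix"), inherits(b, "normalized_matrix"))
  if (!identical(a$otu_ids, b$otu_ids))
    stop("OTU sets differ between the two groups")
  if (nrow(a$values) < 2 || nrow(b$values) < 2)
    stop("each group needs at least 2 samples")
  res <- vapply(seq_along(a$otu_ids), function(j) {
    x <- a$values[, j]; y <- b$values[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # Welch statistic undefined at zero pooled variance; identical values
      # mean no evidence of a difference, differing constants mean maximal.
      if (x[1] == y[1]) return(c(0, 1))
      return(c(Inf, 0))
    }
    ht <- stats::t.test(x, y, var.equal = FALSE)
    c(unname(ht$statistic), ht$p.value)
  }, numeric(2))
  p <- res[2, ]
  data.frame(otu_id = a$otu_ids, t = res[1, ], p = p,
             heat = pmin(pmax(1 - p, 0), 1),
             stringsAsFactors = FALSE)
}
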