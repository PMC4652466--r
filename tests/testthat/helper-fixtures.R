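# Fixtures are built in code; no binary files.

# wrap a prescribed masked correlation matrix as a correlation_result so
# networks with exact edge structure can be built through the public API
fake_corr <- function(r_masked, mask_alpha = 0.25) {
  n <- ncol(r_masked)
  if (is.null(colnames(r_masked)))
    dimnames(r_masked) <- list(sprintf("T%02d", 1:n), sprintf("T%02d", 1:n))
  structure(list(r = r_masked, p = matrix(0, n, n, dimnames = dimnames(r_masked)),
                 q = matrix(0, n, n, dimnames = dimnames(r_masked)),
                 r_masked = r_masked, mask_alpha = mask_alpha, n_samples = 10L),
            class = "correlation_result")
}

net_from_masked <- function(r_masked) build_network(fake_corr(r_masked))

# block-diagonal positive correlation matrix: one block per size
block_corr <- function(sizes, intra = 0.8) {
  n <- sum(sizes)
  R <- diag(n)
  off <- 0
  for (s in sizes) {
    ix <- off + seq_len(s)
    R[ix, ix] <- intra
    off <- off + s
  }
  diag(R) <- 1
  dimnames(R) <- list(sprintf("T%02d", 1:n), sprintf("T%02d", 1:n))
  R
}

# adjacency of two disjoint unit-weight triangles
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6))
    for (i in tri) for (j in tri) if (i != j) w[i, j] <- 1
  w
}

# two k-cliques joined by a single weak bridge edge
barbell <- function(k = 5, bridge = 0.05) {
  n <- 2 * k
  w <- matrix(0, n, n)
  for (cl in list(1:k, (k + 1):n))
    for (i in cl) for (j in cl) if (i != j) w[i, j] <- 1
  w[k, k + 1] <- bridge
  w[k + 1, k] <- bridge
  w
}

# write a small abundance + metadata TSV pair, returning the two paths
write_toy_tables <- function(counts, groups, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- abundance_matrix(counts, groups)
  paths <- file.path(dir, c("abund.tsv", "meta.tsv"))
  write_abundance_table(m, paths[1], paths[2])
  paths
}

# deterministic toy counts: 4 samples x 3 OTUs
toy_counts <- function() {
  counts <- matrix(c(10, 0, 5,
                     20, 1, 0,
                     30, 0, 2,
                     40, 2, 1), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("S", 1:4), c("Prev", "Strep", "Veil")))
  counts
}
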