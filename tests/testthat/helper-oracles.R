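# Independent oracles, written against the textbook definitions and kept
# deliberately naive. They never call the package code paths they check.

# Benjamini-Hochberg step-up, explicit sort + running minimum from the top.
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  q_sorted <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, p[o[k]] * m / k)
    q_sorted[k] <- running
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Naive Markov clustering: plain loops, no pruning, clusters read as the
# weakly connected components of the thresholded converged matrix.
naive_mcl <- function(w, inflation = 2, self_loop = 1, iters = 200) {
  n <- nrow(w)
  M <- w
  for (i in 1:n) M[i, i] <- self_loop
  for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  for (step in 1:iters) {
    M <- M %*% M
    M <- M^inflation
    for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  }
  adj <- (M > 1e-6) | t(M > 1e-6)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in 1:n) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# Adjusted Rand index from the contingency table (Hubert & Arabie).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Welch two-sample t-test p-value straight from the textbook formulas.
welch_p_oracle <- function(x, y) {
  vx <- sum((x - mean(x))^2) / (length(x) - 1)
  vy <- sum((y - mean(y))^2) / (length(y) - 1)
  se2 <- vx / length(x) + vy / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                 (vy / length(y))^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}
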