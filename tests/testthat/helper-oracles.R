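# Exhaustive brute-force graph-metric oracle: Floyd-Warshall distances,
# explicit shortest-path counting, triangle counting via A^3.  Independent
# of the package's implementation path.

oracle_floyd <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_graph_metrics <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd(adj)
  inv <- 1 / d
  diag(inv) <- 0
  nodal_eff <- rowSums(inv) / (n - 1)
  deg <- rowSums(adj)

  sigma <- matrix(0, n, n)           # shortest-path counts
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (v in order(d[s, ])) {
      if (v == s || !is.finite(d[s, v])) next
      preds <- which(adj[, v] == 1 & d[s, ] == d[s, v] - 1)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  if (n >= 3) {
    for (i in seq_len(n)) {
      tot <- 0
      for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
        if (s == i || t == i || !is.finite(d[s, t])) next
        if (is.finite(d[s, i]) && is.finite(d[i, t]) &&
            d[s, i] + d[i, t] == d[s, t]) {
          tot <- tot + sigma[s, i] * sigma[i, t] / sigma[s, t]
        }
      }
      btw[i] <- tot / ((n - 1) * (n - 2) / 2)
    }
  }
  tri <- diag(adj %*% adj %*% adj) / 2
  cc <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    ds <- oracle_floyd(adj[nb, nb, drop = FALSE])
    invs <- 1 / ds
    diag(invs) <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  list(global_efficiency = mean(nodal_eff), degree = deg,
       nodal_efficiency = nodal_eff, betweenness = btw,
       clustering = cc, local_efficiency = loc)
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(runif(sum(up)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

expect_metrics_equal <- function(got, want, tol = 1e-12) {
  for (nm in c("global_efficiency", "degree", "nodal_efficiency",
               "betweenness", "clustering", "local_efficiency")) {
    expect_equal(unname(got[[nm]]), unname(want[[nm]]), tolerance = tol,
                 label = nm)
  }
}

# Benjamini-Hochberg step-up oracle: q_(i) = min_{j >= i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
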