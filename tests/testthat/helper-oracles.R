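# Independent brute-force oracles for small weighted graphs. Distances come
# from Floyd-Warshall; shortest-path counts from the combinatorial
# recurrence over nodes ordered by distance; betweenness from the
# sigma_sv * sigma_vt / sigma_st identity. Deliberately a different
# algorithm family from the package's Dijkstra-based implementation.
brute_graph_metrics <- function(W, tol = 1e-9) {
  K <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  diag(len) <- 0
  # Floyd-Warshall
  d <- len
  for (k in seq_len(K)) {
    for (i in seq_len(K)) {
      alt <- d[i, k] + d[k, ]
      d[i, ] <- pmin(d[i, ], alt)
    }
  }
  # shortest-path counts
  sig <- matrix(0, K, K)
  for (s in seq_len(K)) {
    sig[s, s] <- 1
    ord <- order(d[s, ])
    for (t in ord) {
      if (t == s || !is.finite(d[s, t])) next
      for (u in seq_len(K)) {
        if (u != t && W[u, t] > 0 &&
          abs(d[s, u] + len[u, t] - d[s, t]) <= tol * (1 + d[s, t])) {
          sig[s, t] <- sig[s, t] + sig[s, u]
        }
      }
    }
  }
  btw <- numeric(K)
  for (v in seq_len(K)) {
    for (s in seq_len(K)) {
      for (t in seq_len(K)) {
        if (s == t || v == s || v == t) next
        if (!is.finite(d[s, t])) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) <= tol * (1 + d[s, t])) {
          btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  btw <- btw / 2 / ((K - 1) * (K - 2) / 2)
  # Onnela clustering by direct triangle enumeration
  wmax <- max(W)
  cl <- 0
  if (wmax > 0) {
    y <- (W / wmax)^(1 / 3)
    for (i in seq_len(K)) {
      ki <- sum(W[i, ] > 0)
      if (ki < 2) next
      cyc <- 0
      for (j in seq_len(K)) {
        for (l in seq_len(K)) {
          if (j != l && j != i && l != i) {
            cyc <- cyc + y[i, j] * y[j, l] * y[l, i]
          }
        }
      }
      cl <- cl + cyc / (ki * (ki - 1))
    }
    cl <- cl / K
  }
  off_d <- d[upper.tri(d)]
  list(
    strength = rowSums(W), degree = rowSums(W > 0), betweenness = btw,
    clustering = cl,
    path_length = mean(off_d[is.finite(off_d)])
  )
}

# small modular Fisher-z matrix with planted communities (for graph tests)
modular_z <- function(K = 60, blocks = 4, within = 0.4, between = 0.05,
                      noise = 0.1, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(blocks), length.out = K)
  z <- ifelse(outer(lab, lab, "=="), within, between) +
    matrix(rnorm(K * K, 0, noise), K, K)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  z
}
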