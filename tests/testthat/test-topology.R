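triangle_graph <- function(w = 0.5) {
  m <- matrix(w, 3, 3)
  diag(m) <- 0
  structure(
    list(weights = m, density = 1, K = 3, subject_id = "t", group = NA),
    class = "thresholded_graph"
  )
}

path_graph <- function() {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- m[2, 3] <- m[3, 2] <- 1
  structure(
    list(weights = m, density = 2 / 3, K = 3, subject_id = "p", group = NA),
    class = "thresholded_graph"
  )
}

test_that("nodal metrics agree with closed-form small cases", {
  tri <- nodal_metrics(triangle_graph())
  expect_equal(tri$strength, rep(1, 3))
  expect_equal(tri$degree, rep(2L, 3))
  expect_equal(tri$betweenness, rep(0, 3))
  pg <- nodal_metrics(path_graph())
  expect_equal(pg$betweenness, c(0, 1, 0)) # single intermediary
  expect_error(
    nodal_metrics(list(weights = matrix(0, 2, 2), K = 2)),
    "K < 3"
  )
})

test_that("global metrics match closed forms", {
  m <- matrix(1, 4, 4)
  diag(m) <- 0
  g4 <- list(weights = m, density = 1, K = 4)
  gm <- global_metrics(g4)
  expect_equal(gm$clustering, 1)
  expect_equal(gm$path_length, 1)
  expect_equal(global_metrics(path_graph())$clustering, 0)
  expect_error(
    global_metrics(list(weights = matrix(0, 3, 3), K = 3)),
    "no edges"
  )
})

test_that("metrics equal an independent igraph computation on larger graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:3) {
    z <- modular_z(45, seed = s)
    g <- threshold_by_density(z, c(0.08, 0.15, 0.3)[s])
    nm <- nodal_metrics(g)
    gm <- global_metrics(g)
    ig <- igraph::graph_from_adjacency_matrix(
      g$weights,
      mode = "undirected", weighted = TRUE
    )
    btw <- igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight) /
      ((45 - 1) * (45 - 2) / 2)
    expect_equal(nm$betweenness, unname(btw), tolerance = 1e-12)
    expect_equal(nm$strength, unname(igraph::strength(ig)))
    expect_equal(nm$degree, unname(igraph::degree(ig)))
    dd <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
    off <- dd[upper.tri(dd)]
    expect_equal(gm$path_length, mean(off[is.finite(off)]))
  }
})

test_that("strength satisfies the handshake identity and scale consistency", {
  z <- modular_z(40, seed = 7)
  g <- threshold_by_density(z, 0.12)
  nm <- nodal_metrics(g)
  expect_equal(sum(nm$strength), sum(g$weights))
  g2 <- g
  g2$weights <- 3 * g$weights
  nm2 <- nodal_metrics(g2)
  expect_equal(nm2$strength, 3 * nm$strength)
  expect_equal(nm2$degree, nm$degree)
  expect_equal(nm2$betweenness, nm$betweenness)
})

test_that("network means aggregate nodal values", {
  parc <- make_parcellation(c(FPN = 3, DMN = 4), seed = 1)
  expect_equal(network_mean(rep(2.5, 7), parc, "FPN"), 2.5)
  vals <- c(1, 2, 3, 10, 20, 30, 40)
  expect_equal(network_mean(vals, parc, "FPN"), 2)
  expect_equal(network_mean(vals, parc, "DMN"), 25)
  expect_error(network_mean(vals, parc, "NOPE"), "unknown network")
  expect_error(network_mean(1:3, parc, "FPN"), "does not match")
})

test_that("rewired nulls preserve degree sequence and weight multiset", {
  z <- modular_z(50, seed = 8)
  g <- threshold_by_density(z, 0.1)
  nulls <- rewire_null(g, n_nulls = 5, seed = 3)
  deg <- colSums(g$weights > 0)
  wts <- sort(g$weights[upper.tri(g$weights) & g$weights > 0])
  for (n in nulls) {
    expect_equal(colSums(n$weights > 0), deg)
    expect_equal(sort(n$weights[upper.tri(n$weights) & n$weights > 0]), wts)
  }
  # same seed, same nulls
  nulls2 <- rewire_null(g, n_nulls = 5, seed = 3)
  expect_identical(nulls[[2]]$weights, nulls2[[2]]$weights)
  # rewiring destroys modular clustering
  c_real <- global_metrics(g)$clustering
  c_null <- mean(vapply(
    rewire_null(g, n_nulls = 20, seed = 4),
    function(n) global_metrics(n)$clustering, 1.0
  ))
  expect_gt(c_real, c_null)
})

test_that("null normalization handles zero null means as specified", {
  expect_equal(normalize_by_null(c(2, 4), list(c(1, 2), c(3, 6))), c(1, 1))
  expect_equal(normalize_by_null(c(0, 3), list(c(0, 1), c(0, 2))), c(1, 2))
  out <- normalize_by_null(c(5, 0), list(c(0, 1), c(0, 1)))
  expect_true(is.na(out[1]))
  expect_equal(out[2], 0)
  expect_error(normalize_by_null(1:3, list(1:2)), "shape mismatch")
})

test_that("small-worldness is 1 against self-nulls and >1 for a lattice", {
  z <- modular_z(30, seed = 9)
  g <- threshold_by_density(z, 0.2)
  expect_equal(small_worldness(g, list(g, g, g)), 1, tolerance = 1e-12)
  # ring lattice K = 60, k = 6
  K <- 60
  m <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (off in 1:3) {
      j <- ((i - 1 + off) %% K) + 1
      m[i, j] <- m[j, i] <- 1
    }
  }
  ring <- structure(
    list(weights = m, density = 6 / 59, K = K, subject_id = "r", group = NA),
    class = "thresholded_graph"
  )
  nulls <- rewire_null(ring, n_nulls = 20, seed = 5)
  expect_gt(small_worldness(ring, nulls), 1)
})

test_that("AUC over densities integrates by the trapezoid rule", {
  d <- density_grid()$densities
  expect_equal(auc_over_densities(rep(2, 16), d), 0.6, tolerance = 1e-12)
  expect_equal(auc_over_densities(d, d), (0.325^2 - 0.025^2) / 2,
    tolerance = 1e-12
  )
  expect_equal(
    auc_over_densities(rev(d), rev(d)),
    auc_over_densities(d, d)
  )
  expect_error(auc_over_densities(1, 0.1), "at least two")
  expect_error(auc_over_densities(1:3, 1:2), "same length")
  # flagged non-finite values are excluded
  v <- c(NA, 1, 1, NA)
  expect_equal(auc_over_densities(v, c(0.1, 0.2, 0.3, 0.4)), 0.1)
})

test_that("subject topology marks an admissible low-density range", {
  z <- modular_z(60, within = 0.5, noise = 0.08, seed = 10)
  C <- structure(
    list(z = z, subject_id = "s1", group = "CONTROL"),
    class = "connectivity_matrix"
  )
  grid <- density_grid(0.05, 0.45, 0.1)
  prof <- subject_topology(C, grid, n_nulls = 15, seed = 2)
  expect_true(any(prof$admissible))
  # normalized degree is identically 1 where defined (degree preserved)
  adm <- which(prof$admissible)[1]
  nd <- prof$norm$degree[, adm]
  expect_true(all(nd[is.finite(nd)] == 1))
  # sigma equals gamma / lambda
  expect_equal(
    prof$sigma[adm],
    prof$gamma[adm] / prof$lambda[adm]
  )
})
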