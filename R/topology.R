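#' Nodal topological metrics of a thresholded graph
#'
#' Connectivity strength (row sums of edge weights), degree (nonzero edge
#' counts) and weighted shortest-path betweenness. Betweenness uses edge
#' lengths `1/weight` (the standard mapping for correlation-weighted graphs)
#' and is normalized by `(K - 1)(K - 2) / 2`, the number of node pairs a
#' node could mediate.
#'
#' @param g A `thresholded_graph`.
#' @return A `nodal_metrics` list: `strength`, `degree`, `betweenness`,
#'   `density`.
#' @examples
#' z <- matrix(0.5, 3, 3); diag(z) <- 0
#' nodal_metrics(threshold_by_density(z, 1))$strength
#' @export
nodal_metrics <- function(g) {
  if (g$K < 3) stopf("betweenness undefined for K < 3 nodes")
  m <- .cpp_graph_metrics(g$weights)
  structure(
    list(
      strength = m$strength, degree = m$degree,
      betweenness = m$betweenness, density = g$density
    ),
    class = "nodal_metrics"
  )
}

#' Global clustering coefficient and characteristic path length
#'
#' Weighted clustering uses the geometric-mean (Onnela) triangle form with
#' weights scaled by the maximum edge weight, averaged over all nodes
#' (degree < 2 nodes contribute 0). Characteristic path length is the mean
#' finite shortest-path length on `1/weight` edge lengths; disconnected
#' pairs are excluded.
#'
#' @param g A `thresholded_graph`.
#' @return List with `clustering` and `path_length`.
#' @export
global_metrics <- function(g) {
  if (g$K < 3) stopf("global metrics undefined for K < 3 nodes")
  if (sum(g$weights > 0) == 0) stopf("undefined metrics: graph has no edges")
  m <- .cpp_graph_metrics(g$weights)
  list(clustering = m$clustering, path_length = m$path_length)
}

#' Degree-preserving rewired null graphs
#'
#' Each null applies Maslov-Sneppen double-edge swaps (`swaps_per_edge`
#' attempts per edge) to the binary topology, then reassigns the original
#' multiset of edge weights to the rewired edges in random order. The degree
#' sequence, edge count and weight multiset are preserved exactly.
#'
#' @param g A `thresholded_graph` with at least one edge.
#' @param n_nulls Number of surrogate graphs.
#' @param seed Integer seed.
#' @param swaps_per_edge Swap attempts per edge (mixing heuristic).
#' @return List of `thresholded_graph` surrogates.
#' @export
rewire_null <- function(g, n_nulls = 100, seed = 1, swaps_per_edge = 10) {
  n_edges <- sum(g$weights > 0) / 2
  if (n_edges < 1) stopf("cannot rewire a graph without edges")
  with_seed(seed, {
    lapply(seq_len(n_nulls), function(i) {
      r <- .cpp_rewire(g$weights, as.integer(swaps_per_edge))
      if (r$accepted == 0 && n_edges >= 2) {
        warnf("rewiring stalled: no valid swap accepted (null %d)", i)
      }
      out <- g
      out$weights <- r$weights
      out
    })
  })
}

#' Normalize metrics against a null ensemble
#'
#' Elementwise division of the real value by the null mean. A `0 / 0`
#' normalizes to 1 (real and nulls agree); a nonzero value over a zero null
#' mean is flagged `NA` and excluded from downstream AUC summaries.
#'
#' @param real Numeric scalar or vector.
#' @param nulls List of same-shaped numeric values, or a matrix with one
#'   null per row.
#' @return Same shape as `real`.
#' @export
normalize_by_null <- function(real, nulls) {
  nm <- if (is.matrix(nulls)) {
    colMeans(nulls)
  } else if (is.list(nulls)) {
    if (!length(nulls)) stopf("need at least one null")
    if (any(vapply(nulls, length, 1L) != length(real))) {
      stopf("shape mismatch between real values and nulls")
    }
    colMeans(do.call(rbind, lapply(nulls, as.numeric)))
  } else {
    as.numeric(nulls)
  }
  if (length(nm) != length(real)) {
    stopf("shape mismatch between real values and null means")
  }
  out <- real / nm
  zero <- nm == 0
  out[zero & real == 0] <- 1
  out[zero & real != 0] <- NA_real_
  out
}

#' Small-worldness of a graph against rewired nulls
#'
#' `sigma = gamma / lambda`, where `gamma` is clustering normalized by the
#' null-mean clustering and `lambda` the equally normalized characteristic
#' path length. Values above 1 indicate small-world organization; the
#' density-admissibility criterion requires `sigma > 1.5`.
#'
#' @param g A `thresholded_graph`.
#' @param nulls List of null graphs from [rewire_null()].
#' @return Scalar sigma.
#' @export
small_worldness <- function(g, nulls) {
  real <- global_metrics(g)
  nc <- vapply(nulls, function(n) global_metrics(n)$clustering, 1.0)
  nl <- vapply(nulls, function(n) global_metrics(n)$path_length, 1.0)
  if (mean(nc) == 0 || mean(nl) == 0) {
    stopf("undefined sigma: zero null means")
  }
  (real$clustering / mean(nc)) / (real$path_length / mean(nl))
}

#' Trapezoidal area under a metric across densities
#'
#' Integrates `values` over `densities` (fraction units) by the trapezoid
#' rule after sorting by density; `NA` values (flagged normalizations) are
#' dropped pairwise. Used to summarize metrics across the admissible density
#' range, removing the dependence on any single threshold.
#'
#' @param values Numeric vector, one value per density.
#' @param densities Numeric vector of densities.
#' @return Scalar AUC (`NA` if fewer than two finite points remain).
#' @examples
#' auc_over_densities(rep(2, 16), density_grid()$densities) # 0.6
#' @export
auc_over_densities <- function(values, densities) {
  if (length(values) != length(densities)) {
    stopf("values and densities must have the same length")
  }
  if (length(densities) < 2) {
    stopf("AUC needs at least two densities")
  }
  ok <- is.finite(values) & is.finite(densities)
  if (sum(ok) < 2) {
    return(NA_real_)
  }
  v <- values[ok]
  d <- densities[ok]
  o <- order(d)
  v <- v[o]
  d <- d[o]
  sum(diff(d) * (head(v, -1) + v[-1]) / 2)
}

#' Mean of a nodal metric over one network's nodes
#'
#' The network-level value of a nodal metric: the arithmetic mean over the
#' `K_j` nodes assigned to the network.
#'
#' @param values Numeric vector, one value per node (parcellation order).
#' @param parc A parcellation.
#' @param network Network name.
#' @return Scalar mean.
#' @export
network_mean <- function(values, parc, network) {
  if (length(values) != nrow(parc)) {
    stopf("values length %d does not match parcellation K = %d",
      length(values), nrow(parc))
  }
  idx <- parc$network == network
  if (!any(idx)) stopf("unknown network '%s'", network)
  mean(values[idx])
}

#' Raw and null-normalized topology of one subject across the density grid
#'
#' For every density: thresholds the connectivity matrix, computes nodal
#' strength/degree/betweenness and global clustering/path length, estimates
#' the null distribution of each from `n_nulls` degree-preserving rewired
#' surrogates, and derives the normalized metrics, `gamma`, `lambda`,
#' `sigma` and the admissibility flag (unconnected nodes < 10% and
#' `sigma > 1.5`).
#'
#' @param C A `connectivity_matrix`.
#' @param grid A [density_grid()].
#' @param n_nulls Null networks per density.
#' @param seed Integer seed.
#' @param swaps_per_edge Swap attempts per edge for the nulls.
#' @param max_unconnected,sigma_min Admissibility criteria.
#' @param contiguous Treat the admissible range as contiguous in density:
#'   densities are evaluated in increasing order and, once small-worldness
#'   falls to `sigma_min` or below, all higher densities are marked
#'   inadmissible without evaluating their null ensembles. Sigma decreases
#'   monotonically with density on correlation-derived graphs, so this
#'   reproduces the contiguous threshold range the analysis assumes while
#'   skipping redundant null models.
#' @param max_eval Highest density index to evaluate; used by
#'   [cohort_topology()] to skip densities already excluded from the shared
#'   admissible range by earlier subjects (the result over that range is
#'   unchanged).
#' @return A `topology_profile`: per-density raw and normalized metric
#'   matrices (K x n_densities), `gamma`, `lambda`, `sigma`,
#'   `frac_unconnected`, `admissible`.
#' @export
subject_topology <- function(C, grid, n_nulls = 100, seed = 1,
                             swaps_per_edge = 10, max_unconnected = 0.1,
                             sigma_min = 1.5, contiguous = TRUE,
                             max_eval = Inf) {
  prep <- threshold_prep(C)
  K <- prep$K
  nd <- length(grid$densities)
  raw <- list(
    strength = matrix(NA_real_, K, nd), degree = matrix(NA_real_, K, nd),
    betweenness = matrix(NA_real_, K, nd)
  )
  norm <- raw
  gamma <- lambda <- sigma <- frac_unc <- rep(NA_real_, nd)
  admissible <- logical(nd)
  sigma_failed <- FALSE
  for (i in seq_len(nd)) {
    if (i > max_eval) break
    g <- threshold_take(prep, grid$densities[i])
    frac_unc[i] <- fraction_unconnected(g)
    if (sum(g$weights > 0) == 0) next
    if (contiguous && sigma_failed) next
    real <- .cpp_graph_metrics(g$weights)
    ens <- with_seed(
      derive_seed(seed, "nulls", i),
      .cpp_null_ensemble(g$weights, as.integer(n_nulls),
        as.integer(swaps_per_edge))
    )
    raw$strength[, i] <- real$strength
    raw$degree[, i] <- real$degree
    raw$betweenness[, i] <- real$betweenness
    norm$strength[, i] <- normalize_by_null(real$strength, ens$strength)
    # rewired nulls preserve each node's degree exactly, so normalized
    # degree is identically 1 wherever degree > 0
    norm$degree[, i] <- normalize_by_null(
      as.numeric(real$degree),
      matrix(as.numeric(real$degree), 1, K)
    )
    norm$betweenness[, i] <- normalize_by_null(
      real$betweenness,
      ens$betweenness
    )
    gamma[i] <- real$clustering / mean(ens$clustering)
    lambda[i] <- real$path_length / mean(ens$path_length)
    sigma[i] <- gamma[i] / lambda[i]
    # a sigma failure only truncates the range when the graph was well
    # connected: on fragmented very-sparse graphs sigma estimates are not
    # yet in the monotone regime
    if ((!is.finite(sigma[i]) || sigma[i] <= sigma_min) &&
      frac_unc[i] < max_unconnected) {
      sigma_failed <- TRUE
    }
    admissible[i] <- frac_unc[i] < max_unconnected &&
      is.finite(sigma[i]) && sigma[i] > sigma_min
  }
  structure(
    list(
      subject_id = C$subject_id, group = C$group,
      densities = grid$densities, raw = raw, norm = norm,
      gamma = gamma, lambda = lambda, sigma = sigma,
      frac_unconnected = frac_unc, admissible = admissible
    ),
    class = "topology_profile"
  )
}

#' Cohort topology with a shared admissible density range
#'
#' Computes [subject_topology()] for every subject, intersects the
#' per-subject admissible densities (the shared range over which all
#' networks meet the constraints), and summarizes each normalized nodal
#' metric by its AUC over that range, plus the per-network means.
#'
#' @param connectivities List of `connectivity_matrix` objects.
#' @param grid A [density_grid()].
#' @param parc The shared parcellation.
#' @param n_nulls,seed,swaps_per_edge Passed to [subject_topology()].
#' @return A `cohort_topology`: list with `profiles`, logical
#'   `shared_admissible`, `auc_nodal` (subjects x K x 3 array over
#'   strength/betweenness/degree), `auc_network` (subjects x networks x 3),
#'   `groups`, `networks`.
#' @export
cohort_topology <- function(connectivities, grid, parc, n_nulls = 100,
                            seed = 1, swaps_per_edge = 10) {
  n <- length(connectivities)
  profiles <- vector("list", n)
  # running intersection of admissible densities: later subjects skip null
  # ensembles at densities an earlier subject has already excluded
  running <- rep(TRUE, length(grid$densities))
  for (s in seq_len(n)) {
    cap <- if (any(running)) max(which(running)) else 0
    profiles[[s]] <- subject_topology(
      connectivities[[s]], grid,
      n_nulls = n_nulls, seed = derive_seed(seed, "topology", s),
      swaps_per_edge = swaps_per_edge, max_eval = max(cap, 1)
    )
    running <- running & profiles[[s]]$admissible
  }
  adm <- running
  if (sum(adm) < 2) {
    warnf(
      "shared admissible range has %d densities; AUC needs at least 2",
      sum(adm)
    )
  }
  metrics <- c("strength", "betweenness", "degree")
  K <- nrow(parc)
  nets <- unique(parc$network)
  auc_nodal <- array(
    NA_real_, c(n, K, 3),
    dimnames = list(NULL, parc$label, metrics)
  )
  auc_network <- array(
    NA_real_, c(n, length(nets), 3),
    dimnames = list(NULL, nets, metrics)
  )
  d_adm <- grid$densities[adm]
  for (s in if (sum(adm) >= 2) seq_len(n) else integer(0)) {
    for (m in metrics) {
      vals <- profiles[[s]]$norm[[m]][, adm, drop = FALSE]
      auc_nodal[s, , m] <- apply(vals, 1, auc_over_densities, densities = d_adm)
      for (net in nets) {
        auc_network[s, net, m] <- network_mean(auc_nodal[s, , m], parc, net)
      }
    }
  }
  structure(
    list(
      profiles = profiles, shared_admissible = adm, densities = grid$densities,
      auc_nodal = auc_nodal, auc_network = auc_network,
      groups = vapply(profiles, `[[`, "", "group"),
      subject_ids = vapply(profiles, `[[`, "", "subject_id"),
      networks = nets, parcellation = parc
    ),
    class = "cohort_topology"
  )
}
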