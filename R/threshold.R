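#' Connection-density grid
#'
#' Inclusive arithmetic sequence of proportional connection densities; the
#' defaults reproduce the 2.5-32.5% range in steps of 2% (16 densities).
#' Admissibility flags are `NA` until [select_density_range()] fills them.
#'
#' @param start,stop,step Density fractions, `0 < start <= stop <= 1`.
#' @return A `density_grid`: list with `densities` and logical `admissible`.
#' @examples
#' length(density_grid()$densities) # 16
#' @export
density_grid <- function(start = 0.025, stop = 0.325, step = 0.02) {
  if (step <= 0) stopf("invalid step: step must be positive")
  if (!(start > 0 && start <= stop && stop <= 1)) {
    stopf("invalid range: need 0 < start <= stop <= 1")
  }
  densities <- seq(start, stop, by = step)
  structure(
    list(densities = densities, admissible = rep(NA, length(densities))),
    class = "density_grid"
  )
}

as_z_matrix <- function(C) {
  if (inherits(C, "connectivity_matrix")) C$z else as.matrix(C)
}

#' Threshold a connectivity matrix at a proportional density
#'
#' Sorts the upper-triangle absolute Fisher-z values from high to low and
#' retains the top `round(density * K * (K - 1) / 2)` as edges weighted by
#' `|z|` (rounding half away from zero; ties at the cut broken by ascending
#' `(i, j)` lexicographic order, which makes edge sets nested across
#' densities). All other entries are zero.
#'
#' @param C A `connectivity_matrix` or plain symmetric matrix.
#' @param density Fraction of possible edges to retain, in (0, 1].
#' @return A `thresholded_graph`: list with `weights` (K x K, symmetric,
#'   zero diagonal), `density`, `K`, `subject_id`, `group`.
#' @export
threshold_by_density <- function(C, density) {
  threshold_take(threshold_prep(C), density)
}

# one-time sort of the upper-triangle |z| values in cut order; the ordering
# is shared by every density (which is what makes edge sets nested)
threshold_prep <- function(C) {
  z <- as_z_matrix(C)
  K <- nrow(z)
  W <- abs(z)
  diag(W) <- 0
  ut <- which(upper.tri(W))
  ij <- arrayInd(ut, dim(W))
  ord <- order(-W[ut], ij[, 1], ij[, 2])
  list(
    W = W, K = K, sorted_idx = ut[ord],
    subject_id = if (inherits(C, "connectivity_matrix")) {
      C$subject_id
    } else {
      NA_character_
    },
    group = if (inherits(C, "connectivity_matrix")) C$group else
      NA_character_
  )
}

threshold_take <- function(prep, density) {
  if (!(density > 0 && density <= 1)) stopf("density must be in (0, 1]")
  K <- prep$K
  n_pairs <- K * (K - 1) / 2
  m <- round_half_away(density * n_pairs)
  if (m == 0) warnf("density %.4g retains no edges: empty graph", density)
  keep <- prep$sorted_idx[seq_len(min(m, n_pairs))]
  weights <- matrix(0, K, K)
  weights[keep] <- prep$W[keep]
  weights <- weights + t(weights)
  structure(
    list(
      weights = weights, density = density, K = K,
      subject_id = prep$subject_id, group = prep$group
    ),
    class = "thresholded_graph"
  )
}

#' Fraction of unconnected (degree-zero) nodes
#'
#' @param g A `thresholded_graph`.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_unconnected <- function(g) {
  mean(colSums(g$weights > 0) == 0)
}

#' Mark admissible densities for one subject
#'
#' A density is admissible when the thresholded graph has fewer than 10%
#' unconnected nodes and small-worldness above 1.5 (estimated against
#' `null_count` degree-preserving surrogates).
#'
#' @param C A `connectivity_matrix`.
#' @param grid A [density_grid()].
#' @param null_count Number of rewired null networks per density.
#' @param seed Integer seed for the null ensembles.
#' @param max_unconnected,sigma_min Admissibility criteria.
#' @param contiguous Evaluate densities in increasing order and stop
#'   testing small-worldness after its first failure (sigma decreases
#'   monotonically with density on correlation-derived graphs, making the
#'   admissible range contiguous); higher densities are then inadmissible.
#' @return The grid with its `admissible` flags filled in.
#' @export
select_density_range <- function(C, grid, null_count = 100, seed = 1,
                                 max_unconnected = 0.1, sigma_min = 1.5,
                                 contiguous = TRUE) {
  if (!length(grid$densities)) stopf("empty density grid")
  adm <- logical(length(grid$densities))
  for (i in seq_along(grid$densities)) {
    g <- threshold_by_density(C, grid$densities[i])
    if (fraction_unconnected(g) >= max_unconnected) next
    if (sum(g$weights > 0) == 0) next
    ens <- with_seed(
      derive_seed(seed, "nulls", i),
      .cpp_null_ensemble(g$weights, null_count, 10L)
    )
    real <- .cpp_graph_metrics(g$weights)
    sigma <- (real$clustering / mean(ens$clustering)) /
      (real$path_length / mean(ens$path_length))
    adm[i] <- is.finite(sigma) && sigma > sigma_min
    if (contiguous && !adm[i]) break
  }
  if (!any(adm)) warnf("no admissible density for subject %s", C$subject_id)
  grid$admissible <- adm
  grid
}
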