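#' Euclidean inter-node distance matrix
#'
#' @param parc A parcellation with MNI coordinates in mm.
#' @return Symmetric K x K matrix of distances (mm), zero diagonal.
#' @export
distance_matrix <- function(parc) {
  xyz <- as.matrix(parc[, c("x_mm", "y_mm", "z_mm")])
  if (any(!is.finite(xyz))) stopf("non-finite coordinates in parcellation")
  as.matrix(stats::dist(xyz))
}

DIST_BIN_EDGES <- seq(0, 180, by = 10)

#' Distance-binned connectivity strength of one network
#'
#' For each 10 mm distance interval (half-open `[low, high)`, last bin
#' closed at 180 mm), the mean edge weight over all ordered pairs `(i, j)`
#' with `i` in the network, `j` any other whole-brain node and the pair
#' distance in the bin. Pairs without a surviving edge contribute weight 0;
#' bins containing no pairs are flagged missing rather than zero-filled.
#'
#' @param g A `thresholded_graph`.
#' @param D Distance matrix from [distance_matrix()].
#' @param parc The parcellation.
#' @param network Network whose nodes anchor the profile.
#' @return A `distance_profile` data.frame: `bin_low`, `bin_high`, `mean`
#'   (NA when empty), `count`.
#' @export
binned_strength <- function(g, D, parc, network) {
  if (!all(dim(D) == dim(g$weights))) {
    stopf("distance and weight matrices have mismatched shapes")
  }
  idx <- which(parc$network == network)
  if (!length(idx)) stopf("unknown network '%s'", network)
  W <- g$weights[idx, , drop = FALSE]
  Ds <- D[idx, , drop = FALSE]
  self <- cbind(seq_along(idx), idx)
  keep <- rep(TRUE, length(W))
  keep[(self[, 2] - 1) * length(idx) + self[, 1]] <- FALSE
  w <- W[keep]
  d <- Ds[keep]
  if (any(d > 180)) {
    bad <- which(Ds > 180, arr.ind = TRUE)[1, ]
    stopf(
      "node pair (%d, %d) at %.1f mm exceeds the 180 mm bin range",
      idx[bad[1]], bad[2], Ds[bad[1], bad[2]]
    )
  }
  bin <- pmin(floor(d / 10), 17L) + 1L
  counts <- tabulate(bin, nbins = 18)
  sums <- vapply(
    seq_len(18),
    function(b) sum(w[bin == b]), 1.0
  )
  means <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  structure(
    data.frame(
      bin_low = DIST_BIN_EDGES[1:18], bin_high = DIST_BIN_EDGES[2:19],
      mean = means, count = counts
    ),
    network = network, subject_id = g$subject_id, group = g$group,
    class = c("distance_profile", "data.frame")
  )
}

#' Per-bin one-way ANOVA across groups with Tukey post-hoc contrasts
#'
#' Tests the effect of conscious state on distance-binned connectivity
#' strength, one ANOVA per distance interval, with Tukey HSD pairwise
#' contrasts. Bins missing for any subject are skipped with a warning.
#'
#' @param profiles Numeric matrix, subjects x 18 bins (e.g. AUC-summarized
#'   bin means), or a list of `distance_profile` data.frames.
#' @param groups Group label per subject.
#' @return List with `table` (data.frame: bin bounds, F, p) and `tukey`
#'   (per-bin list of contrast data.frames).
#' @export
groupwise_bin_anova <- function(profiles, groups) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    profiles <- do.call(rbind, lapply(profiles, function(p) p$mean))
  }
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    stopf("need at least 2 groups with at least 2 subjects each")
  }
  nb <- ncol(profiles)
  F_val <- p_val <- rep(NA_real_, nb)
  tukey <- vector("list", nb)
  skipped <- integer(0)
  for (b in seq_len(nb)) {
    v <- profiles[, b]
    if (any(!is.finite(v))) {
      skipped <- c(skipped, b)
      next
    }
    fit <- aov(v ~ groups)
    s <- summary(fit)[[1]]
    F_val[b] <- s$`F value`[1]
    p_val[b] <- s$`Pr(>F)`[1]
    tk <- TukeyHSD(fit)$groups
    tukey[[b]] <- data.frame(
      contrast = rownames(tk), diff = tk[, "diff"],
      lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
      row.names = NULL
    )
  }
  if (length(skipped)) {
    warnf(
      "skipping bins with missing values: %s",
      paste(skipped, collapse = ", ")
    )
  }
  list(
    table = data.frame(
      bin_low = DIST_BIN_EDGES[1:nb], bin_high = DIST_BIN_EDGES[2:(nb + 1)],
      F = F_val, p = p_val
    ),
    tukey = tukey
  )
}

#' AUC-summarized distance profiles for a cohort
#'
#' Computes [binned_strength()] for every subject at each admissible density
#' and summarizes each bin by its AUC across those densities (the same AUC
#' convention used for the topological metrics).
#'
#' @param connectivities List of `connectivity_matrix` objects.
#' @param ctop A `cohort_topology` (supplies the shared admissible range).
#' @param parc The parcellation.
#' @param network Network to profile.
#' @return Matrix subjects x 18 of AUC bin means (NA for empty bins), with
#'   the per-bin pair counts as attribute `counts`.
#' @export
cohort_distance_profiles <- function(connectivities, ctop, parc, network) {
  D <- distance_matrix(parc)
  adm <- which(ctop$shared_admissible)
  if (length(adm) < 2) stopf("need at least 2 admissible densities")
  dens <- ctop$densities[adm]
  n <- length(connectivities)
  out <- matrix(NA_real_, n, 18)
  counts <- NULL
  for (s in seq_len(n)) {
    per_density <- matrix(NA_real_, 18, length(adm))
    for (k in seq_along(adm)) {
      g <- threshold_by_density(connectivities[[s]], dens[k])
      prof <- binned_strength(g, D, parc, network)
      per_density[, k] <- prof$mean
      if (is.null(counts)) counts <- prof$count
    }
    out[s, ] <- apply(per_density, 1, function(v) {
      if (all(is.finite(v))) auc_over_densities(v, dens) else NA_real_
    })
  }
  attr(out, "counts") <- counts
  attr(out, "network") <- network
  out
}
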