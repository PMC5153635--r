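#' Two-way fixed-effects ANOVA on the subject x network table
#'
#' Tests the effects of conscious state and brain network (and their
#' interaction) on a network-level topological metric. Fitted as a fully
#' crossed fixed-effects design: with 29 subjects and 10 networks the error
#' degrees of freedom are 290 - 30 = 260 and the effect dfs (2, 9, 18).
#'
#' @param value Numeric vector, one entry per (subject, network) cell.
#' @param state Conscious-state label per entry.
#' @param network Network label per entry.
#' @return An `anova_result` data.frame: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
two_way_anova <- function(value, state, network) {
  state <- factor(state)
  network <- factor(network)
  if (any(table(state, network) == 0)) {
    stopf("empty cell in the state x network design")
  }
  fit <- aov(value ~ state * network)
  s <- summary(fit)[[1]]
  effects <- trimws(rownames(s))
  resid_row <- effects == "Residuals"
  df2 <- s$Df[resid_row]
  out <- data.frame(
    effect = c("state", "network", "state:network"),
    F = s$`F value`[!resid_row],
    df1 = s$Df[!resid_row],
    df2 = df2,
    p = s$`Pr(>F)`[!resid_row]
  )
  # degenerate data: an effect whose sum of squares is numerically zero
  # (relative to the total variation, itself relative to the data scale)
  # carries no signal; report F = 0 rather than the 0/0 artefact
  sst <- sum((value - mean(value))^2)
  ss_eff <- s$`Sum Sq`[!resid_row]
  if (sst <= 1e-20 * max(sum(value^2), 1)) {
    out$F <- 0
    out$p <- 1
  } else {
    zero_ss <- ss_eff <= 1e-12 * sst
    out$F[zero_ss] <- 0
    out$p[zero_ss] <- 1
  }
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey HSD post-hoc contrasts
#'
#' Studentized-range-adjusted pairwise group comparisons following a
#' one-way ANOVA.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 groups, each of size >= 2).
#' @return Data.frame with `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_posthoc <- function(values, groups) {
  groups <- factor(groups)
  tab <- table(groups)
  if (length(tab) < 2) stopf("need at least 2 groups")
  if (any(tab < 2)) stopf("every group needs at least 2 observations")
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  data.frame(
    contrast = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL
  )
}

#' Baseline-referenced Pearson correlation between two network metrics
#'
#' Correlates two per-patient metrics after subtracting the control-group
#' means (the controls serve as baseline), with Bonferroni adjustment over
#' the declared number of comparisons (default 3: the three topological
#' metrics).
#'
#' @param patient_a,patient_b Per-patient values of the two metrics.
#' @param control_mean_a,control_mean_b Control-group means.
#' @param m_comparisons Bonferroni comparison count.
#' @return List with `r`, `p`, `bonferroni_p` (capped at 1), `n`.
#' @export
baseline_correlation <- function(patient_a, patient_b, control_mean_a,
                                 control_mean_b, m_comparisons = 3) {
  if (length(patient_a) != length(patient_b) || length(patient_a) < 3) {
    stopf("need at least 3 patients with paired values")
  }
  a <- patient_a - control_mean_a
  b <- patient_b - control_mean_b
  if (var(a) == 0 || var(b) == 0) {
    stopf("undefined correlation: zero variance")
  }
  ct <- cor.test(a, b)
  list(
    r = unname(ct$estimate), p = ct$p.value,
    bonferroni_p = min(1, ct$p.value * m_comparisons),
    n = length(a)
  )
}

# one-way ANOVA F for every column of X (subjects x variables), vectorized
anova_f_columns <- function(X, groups) {
  groups <- factor(groups)
  n <- nrow(X)
  k <- nlevels(groups)
  counts <- as.vector(table(groups))
  gm <- colMeans(X)
  group_sums <- rowsum(X, groups)
  group_means <- group_sums / counts
  ssb <- colSums(counts * (t(t(group_means) - gm))^2)
  sst <- colSums(t(t(X) - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
}

#' Permutation test on nodal average F-values with FDR control
#'
#' For every node, the one-way ANOVA F across the three groups is averaged
#' over the three topological metrics; the null distribution is built by
#' re-sampling subjects into three new groups of the original sizes
#' `n_perm` times. Per-node p-values are the proportion of null average
#' F-values at or above the observed one, corrected across nodes by
#' Benjamini-Hochberg FDR.
#'
#' @param metric_array Numeric array, subjects x nodes x metrics (e.g. the
#'   AUC-summarized normalized strength/betweenness/degree of the tested
#'   networks' nodes).
#' @param groups Group label per subject (3 groups).
#' @param n_perm Number of permutations (default 10000; below 100 a
#'   warning flags the unstable p resolution).
#' @param seed Integer seed.
#' @return A `nodal_test_result` data.frame: `node`, `F` (observed average),
#'   `p`, `q` (BH-adjusted).
#' @export
nodal_permutation_test <- function(metric_array, groups, n_perm = 10000,
                                   seed = 1) {
  groups <- factor(groups)
  if (nlevels(groups) != 3) stopf("the nodal test expects 3 groups")
  if (n_perm < 100) warnf("n_perm = %d gives unstable p resolution", n_perm)
  dims <- dim(metric_array)
  n_sub <- dims[1]
  n_node <- dims[2]
  n_metric <- dims[3]
  flat <- matrix(metric_array, n_sub, n_node * n_metric)
  avg_f <- function(g) {
    f <- anova_f_columns(flat, g)
    rowMeans(matrix(f, n_node, n_metric))
  }
  obs <- avg_f(groups)
  exceed <- numeric(n_node)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      null_f <- avg_f(sample(groups))
      exceed <- exceed + (null_f >= obs)
    }
  })
  p <- exceed / n_perm
  node_names <- dimnames(metric_array)[[2]]
  if (is.null(node_names)) node_names <- as.character(seq_len(n_node))
  out <- data.frame(
    node = node_names, F = obs, p = p, q = p.adjust(p, method = "BH"),
    row.names = NULL
  )
  class(out) <- c("nodal_test_result", "data.frame")
  out
}
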