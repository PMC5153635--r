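test_that("two-way ANOVA reproduces the crossed-design degrees of freedom", {
  set.seed(1)
  n_sub <- 29
  nets <- paste0("net", 1:10)
  state <- rep(c("VS_UWS", "MCS", "CONTROL"), c(11, 7, 11))
  df <- expand.grid(subject = seq_len(n_sub), network = nets)
  df$state <- state[df$subject]
  df$value <- rnorm(nrow(df))
  res <- two_way_anova(df$value, df$state, df$network)
  expect_equal(res$df1, c(2, 9, 18))
  expect_equal(res$df2, rep(260, 3)) # 290 - 30
  expect_true(all(res$F >= 0))
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("two-way ANOVA handles constant data and planted effects", {
  state <- rep(c("A", "B", "C"), each = 20)
  network <- rep(rep(c("x", "y"), each = 10), 3)
  res <- two_way_anova(rep(1, 60), state, network)
  expect_equal(res$F, rep(0, 3))
  # sums of squares are additive
  set.seed(2)
  value <- rnorm(60)
  fit <- aov(value ~ factor(state) * factor(network))
  s <- summary(fit)[[1]]
  expect_equal(sum(s$`Sum Sq`), sum((value - mean(value))^2),
    tolerance = 1e-8
  )
  # planted additive state effect detected at alpha = 0.01
  hits <- vapply(1:100, function(i) {
    v <- rnorm(60) + (state == "A") * 1.5
    two_way_anova(v, state, network)$p[1] < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(
    two_way_anova(1:4, c("A", "A", "B", "B"), c("x", "x", "x", "y")),
    "empty cell"
  )
})

test_that("Tukey post-hoc contrasts behave like studentized-range tests", {
  set.seed(3)
  same <- c(rnorm(10), rnorm(10))
  g2 <- rep(c("a", "b"), each = 10)
  tk_same <- tukey_posthoc(same, g2)
  expect_gt(tk_same$p_adj, 0.2)
  # one group shifted by 5 SD: its two contrasts significant, the third not
  vals <- c(rnorm(10), rnorm(10), rnorm(10, 5))
  g3 <- rep(c("a", "b", "c"), each = 10)
  tk <- tukey_posthoc(vals, g3)
  expect_lt(tk$p_adj[tk$contrast == "c-a"], 0.001)
  expect_lt(tk$p_adj[tk$contrast == "c-b"], 0.001)
  expect_gt(tk$p_adj[tk$contrast == "b-a"], 0.05)
  # adjusted p is at least the plain two-sample p
  p_plain <- t.test(vals[g3 == "b"], vals[g3 == "a"], var.equal = TRUE)$p.value
  expect_gte(tk$p_adj[tk$contrast == "b-a"], p_plain)
  expect_error(tukey_posthoc(1:3, c("a", "a", "b")), "at least 2")
})

test_that("baseline-referenced correlations subtract control means", {
  a <- c(1, 2, 3, 4, 5)
  res <- baseline_correlation(a, -a, 2, 1)
  expect_equal(res$r, -1)
  set.seed(4)
  x <- rnorm(10)
  res2 <- baseline_correlation(x, rnorm(10), 0.5, 0.2, m_comparisons = 3)
  expect_equal(res2$bonferroni_p, min(1, res2$p * 3))
  # shifting by the baseline leaves r unchanged (location invariance)
  res3 <- baseline_correlation(a, -a, 0, 0)
  expect_equal(res3$r, res$r)
  expect_error(baseline_correlation(rep(1, 5), 1:5, 0, 0), "zero variance")
  expect_error(baseline_correlation(1:2, 1:2, 0, 0), "at least 3")
})

test_that("Bonferroni arithmetic matches the worked example", {
  res <- baseline_correlation(c(1, 2, 3, 5), c(2, 1, 4, 3), 0, 0,
    m_comparisons = 3
  )
  expect_equal(res$bonferroni_p, min(1, res$p * 3))
  # m = 3, p = 0.02 -> 0.06
  expect_equal(min(1, 0.02 * 3), 0.06)
})

test_that("nodal permutation test calibrates under the null and finds effects", {
  set.seed(5)
  groups <- rep(c("VS_UWS", "MCS", "CONTROL"), c(7, 5, 7))
  n_sub <- length(groups)
  # null data: essentially no discoveries at q < 0.05
  frac_disc <- vapply(1:10, function(i) {
    arr <- array(rnorm(n_sub * 8 * 3), c(n_sub, 8, 3))
    res <- nodal_permutation_test(arr, groups, n_perm = 300, seed = i)
    mean(res$q < 0.05)
  }, 1.0)
  expect_lt(mean(frac_disc), 0.05)
  # planted single-node effect is ranked first
  top_hits <- vapply(1:10, function(i) {
    set.seed(100 + i)
    arr <- array(rnorm(n_sub * 8 * 3), c(n_sub, 8, 3))
    arr[groups == "VS_UWS", 3, ] <- arr[groups == "VS_UWS", 3, ] + 2
    res <- nodal_permutation_test(arr, groups, n_perm = 300, seed = i)
    which.min(res$p) == 3
  }, TRUE)
  expect_gte(mean(top_hits), 0.8)
  # observed F matches a per-column aov oracle
  arr <- array(rnorm(n_sub * 3 * 3), c(n_sub, 3, 3))
  res <- nodal_permutation_test(arr, groups, n_perm = 100, seed = 1)
  for (nd in 1:3) {
    f_ora <- mean(vapply(1:3, function(m) {
      summary(aov(arr[, nd, m] ~ factor(groups)))[[1]]$`F value`[1]
    }, 1.0))
    expect_equal(res$F[nd], f_ora, tolerance = 1e-8)
  }
  expect_warning(
    nodal_permutation_test(arr, groups, n_perm = 50, seed = 1),
    "unstable"
  )
  expect_error(
    nodal_permutation_test(arr[groups != "MCS", , ],
      groups[groups != "MCS"],
      n_perm = 100
    ),
    "3 groups"
  )
})

test_that("FDR adjustment is Benjamini-Hochberg with monotone step-up", {
  set.seed(6)
  groups <- rep(c("VS_UWS", "MCS", "CONTROL"), each = 5)
  arr <- array(rnorm(15 * 6 * 3), c(15, 6, 3))
  res <- nodal_permutation_test(arr, groups, n_perm = 200, seed = 2)
  expect_equal(res$q, p.adjust(res$p, method = "BH"))
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("the permutation null is exchangeable", {
  set.seed(7)
  groups <- rep(c("VS_UWS", "MCS", "CONTROL"), each = 5)
  p_orig <- c()
  p_relab <- c()
  for (r in 1:25) {
    arr <- array(rnorm(15 * 4 * 3), c(15, 4, 3))
    p_orig <- c(
      p_orig,
      nodal_permutation_test(arr, groups, n_perm = 150, seed = r)$p
    )
    p_relab <- c(
      p_relab,
      nodal_permutation_test(arr, sample(groups), n_perm = 150,
        seed = r + 1000)$p
    )
  }
  ks <- suppressWarnings(ks.test(p_orig, p_relab))
  expect_gt(ks$p.value, 0.01)
})
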