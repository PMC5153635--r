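# minimal cohort_topology stand-in with known AUC values
mock_ctop <- function(n_sub, parc, values = NULL, groups = NULL) {
  metrics <- c("strength", "betweenness", "degree")
  K <- nrow(parc)
  if (is.null(values)) {
    set.seed(99)
    values <- array(rnorm(n_sub * K * 3), c(n_sub, K, 3))
  }
  dimnames(values) <- list(NULL, parc$label, metrics)
  if (is.null(groups)) {
    groups <- rep(c("VS_UWS", "MCS", "CONTROL"), length.out = n_sub)
  }
  structure(
    list(
      auc_nodal = values, groups = groups,
      parcellation = parc, networks = unique(parc$network)
    ),
    class = "cohort_topology"
  )
}

test_that("feature matrices concatenate 3 metrics per node deterministically", {
  parc <- make_parcellation(c(FPN = 25, DMN = 58, Other = 10), seed = 1)
  ctop <- mock_ctop(6, parc)
  fm <- build_features(ctop, c("FPN", "DMN"))
  expect_equal(ncol(fm$X), 3 * (25 + 58)) # 249 features at the study sizes
  expect_equal(nrow(fm$feature_index), 249)
  one <- build_features(ctop, "FPN")
  expect_equal(ncol(one$X), 75)
  # single node, three features
  single <- make_parcellation(c(FPN = 1, DMN = 1), seed = 1)
  fm1 <- build_features(mock_ctop(4, single), "FPN")
  expect_equal(ncol(fm1$X), 3)
  # identical ordering across calls
  fm2 <- build_features(ctop, c("FPN", "DMN"))
  expect_identical(fm$feature_index, fm2$feature_index)
  expect_identical(fm$X, fm2$X)
  expect_error(build_features(ctop, "Missing"), "unknown")
})

test_that("one-vs-rest training separates a separable 3-class toy set", {
  set.seed(2)
  centers <- rbind(c(0, 6), c(6, 0), c(-6, -6))
  X <- do.call(rbind, lapply(1:3, function(c) {
    sweep(matrix(rnorm(20, 0, 0.4), 10, 2), 2, centers[c, ], "+")
  }))
  y <- factor(rep(c("A", "B", "C"), each = 10))
  ovr <- train_ovr(X, y)
  expect_equal(dim(ovr$W), c(3, 2))
  pred <- apply(X, 1, function(x) {
    ovr$levels[decode_scores(drop(ovr$W %*% x) + ovr$b)]
  })
  expect_equal(mean(pred == as.character(y)), 1)
  # duplicated feature columns stay finite under regularization
  ovr2 <- train_ovr(cbind(X, X[, 1]), y)
  expect_true(all(is.finite(ovr2$W)))
  expect_error(train_ovr(X[1:10, ], droplevels(y[1:10])), "class")
})

test_that("loss-based decoding takes the maximal score with a stable tie rule", {
  expect_equal(decode_scores(c(2, -1, -1)), 1)
  expect_equal(decode_scores(c(-1, 3, 2)), 2)
  expect_equal(decode_scores(c(0.5, 0.5, -1)), 1) # tie -> lowest index
  set.seed(3)
  for (i in 1:50) {
    s <- rnorm(3)
    expect_equal(decode_scores(s), which.max(s))
  }
  expect_error(decode_scores(c(1, NaN, 0)), "non-finite")
})

test_that("LOOCV reports accuracy, per-class tallies and the binary identity", {
  set.seed(4)
  X <- rbind(
    matrix(rnorm(22, 5, 0.5), 11, 2),
    matrix(rnorm(22, -5, 0.5), 11, 2)
  )
  y <- factor(rep(c("VS_UWS", "CONTROL"), each = 11),
    levels = c("VS_UWS", "CONTROL")
  )
  rep <- loocv_classify(X, y)
  expect_equal(rep$accuracy, 100)
  expect_equal(sum(rep$per_class$correct), 22)
  expect_equal(rep$positive_class, "VS_UWS")
  # exact accuracy identity from sensitivity/specificity
  expect_equal(
    binary_accuracy_from_rates(
      rep$sensitivity, rep$specificity,
      rep$per_class$total[rep$per_class$class == "VS_UWS"],
      rep$per_class$total[rep$per_class$class != "VS_UWS"]
    ),
    rep$accuracy
  )
  expect_error(loocv_classify(X[1:2, ], y[1:2]), "at least 3")
})

test_that("LOOCV predictions are invariant to subject ordering", {
  set.seed(5)
  X <- rbind(
    matrix(rnorm(30, 2, 1), 10, 3),
    matrix(rnorm(30, -2, 1), 10, 3)
  )
  y <- factor(rep(c("a", "b"), each = 10))
  base <- loocv_classify(X, y)
  perm <- sample(20)
  shuffled <- loocv_classify(X[perm, ], y[perm])
  expect_equal(shuffled$predictions, base$predictions[perm])
  expect_equal(shuffled$accuracy, base$accuracy)
})

test_that("label-shuffled cohorts classify near chance", {
  set.seed(6)
  X <- matrix(rnorm(16 * 8), 16, 8)
  accs <- vapply(1:30, function(i) {
    y <- factor(sample(rep(c("a", "b"), each = 8)))
    loocv_classify(X, y)$accuracy
  }, 1.0)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 3 * se + 5)
})

test_that("permutation p-values follow the counting definition", {
  set.seed(7)
  X <- rbind(
    matrix(rnorm(16, 3, 1), 8, 2),
    matrix(rnorm(16, -3, 1), 8, 2)
  )
  y <- factor(rep(c("a", "b"), each = 8))
  out <- permutation_pvalue(X, y, n_perm = 30, seed = 11)
  expect_equal(out$p, mean(out$null_accuracies >= out$accuracy - 1e-9))
  expect_length(out$null_accuracies, 30)
  expect_gte(out$p, 0)
  expect_lte(out$p, 1)
  # a separable cohort beats its null distribution
  expect_equal(out$accuracy, 100)
  expect_lt(out$p, 0.2)
})

test_that("accuracy bookkeeping matches hand arithmetic", {
  expect_equal(accuracy_from_counts(c(9, 4, 6), c(11, 7, 11)),
    100 * 19 / 29)
  expect_equal(binary_accuracy_from_rates(80, 90, 10, 10), 85)
  expect_error(accuracy_from_counts(c(5), c(4)), "invalid")
})

test_that("nodal weight maps implement both summation conventions", {
  parc <- make_parcellation(c(FPN = 1, DMN = 1), seed = 1)
  fi <- data.frame(
    network = rep(c("FPN", "DMN"), each = 3),
    node_id = rep(1:2, each = 3),
    metric = rep(c("strength", "betweenness", "degree"), 2)
  )
  ovr <- structure(
    list(
      W = rbind(c(1, -2, 0.5, 0, 0, 0), matrix(0, 2, 6)),
      b = rep(0, 3), levels = c("A", "B", "C")
    ),
    class = "ovr_classifiers"
  )
  wm <- nodal_weight_map(ovr, fi)
  expect_equal(unname(wm["1"]), 0.5) # |1 - 2 + 0.5|
  wm2 <- nodal_weight_map(ovr, fi, convention = "abs_then_sum")
  expect_equal(unname(wm2["1"]), 3.5)
  expect_equal(unname(wm["2"]), 0)
  # random weights against a direct summation oracle
  set.seed(8)
  ovr$W <- matrix(rnorm(18), 3, 6)
  wm3 <- nodal_weight_map(ovr, fi)
  for (nd in 1:2) {
    cols <- which(fi$node_id == nd)
    expect_equal(unname(wm3[as.character(nd)]), abs(sum(ovr$W[, cols])))
  }
  expect_error(nodal_weight_map(ovr, fi[1:4, ]), "feature index")
})
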