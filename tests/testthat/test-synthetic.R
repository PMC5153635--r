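test_that("parcellation reproduces the 264-node, 10-network partition", {
  parc <- make_parcellation(seed = 1)
  expect_equal(nrow(parc), 264)
  expect_equal(length(unique(parc$network)), 10)
  expect_equal(sum(parc$network == "FPN"), 25)
  expect_equal(sum(parc$network == "DMN"), 58)
  expect_true(all(is.finite(as.matrix(parc[, c("x_mm", "y_mm", "z_mm")]))))
  # every node belongs to exactly one network; counts sum to K
  expect_equal(sum(table(parc$network)), nrow(parc))
  # distances stay within the profiling range
  expect_lt(max(distance_matrix(parc)), 180)
})

test_that("parcellation handles degenerate partitions and determinism", {
  one <- make_parcellation(c(Solo = 10), seed = 3)
  expect_equal(unique(one$network), "Solo")
  expect_equal(nrow(one), 10)
  a <- make_parcellation(c(FPN = 5, DMN = 6), seed = 9)
  b <- make_parcellation(c(FPN = 5, DMN = 6), seed = 9)
  expect_identical(a, b)
  expect_error(make_parcellation(c(5, 6)), "named")
  expect_error(make_parcellation(c(A = 0, B = 3)), "positive")
  expect_error(make_parcellation(c(A = 3), spread_mm = -1), "positive")
})

test_that("effect spec validates group multipliers", {
  fx <- effect_spec()
  expect_equal(unname(fx$multipliers["CONTROL"]), 0)
  expect_equal(unname(fx$multipliers["VS_UWS"]), 1)
  expect_error(
    effect_spec(multipliers = c(VS_UWS = 1, MCS = 0.5, CONTROL = 0.1)),
    "CONTROL"
  )
  expect_error(effect_spec(multipliers = c(VS_UWS = 1)), "groups")
})

test_that("group covariance plants distance-dependent FPN/DMN effects", {
  parc <- make_parcellation(seed = 2)
  D <- distance_matrix(parc)
  fx <- effect_spec()
  ctrl <- group_covariance(parc, "CONTROL", fx)
  vs <- group_covariance(parc, "VS_UWS", fx)
  fpn <- parc$network == "FPN"
  dmn <- parc$network == "DMN"
  long <- D > 75
  delta <- vs - ctrl
  # long-range within-FPN pairs gain, short-range within-DMN pairs lose
  fpn_long <- delta[fpn, fpn][long[fpn, fpn]]
  expect_gt(mean(fpn_long), 0.1)
  dmn_short_mask <- !long[dmn, dmn] & upper.tri(delta[dmn, dmn])
  expect_lt(mean(delta[dmn, dmn][dmn_short_mask]), -0.1)
  # both are positive definite after the eigenvalue floor
  expect_gt(min(eigen(vs, symmetric = TRUE, only.values = TRUE)$values), 0)
  # controls keep the unperturbed modular covariance (floor changes nothing
  # material)
  expect_lt(max(abs(ctrl - base_covariance(parc))), 1e-8)
})

test_that("sample correlations converge to the specified covariance", {
  parc <- make_parcellation(c(FPN = 10, DMN = 12, Other = 8), seed = 5)
  fx <- effect_spec(
    multipliers = c(VS_UWS = 0, MCS = 0, CONTROL = 0),
    noise_sd = 0,
    nuisance_gain = c(global = 0, wm = 0, csf = 0, motion = 0)
  )
  target <- cov2cor(group_covariance(parc, "CONTROL", fx))
  err <- vapply(c(500, 5000), function(T) {
    rec <- simulate_subject(parc, "CONTROL", fx, T = T, seed = 11)
    norm(cor(t(rec$timeseries)) - target, "F")
  }, 1.0)
  expect_lt(err[2], err[1])
  expect_lt(err[2] / norm(target, "F"), 0.15)
})

test_that("subject simulation honours the scan-length and validity contracts", {
  parc <- make_parcellation(c(FPN = 6, DMN = 6), seed = 4)
  rec <- simulate_subject(parc, "MCS", T = 235, seed = 7)
  expect_equal(dim(rec$timeseries), c(12, 235))
  expect_equal(dim(rec$confounds), c(9, 235))
  expect_true(all(is.finite(rec$timeseries)))
  expect_error(simulate_subject(parc, "MCS", T = 2, seed = 1), "at least 3")
  again <- simulate_subject(parc, "MCS", T = 235, seed = 7)
  expect_identical(rec$timeseries, again$timeseries)
})

test_that("generated series are band-limited to 0.01-0.08 Hz", {
  parc <- make_parcellation(c(FPN = 5, DMN = 5), seed = 6)
  rec <- simulate_subject(parc, "CONTROL", T = 235, seed = 8)
  ts <- rec$timeseries
  fs <- 1 / rec$tr_s
  for (i in c(1, 5, 10)) {
    x <- ts[i, ] - mean(ts[i, ])
    p <- Mod(fft(x))^2
    freq <- (seq_along(x) - 1) * fs / length(x)
    half <- freq <= fs / 2
    in_band <- half & freq >= 0.009 & freq <= 0.085
    expect_gt(sum(p[in_band]) / sum(p[half]), 0.9)
  }
})

test_that("cohort simulation orders, labels and reproduces subjects", {
  parc <- make_parcellation(c(FPN = 6, DMN = 8, Other = 6), seed = 2)
  co <- simulate_cohort(2, 1, 2, parc = parc, T = 40, seed = 31)
  expect_equal(
    as.character(co$groups),
    c("VS_UWS", "VS_UWS", "MCS", "CONTROL", "CONTROL")
  )
  expect_equal(length(co$subjects), 5)
  expect_match(co$subjects[[1]]$subject_id, "VS")
  co2 <- simulate_cohort(2, 1, 2, parc = parc, T = 40, seed = 31)
  expect_identical(co$subjects[[4]]$timeseries, co2$subjects[[4]]$timeseries)
  ctrl_only <- simulate_cohort(0, 0, 3, parc = parc, T = 40, seed = 1)
  expect_equal(as.character(unique(ctrl_only$groups)), "CONTROL")
  expect_error(simulate_cohort(0, 0, 0, parc = parc), "empty cohort")
})

test_that("planted effects shift within-network Fisher z in the stated directions", {
  parc <- make_parcellation(seed = 12)
  D <- distance_matrix(parc)
  fpn <- parc$network == "FPN"
  dmn <- parc$network == "DMN"
  fpn_long <- D[fpn, fpn] > 75 & upper.tri(D[fpn, fpn])
  dmn_short <- D[dmn, dmn] < 40 & upper.tri(D[dmn, dmn])
  n_rep <- 10
  fpn_up <- dmn_down <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    zs <- lapply(c("VS_UWS", "CONTROL"), function(g) {
      rec <- simulate_subject(
        parc, g,
        seed = 1000 * r + (g == "VS_UWS")
      )
      preprocess_subject(rec)$z
    })
    fpn_up[r] <- mean(zs[[1]][fpn, fpn][fpn_long]) >
      mean(zs[[2]][fpn, fpn][fpn_long])
    dmn_down[r] <- mean(zs[[1]][dmn, dmn][dmn_short]) <
      mean(zs[[2]][dmn, dmn][dmn_short])
  }
  expect_gte(mean(fpn_up), 0.9)
  expect_gte(mean(dmn_down), 0.9)
})
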