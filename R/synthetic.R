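#' Default 10-network partition sizes for a 264-node parcellation
#'
#' Node counts per functional network for the synthetic parcellation,
#' mirroring the published 264-region functional atlas as grouped into ten
#' large-scale networks: 25 fronto-parietal (FPN) and 58 default-mode (DMN)
#' nodes, with the remaining regions distributed over visual, somatomotor,
#' cingulo-opercular, auditory, salience, dorsal/ventral attention and a
#' residual (subcortical/cerebellar/unassigned) network.
#'
#' @return Named integer vector of length 10 summing to 264.
#' @export
power264_network_sizes <- function() {
  c(
    Visual = 31L, SMN = 35L, CON = 14L, AUD = 13L, SAL = 18L,
    FPN = 25L, DMN = 58L, DAN = 11L, VAN = 9L, Other = 50L
  )
}

# Spatial layout of network cluster centres (mm, MNI-like axes). Networks can
# have one or two lobes; the FPN is deliberately two distant lobes
# (frontal/parietal) so that long-range (>75 mm) within-FPN node pairs exist,
# while the DMN is a single compact midline cluster so that within-DMN pairs
# are predominantly short-range (<40 mm). The residual network gets a wider
# spread multiplier (subcortical + cerebellar territory).
network_layout <- function() {
  list(
    Visual = list(centres = matrix(c(0, -72, 0), 1), spread_mult = 1),
    SMN = list(
      centres = rbind(c(-30, -21, 51), c(30, -21, 51)),
      spread_mult = 1
    ),
    CON = list(centres = matrix(c(0, 13, 26), 1), spread_mult = 1),
    AUD = list(
      centres = rbind(c(-47, -21, 9), c(47, -21, 9)),
      spread_mult = 1
    ),
    SAL = list(centres = matrix(c(0, 17, -4), 1), spread_mult = 1),
    FPN = list(
      centres = rbind(c(-38, 34, 21), c(38, -47, 38)),
      spread_mult = 1
    ),
    DMN = list(centres = matrix(c(0, -47, 21), 1), spread_mult = 1),
    DAN = list(centres = matrix(c(0, -51, 47), 1), spread_mult = 1),
    VAN = list(centres = matrix(c(43, 9, 4), 1), spread_mult = 1),
    Other = list(centres = matrix(c(0, -17, -17), 1), spread_mult = 1.6)
  )
}

# deterministic fallback centres for networks outside the built-in layout:
# golden-angle spiral on a 55 mm sphere
fallback_centre <- function(index) {
  phi <- (1 + sqrt(5)) / 2
  zi <- 1 - 2 * ((index - 0.5) / max(index, 8))
  zi <- max(min(zi, 0.99), -0.99)
  theta <- 2 * pi * index / phi
  r <- sqrt(1 - zi^2)
  55 * c(r * cos(theta), r * sin(theta), zi)
}

#' Generate a synthetic spatially embedded parcellation
#'
#' Places one Gaussian spatial cluster per network lobe so that inter-node
#' Euclidean distances span roughly 0-175 mm. Node offsets are clamped to
#' 2.5 standard deviations of the cluster spread, which (with the built-in
#' cluster layout) bounds every pairwise distance below 180 mm, the upper
#' edge of the distance-profile binning.
#'
#' @param network_sizes Named integer vector mapping network name to node
#'   count; defaults to the 10-network, 264-node partition of
#'   [power264_network_sizes()].
#' @param spread_mm Gaussian cluster spread (standard deviation, mm).
#' @param seed Integer seed; the layout is deterministic given the seed.
#' @return A `parcellation`: data.frame with columns `node_id`, `label`,
#'   `x_mm`, `y_mm`, `z_mm`, `network`.
#' @examples
#' parc <- make_parcellation(c(FPN = 5, DMN = 8), seed = 1)
#' table(parc$network)
#' @export
make_parcellation <- function(network_sizes = power264_network_sizes(),
                              spread_mm = 12, seed = 1) {
  if (length(network_sizes) < 1 || is.null(names(network_sizes)) ||
    any(!nzchar(names(network_sizes)))) {
    stopf("invalid partition: network_sizes must be a named vector")
  }
  if (any(network_sizes <= 0)) {
    stopf("invalid partition: all network counts must be positive")
  }
  if (!is.numeric(spread_mm) || spread_mm <= 0) {
    stopf("spread_mm must be a positive number")
  }
  layout <- network_layout()
  nets <- names(network_sizes)
  rows <- vector("list", length(nets))
  with_seed(seed, {
    fallback_i <- 0
    for (ni in seq_along(nets)) {
      net <- nets[ni]
      n <- as.integer(network_sizes[ni])
      if (net %in% names(layout)) {
        centres <- layout[[net]]$centres
        smult <- layout[[net]]$spread_mult
      } else {
        fallback_i <- fallback_i + 1
        centres <- matrix(fallback_centre(fallback_i), 1)
        smult <- 1
      }
      n_lobes <- nrow(centres)
      lobe_sizes <- diff(round(seq(0, n, length.out = n_lobes + 1)))
      lobe <- rep(seq_len(n_lobes), lobe_sizes)
      sdv <- spread_mm * smult
      offs <- matrix(rnorm(3 * n, 0, sdv), n, 3)
      rad <- sqrt(rowSums(offs^2))
      too_far <- rad > 2.5 * sdv
      if (any(too_far)) {
        offs[too_far, ] <- offs[too_far, ] * (2.5 * sdv / rad[too_far])
      }
      xyz <- centres[lobe, , drop = FALSE] + offs
      rows[[ni]] <- data.frame(
        label = sprintf("%s_%02d", net, seq_len(n)),
        x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
        network = net, stringsAsFactors = FALSE
      )
    }
  })
  parc <- do.call(rbind, rows)
  parc <- cbind(node_id = seq_len(nrow(parc)), parc)
  rownames(parc) <- NULL
  # hard guard: keep every pairwise distance inside the 0-180 mm bin range
  D <- as.matrix(stats::dist(parc[, c("x_mm", "y_mm", "z_mm")]))
  dmax <- max(D)
  if (dmax > 179) {
    ctr <- colMeans(parc[, c("x_mm", "y_mm", "z_mm")])
    sc <- 175 / dmax
    for (cc in c("x_mm", "y_mm", "z_mm")) {
      parc[[cc]] <- ctr[[cc]] + (parc[[cc]] - ctr[[cc]]) * sc
    }
  }
  class(parc) <- c("parcellation", "data.frame")
  parc
}

#' Specify the planted group effects of the synthetic cohort
#'
#' Encodes the direction and magnitude of the group-dependent covariance
#' alterations the generator plants: a gain on long-range (>75 mm)
#' within-FPN node-pair correlations and a loss on short-range within-DMN
#' pair correlations, each scaled by a per-group multiplier. Defaults give
#' +/-0.15 correlation units for VS/UWS and +/-0.08 for MCS (monotone
#' ordering VS > MCS > control); controls are unperturbed by construction.
#'
#' @param fpn_long_gain Additive correlation gain on within-FPN pairs with
#'   inter-node distance above `long_threshold_mm`.
#' @param dmn_short_loss Additive correlation loss (subtracted) on
#'   within-DMN pairs below `long_threshold_mm`.
#' @param multipliers Named per-group multipliers; `CONTROL` must be 0.
#' @param noise_sd Standard deviation of additive white observation noise
#'   (applied before band-pass filtering; signals have unit variance).
#' @param long_threshold_mm Distance separating short from long connections.
#' @param nuisance_gain Named gains of the shared nuisance components added
#'   to every node: global fluctuation, white-matter and CSF signals, and
#'   node-specific motion coupling.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(fpn_long_gain = 0.15, dmn_short_loss = 0.15,
                        multipliers = c(VS_UWS = 1, MCS = 8 / 15, CONTROL = 0),
                        noise_sd = 0.2, long_threshold_mm = 75,
                        nuisance_gain = c(
                          global = 0.4, wm = 0.3,
                          csf = 0.2, motion = 0.1
                        )) {
  if (!all(GROUP_LEVELS %in% names(multipliers))) {
    stopf(
      "multipliers must name all groups: %s",
      paste(GROUP_LEVELS, collapse = ", ")
    )
  }
  if (multipliers[["CONTROL"]] != 0) {
    stopf("the CONTROL multiplier must be 0 (controls are unperturbed)")
  }
  structure(
    list(
      fpn_long_gain = fpn_long_gain, dmn_short_loss = dmn_short_loss,
      multipliers = multipliers[GROUP_LEVELS], noise_sd = noise_sd,
      long_threshold_mm = long_threshold_mm, nuisance_gain = nuisance_gain
    ),
    class = "effect_spec"
  )
}

#' Base modular covariance of the synthetic cohort
#'
#' Unit variances, within-network pairwise correlation `within`,
#' between-network correlation `between`. These defaults produce admissible
#' density ranges and small-world thresholded graphs comparable to empirical
#' resting-state data.
#'
#' @param parc A [make_parcellation()] parcellation.
#' @param within,between Within/between-network pairwise correlations.
#' @return K x K covariance matrix.
#' @export
base_covariance <- function(parc, within = 0.3, between = 0.05) {
  same <- outer(parc$network, parc$network, "==")
  sigma <- ifelse(same, within, between)
  diag(sigma) <- 1
  sigma
}

#' Group covariance with planted distance-dependent FPN/DMN effects
#'
#' Adds the [effect_spec()] perturbations for `group` to the base covariance:
#' `+fpn_long_gain * multiplier` on within-FPN pairs beyond the distance
#' threshold and `-dmn_short_loss * multiplier` on within-DMN pairs below it.
#' Positive definiteness is enforced by flooring eigenvalues at 1e-6 and
#' re-symmetrizing.
#'
#' @inheritParams base_covariance
#' @param group One of `"VS_UWS"`, `"MCS"`, `"CONTROL"`.
#' @param fx An [effect_spec()].
#' @return K x K symmetric positive-definite covariance matrix.
#' @export
group_covariance <- function(parc, group, fx = effect_spec(),
                             within = 0.3, between = 0.05) {
  group <- match.arg(group, GROUP_LEVELS)
  sigma <- base_covariance(parc, within, between)
  mult <- fx$multipliers[[group]]
  if (mult != 0) {
    D <- distance_matrix(parc)
    fpn <- parc$network == "FPN"
    dmn <- parc$network == "DMN"
    long <- D > fx$long_threshold_mm
    pert <- matrix(0, nrow(sigma), ncol(sigma))
    pert[fpn, fpn] <- pert[fpn, fpn] + fx$fpn_long_gain * mult *
      long[fpn, fpn]
    pert[dmn, dmn] <- pert[dmn, dmn] - fx$dmn_short_loss * mult *
      (!long[dmn, dmn])
    diag(pert) <- 0
    sigma <- sigma + pert
  }
  ed <- eigen(sigma, symmetric = TRUE)
  floored <- pmax(ed$values, 1e-6)
  sigma <- ed$vectors %*% (floored * t(ed$vectors))
  sigma <- (sigma + t(sigma)) / 2
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stopf("covariance generation failed: not positive definite after flooring")
  }
  sigma
}

# band-limited unit-variance nuisance channel
band_noise <- function(T, tr_s) {
  x <- bandpass_timeseries(matrix(rnorm(T), 1), tr_s = tr_s)[1, ]
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

#' Simulate one subject's nodal time series
#'
#' Draws `T` samples from a zero-mean multivariate Gaussian with the group's
#' planted covariance, adds white observation noise, band-limits every node
#' series to 0.01-0.08 Hz at the repetition time `tr_s`, and adds shared
#' nuisance components (global fluctuation, white-matter and CSF signals,
#' and node-specific motion coupling) together with the corresponding
#' confound channels (global, WM, CSF, six motion channels).
#'
#' @inheritParams group_covariance
#' @param T Number of time points (default 235, i.e. 240 volumes with the
#'   first five discarded at TR = 2 s).
#' @param seed Integer seed.
#' @param tr_s Repetition time in seconds.
#' @param subject_id Subject identifier string.
#' @param within,between Base within/between-network correlations (see
#'   [base_covariance()]).
#' @param cov_eig Optional pre-computed eigen decomposition of the group
#'   covariance (as returned by `eigen(, symmetric = TRUE)`), used by
#'   [simulate_cohort()] to avoid refactorizing per subject.
#' @return A `subject_record`: list with `subject_id`, `group`,
#'   `timeseries` (K x T) and `confounds` (9 x T).
#' @export
simulate_subject <- function(parc, group, fx = effect_spec(), T = 235,
                             seed = 1, tr_s = 2, subject_id = "sub-01",
                             cov_eig = NULL, within = 0.3, between = 0.05) {
  group <- match.arg(group, GROUP_LEVELS)
  if (!is.numeric(T) || T < 3) stopf("T must be at least 3 time points")
  K <- nrow(parc)
  if (is.null(cov_eig)) {
    cov_eig <- eigen(
      group_covariance(parc, group, fx, within, between),
      symmetric = TRUE
    )
  }
  lam <- pmax(cov_eig$values, 0)
  with_seed(seed, {
    z <- matrix(rnorm(K * T), K, T)
    ts <- cov_eig$vectors %*% (sqrt(lam) * z)
    if (fx$noise_sd > 0) ts <- ts + matrix(rnorm(K * T, 0, fx$noise_sd), K, T)
    ts <- bandpass_timeseries(ts, tr_s = tr_s)
    gl <- band_noise(T, tr_s)
    wm <- band_noise(T, tr_s)
    csf <- band_noise(T, tr_s)
    motion <- t(apply(matrix(rnorm(6 * T, 0, 0.1), 6, T), 1, cumsum))
    g <- fx$nuisance_gain
    ts <- ts + rep(1, K) %o% (g[["global"]] * gl + g[["wm"]] * wm +
      g[["csf"]] * csf)
    ts <- ts + matrix(rnorm(K * 6, 0, g[["motion"]]), K, 6) %*% motion
    confounds <- rbind(global = colMeans(ts), wm = wm, csf = csf, motion)
    rownames(confounds) <- c(
      "global", "wm", "csf", paste0("motion", 1:6)
    )
    rownames(ts) <- parc$label
    if (any(!is.finite(ts))) stopf("generation error: non-finite time series")
    structure(
      list(
        subject_id = subject_id, group = group,
        timeseries = ts, confounds = confounds, tr_s = tr_s
      ),
      class = "subject_record"
    )
  })
}

#' Simulate a multi-subject cohort
#'
#' Generates `n_vs + n_mcs + n_ctrl` subjects (ordered VS/UWS, MCS, control)
#' with per-subject seeds derived deterministically from the cohort seed.
#' Defaults reproduce the study's group sizes: 11 VS/UWS, 7 MCS and 11
#' controls (29 subjects, 264 nodes, 235 time points at TR = 2 s).
#'
#' @param n_vs,n_mcs,n_ctrl Subjects per group (non-negative).
#' @param parc Parcellation; generated from the cohort seed when `NULL`.
#' @inheritParams simulate_subject
#' @return A `cohort`: list with `parcellation`, `subjects` (list of
#'   `subject_record`), `groups` (factor) and the generator settings.
#' @examples
#' co <- simulate_cohort(2, 2, 2, parc = make_parcellation(c(FPN = 6, DMN = 8)),
#'                       T = 40, seed = 7)
#' table(co$groups)
#' @export
simulate_cohort <- function(n_vs = 11, n_mcs = 7, n_ctrl = 11, parc = NULL,
                            fx = effect_spec(), T = 235, tr_s = 2, seed = 1,
                            within = 0.3, between = 0.05) {
  counts <- c(n_vs, n_mcs, n_ctrl)
  if (any(counts < 0)) stopf("group counts must be non-negative")
  if (sum(counts) == 0) stopf("empty cohort: all group counts are zero")
  if (is.null(parc)) {
    parc <- make_parcellation(seed = derive_seed(seed, "parcellation"))
  }
  groups <- rep(GROUP_LEVELS, counts)
  ids <- sprintf(
    "sub-%s%02d", c("VS", "MCS", "CTRL")[match(groups, GROUP_LEVELS)],
    unlist(lapply(counts, seq_len))
  )
  eigs <- list()
  for (g in unique(groups)) {
    eigs[[g]] <- eigen(
      group_covariance(parc, g, fx, within, between),
      symmetric = TRUE
    )
  }
  subjects <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    subjects[[i]] <- simulate_subject(
      parc, groups[i], fx,
      T = T, seed = derive_seed(seed, "subject", i), tr_s = tr_s,
      subject_id = ids[i], cov_eig = eigs[[groups[i]]]
    )
  }
  structure(
    list(
      parcellation = parc, subjects = subjects,
      groups = factor(groups, levels = GROUP_LEVELS),
      fx = fx, T = T, tr_s = tr_s, seed = seed
    ),
    class = "cohort"
  )
}
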