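#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with validated
#' defaults matching the study conditions: 29 subjects (11 VS/UWS, 7 MCS,
#' 11 controls), 264 nodes in 10 networks, 235 time points at TR = 2 s,
#' 0.01-0.08 Hz band, densities 2.5-32.5% in steps of 2%, 100 rewired
#' nulls, 1000 MVPA permutations and 10000 nodal permutations.
#'
#' @param n_vs,n_mcs,n_ctrl Group sizes for simulation.
#' @param T Time points per subject.
#' @param tr_s Repetition time (s).
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param density_start,density_stop,density_step Density grid.
#' @param n_nulls Rewired null networks per density.
#' @param n_perm_mvpa Label permutations for classification p-values.
#' @param n_perm_nodal Permutations for the nodal test.
#' @param networks Networks whose features feed the classifier.
#' @param fx Planted-effect specification ([effect_spec()]).
#' @param network_sizes,spread_mm Parcellation layout for simulation (see
#'   [make_parcellation()]).
#' @param cov_within,cov_between Base within/between-network correlations
#'   of the simulated covariance (see [base_covariance()]).
#' @param seed Master seed; all stage seeds derive from it.
#' @param input_dir Optional cohort directory (from [write_cohort()]); when
#'   given, simulation is skipped and the cohort is read from disk.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_vs = 11, n_mcs = 7, n_ctrl = 11, T = 235,
                            tr_s = 2, low_hz = 0.01, high_hz = 0.08,
                            density_start = 0.025, density_stop = 0.325,
                            density_step = 0.02, n_nulls = 100,
                            n_perm_mvpa = 1000, n_perm_nodal = 10000,
                            networks = c("FPN", "DMN"), fx = effect_spec(),
                            network_sizes = power264_network_sizes(),
                            spread_mm = 12, cov_within = 0.3,
                            cov_between = 0.05, seed = 1, input_dir = NULL) {
  if (n_nulls < 1 || n_perm_mvpa < 1 || n_perm_nodal < 1) {
    stopf("null and permutation counts must be positive")
  }
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stopf("invalid filter band for TR = %g s", tr_s)
  }
  density_grid(density_start, density_stop, density_step) # validates
  structure(
    list(
      n_vs = n_vs, n_mcs = n_mcs, n_ctrl = n_ctrl, T = T, tr_s = tr_s,
      low_hz = low_hz, high_hz = high_hz, density_start = density_start,
      density_stop = density_stop, density_step = density_step,
      n_nulls = n_nulls, n_perm_mvpa = n_perm_mvpa,
      n_perm_nodal = n_perm_nodal, networks = networks, fx = fx,
      network_sizes = network_sizes, spread_mm = spread_mm,
      cov_within = cov_within, cov_between = cov_between,
      seed = seed, input_dir = input_dir
    ),
    class = "pipeline_config"
  )
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, preprocess to Fisher-z connectivity,
#' threshold across the density grid, compute null-normalized topology with
#' a shared admissible range, profile connectivity by distance, classify
#' conscious state (each configured network alone, the combined set, and
#' the three binary contrasts) and run the group statistics. All stage
#' seeds derive from the master seed, so identical configurations produce
#' identical results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @param verbose Log stage progress?
#' @return A `pipeline_result` list: `cohort`, `connectivity`, `topology`,
#'   `distance`, `classification`, `stats`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  # --- cohort -------------------------------------------------------------
  if (!is.null(config$input_dir)) {
    pipeline_log(verbose, "stage simulate: reading cohort from %s",
      config$input_dir)
    cohort <- read_cohort(config$input_dir)
  } else {
    pipeline_log(
      verbose, "stage simulate: %d VS/UWS + %d MCS + %d controls, T = %d",
      config$n_vs, config$n_mcs, config$n_ctrl, config$T
    )
    parc_sim <- make_parcellation(
      config$network_sizes, config$spread_mm,
      seed = derive_seed(config$seed, "parcellation")
    )
    cohort <- simulate_cohort(
      config$n_vs, config$n_mcs, config$n_ctrl, parc = parc_sim,
      fx = config$fx, T = config$T, tr_s = config$tr_s,
      seed = derive_seed(config$seed, "simulate"),
      within = config$cov_within, between = config$cov_between
    )
  }
  parc <- cohort$parcellation
  groups <- as.character(cohort$groups)
  # --- connectivity -------------------------------------------------------
  pipeline_log(verbose, "stage connectivity: band %g-%g Hz",
    config$low_hz, config$high_hz)
  cons <- lapply(
    cohort$subjects, preprocess_subject,
    low_hz = config$low_hz, high_hz = config$high_hz, tr_s = config$tr_s
  )
  # --- topology -----------------------------------------------------------
  grid <- density_grid(
    config$density_start, config$density_stop, config$density_step
  )
  pipeline_log(verbose, "stage topology: %d densities, %d nulls",
    length(grid$densities), config$n_nulls)
  ctop <- cohort_topology(
    cons, grid, parc,
    n_nulls = config$n_nulls, seed = derive_seed(config$seed, "topology")
  )
  # --- distance profiles --------------------------------------------------
  pipeline_log(verbose, "stage distance: profiling %s",
    paste(config$networks, collapse = ", "))
  distance <- list()
  for (net in config$networks) {
    prof <- cohort_distance_profiles(cons, ctop, parc, net)
    distance[[net]] <- list(
      profiles = prof,
      anova = groupwise_bin_anova(prof, groups)
    )
  }
  # --- classification -----------------------------------------------------
  pipeline_log(verbose, "stage classify: LOOCV + %d permutations",
    config$n_perm_mvpa)
  classification <- list()
  feature_sets <- c(
    as.list(config$networks),
    list(config$networks)
  )
  names(feature_sets) <- c(
    config$networks, paste(config$networks, collapse = "+")
  )
  for (fs in names(feature_sets)) {
    fm <- build_features(ctop, feature_sets[[fs]])
    cls_rep <- loocv_classify(fm$X, fm$y)
    perm <- permutation_pvalue(
      fm$X, fm$y, config$n_perm_mvpa,
      seed = derive_seed(config$seed, "perm", fs)
    )
    cls_rep$permutation_p <- perm$p
    cls_rep$weight_map <- nodal_weight_map(cls_rep$ovr, fm$feature_index)
    classification[[fs]] <- cls_rep
  }
  # binary contrasts on the combined feature set
  combined <- build_features(ctop, config$networks)
  lev <- levels(combined$y)
  for (pair in utils::combn(lev, 2, simplify = FALSE)) {
    sel <- combined$y %in% pair
    if (sum(sel) < 3 || length(unique(combined$y[sel])) < 2) next
    nm <- paste(pair, collapse = "_vs_")
    Xp <- combined$X[sel, , drop = FALSE]
    yp <- droplevels(combined$y[sel])
    cls_rep <- loocv_classify(Xp, yp)
    perm <- permutation_pvalue(
      Xp, yp, config$n_perm_mvpa,
      seed = derive_seed(config$seed, "perm", nm)
    )
    cls_rep$permutation_p <- perm$p
    classification[[nm]] <- cls_rep
  }
  # --- group statistics ---------------------------------------------------
  pipeline_log(verbose, "stage stats: ANOVA, correlations, nodal test")
  stats_out <- list()
  nets <- ctop$networks
  n_sub <- length(cons)
  strength_tab <- ctop$auc_network[, , "strength"]
  stats_out$two_way <- two_way_anova(
    as.vector(strength_tab),
    rep(groups, times = length(nets)),
    rep(nets, each = n_sub)
  )
  for (net in config$networks) {
    stats_out$tukey[[net]] <- tukey_posthoc(strength_tab[, net], groups)
  }
  if (length(config$networks) >= 2) {
    is_pat <- groups != "CONTROL"
    is_ctl <- groups == "CONTROL"
    n1 <- config$networks[1]
    n2 <- config$networks[2]
    if (sum(is_pat) >= 3 && sum(is_ctl) >= 1) {
      stats_out$baseline_correlation <- lapply(
        c(strength = "strength", betweenness = "betweenness",
          degree = "degree"),
        function(m) {
          tryCatch(
            baseline_correlation(
              ctop$auc_network[is_pat, n1, m],
              ctop$auc_network[is_pat, n2, m],
              mean(ctop$auc_network[is_ctl, n1, m]),
              mean(ctop$auc_network[is_ctl, n2, m])
            ),
            error = function(e) list(r = NA_real_, p = NA_real_,
              bonferroni_p = NA_real_, n = sum(is_pat))
          )
        }
      )
    }
  }
  node_sel <- parc$node_id[parc$network %in% config$networks]
  stats_out$nodal <- nodal_permutation_test(
    ctop$auc_nodal[, node_sel, , drop = FALSE], groups,
    n_perm = config$n_perm_nodal,
    seed = derive_seed(config$seed, "nodal")
  )
  result <- structure(
    list(
      cohort = cohort, connectivity = cons, topology = ctop,
      distance = distance, classification = classification,
      stats = stats_out, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# serialize the human-readable slices of a pipeline result
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_parcellation(
    result$cohort$parcellation, file.path(out_dir, "parcellation.tsv")
  )
  cls <- lapply(result$classification, function(r) {
    out <- list(
      accuracy = r$accuracy, chance = r$chance,
      permutation_p = r$permutation_p, per_class = r$per_class,
      predictions = r$predictions, truth = r$truth
    )
    if (!is.null(r$sensitivity)) {
      out$sensitivity <- r$sensitivity
      out$specificity <- r$specificity
      out$positive_class <- r$positive_class
    }
    out
  })
  report <- list(
    admissible_densities =
      result$topology$densities[result$topology$shared_admissible],
    classification = cls,
    two_way_anova = result$stats$two_way,
    baseline_correlation = result$stats$baseline_correlation,
    config = result$config[setdiff(names(result$config), "fx")]
  )
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", dataframe = "rows"
  )
  write.table(
    result$stats$nodal, file.path(out_dir, "nodal_test.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(out_dir)
}
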