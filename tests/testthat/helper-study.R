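# Shared driver for the replicated-cohort checks: simulates a cohort at the
# study conditions (29 subjects: 11 VS/UWS + 7 MCS + 11 controls; 264 nodes
# in 10 networks; 235 time points at TR = 2 s), runs connectivity ->
# thresholding -> null-normalized topology (20 rewired nulls per density) ->
# distance profiles -> classification -> group statistics, and returns the
# summaries the acceptance checks assert on. Results are memoized because
# two acceptance properties draw on the same replicate set.
study_cache <- new.env(parent = emptyenv())

run_study_cohort <- function(cohort_seed, n_nulls = 20) {
  cohort <- simulate_cohort(seed = cohort_seed)
  parc <- cohort$parcellation
  groups <- as.character(cohort$groups)
  cons <- lapply(cohort$subjects, preprocess_subject)
  grid <- density_grid()
  ctop <- cohort_topology(
    cons, grid, parc,
    n_nulls = n_nulls,
    seed = derive_seed(cohort_seed, "topology")
  )
  strength <- ctop$auc_network[, , "strength"]
  tukey_fpn <- tukey_posthoc(strength[, "FPN"], groups)
  tukey_dmn <- tukey_posthoc(strength[, "DMN"], groups)
  pat <- groups != "CONTROL"
  bc <- baseline_correlation(
    strength[pat, "FPN"], strength[pat, "DMN"],
    mean(strength[!pat, "FPN"]), mean(strength[!pat, "DMN"])
  )
  dist_tab <- lapply(c(FPN = "FPN", DMN = "DMN"), function(net) {
    prof <- cohort_distance_profiles(cons, ctop, parc, net)
    suppressWarnings(groupwise_bin_anova(prof, groups)$table)
  })
  accuracies <- vapply(
    list(FPN = "FPN", DMN = "DMN", combined = c("FPN", "DMN")),
    function(nets) {
      fm <- build_features(ctop, nets)
      loocv_classify(fm$X, fm$y)$accuracy
    },
    1.0
  )
  list(
    tukey_fpn = tukey_fpn, tukey_dmn = tukey_dmn,
    baseline_r = bc$r, distance = dist_tab, accuracies = accuracies,
    n_admissible = sum(ctop$shared_admissible)
  )
}

study_cohorts <- function(n = 20) {
  key <- paste0("cohorts_", n)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- lapply(seq_len(n), function(i) {
      run_study_cohort(derive_seed(2024, "study-cohort", i))
    })
  }
  study_cache[[key]]
}

# contrast helper: Tukey row for VS/UWS vs control
vs_ctrl_row <- function(tk) {
  tk[tk$contrast %in% c("VS_UWS-CONTROL", "CONTROL-VS_UWS"), , drop = FALSE]
}

# sign of the VS/UWS minus control difference
vs_minus_ctrl <- function(tk) {
  row <- vs_ctrl_row(tk)
  if (row$contrast == "VS_UWS-CONTROL") row$diff else -row$diff
}
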