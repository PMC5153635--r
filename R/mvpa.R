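#' Build the MVPA feature matrix from cohort topology
#'
#' One row per subject; columns concatenate the three AUC-summarized,
#' null-normalized nodal metrics (strength, betweenness, degree) of every
#' node in the selected networks, in deterministic order: network (as
#' given), then node id ascending, then metric.
#'
#' @param ctop A `cohort_topology`.
#' @param networks Character vector of network names to include.
#' @param use_auc Use the AUC summaries (default); `FALSE` concatenates
#'   per-density normalized values instead.
#' @return A `feature_matrix`: list with `X` (subjects x features), `y`
#'   (group factor) and `feature_index` (data.frame column -> node/metric).
#' @export
build_features <- function(ctop, networks = c("FPN", "DMN"), use_auc = TRUE) {
  parc <- ctop$parcellation
  unknown <- setdiff(networks, parc$network)
  if (length(unknown)) {
    stopf("unknown networks: %s", paste(unknown, collapse = ", "))
  }
  metrics <- c("strength", "betweenness", "degree")
  cols <- list()
  index <- list()
  for (net in networks) {
    for (node in parc$node_id[parc$network == net]) {
      for (m in metrics) {
        if (use_auc) {
          cols[[length(cols) + 1]] <- ctop$auc_nodal[, node, m]
        } else {
          adm <- ctop$shared_admissible
          cols[[length(cols) + 1]] <- t(vapply(
            ctop$profiles,
            function(p) p$norm[[m]][node, adm],
            numeric(sum(adm))
          ))
        }
        index[[length(index) + 1]] <- data.frame(
          network = net, node_id = node, metric = m
        )
      }
    }
  }
  X <- do.call(cbind, cols)
  feature_index <- do.call(rbind, index)
  if (use_auc) {
    feature_index$column <- seq_len(nrow(feature_index))
  }
  if (any(!is.finite(X))) {
    stopf("non-finite feature values; a subject is missing a metric")
  }
  structure(
    list(
      X = X, y = factor(ctop$groups, levels = union(
        intersect(GROUP_LEVELS, ctop$groups), unique(ctop$groups)
      )),
      feature_index = feature_index
    ),
    class = "feature_matrix"
  )
}

# oriented linear SVM hyperplane: returns (w, b) such that score = Xw + b is
# positive for `positive` (e1071's decision-value sign follows its internal
# label order, recovered from the decision-value column name)
svm_linear_hyperplane <- function(fit, X, positive) {
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dv <- attr(
    stats::predict(fit, X[1, , drop = FALSE], decision.values = TRUE),
    "decision.values"
  )
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (!identical(first, positive)) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Train one-vs-rest linear SVM classifiers
#'
#' One linear support-vector machine per class (regularization `C_reg`),
#' each separating the class from all others. Features are expected to be
#' standardized by the caller (LOOCV standardizes with training-fold
#' statistics).
#'
#' @param X Numeric matrix, subjects x features.
#' @param y Class labels (2 or more classes, each present).
#' @param C_reg SVM cost parameter.
#' @return An `ovr_classifiers` list: per-class weight matrix `W` (classes x
#'   features), intercepts `b`, class `levels`.
#' @export
train_ovr <- function(X, y, C_reg = 1) {
  y <- factor(y)
  if (any(table(y) < 1) || nlevels(y) < 2) {
    stopf("every class needs at least one training subject")
  }
  lev <- levels(y)
  W <- matrix(0, length(lev), ncol(X), dimnames = list(lev, NULL))
  b <- numeric(length(lev))
  if (length(lev) == 2) {
    # two-class one-vs-rest: the second hyperplane is the first one's mirror
    ybin <- factor(
      ifelse(y == lev[1], lev[1], ".rest"),
      levels = c(lev[1], ".rest")
    )
    fit <- e1071::svm(
      x = X, y = ybin, kernel = "linear", cost = C_reg, scale = FALSE
    )
    hp <- svm_linear_hyperplane(fit, X, lev[1])
    W[1, ] <- hp$w
    b[1] <- hp$b
    W[2, ] <- -hp$w
    b[2] <- -hp$b
    return(structure(
      list(W = W, b = b, levels = lev),
      class = "ovr_classifiers"
    ))
  }
  for (ci in seq_along(lev)) {
    ybin <- factor(
      ifelse(y == lev[ci], lev[ci], ".rest"),
      levels = c(lev[ci], ".rest")
    )
    fit <- e1071::svm(
      x = X, y = ybin, kernel = "linear", cost = C_reg, scale = FALSE
    )
    hp <- svm_linear_hyperplane(fit, X, lev[ci])
    W[ci, ] <- hp$w
    b[ci] <- hp$b
  }
  structure(list(W = W, b = b, levels = lev), class = "ovr_classifiers")
}

ovr_scores <- function(ovr, x) {
  drop(ovr$W %*% x) + ovr$b
}

#' Loss-based decoding: assign the class with the maximal score
#'
#' @param scores Numeric vector of per-class decision scores.
#' @return Index of the winning class (ties break to the lowest index).
#' @export
decode_scores <- function(scores) {
  if (any(!is.finite(scores))) stopf("non-finite classifier score")
  which.max(scores)
}

# z-score columns with given stats; zero-variance columns map to 0
standardize_cols <- function(X, center, scale) {
  scale[scale < 1e-12] <- Inf
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Leave-one-out cross-validated one-vs-rest classification
#'
#' Each subject is held out in turn; the remaining subjects train the
#' one-vs-rest linear SVMs (features z-scored with training-fold mean/SD)
#' and the held-out subject receives the label with the maximal decision
#' score. For binary problems, sensitivity is the proportion of the
#' positive class correctly classified and specificity that of the other
#' class; by convention the positive class is the more severely impaired
#' group (VS/UWS before MCS before control).
#'
#' @param X Numeric matrix, subjects x features.
#' @param y Class labels.
#' @param C_reg SVM cost parameter.
#' @param standardize Z-score features per training fold?
#' @param positive_class Positive class for sensitivity (binary runs).
#' @return A `classification_report`: predictions, accuracy (%), per-class
#'   tallies, sensitivity/specificity (%, binary only), and the nodal
#'   weight map machinery inputs (`ovr` trained on the full sample).
#' @export
loocv_classify <- function(X, y, C_reg = 1, standardize = TRUE,
                           positive_class = NULL) {
  y <- factor(y)
  n <- nrow(X)
  if (n < 3) stopf("LOOCV needs at least 3 subjects")
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < nlevels(y)) {
      stopf("a class is absent from the training fold for subject %d", i)
    }
    if (standardize) {
      ctr <- colMeans(Xtr)
      scl <- apply(Xtr, 2, sd)
      Xtr <- standardize_cols(Xtr, ctr, scl)
      xte <- drop(standardize_cols(X[i, , drop = FALSE], ctr, scl))
    } else {
      xte <- X[i, ]
    }
    ovr <- train_ovr(Xtr, ytr, C_reg)
    pred[i] <- ovr$levels[decode_scores(ovr_scores(ovr, xte))]
  }
  correct <- pred == as.character(y)
  lev <- levels(y)
  per_class <- data.frame(
    class = lev,
    correct = vapply(lev, function(l) sum(correct[y == l]), 1L),
    total = vapply(lev, function(l) sum(y == l), 1L),
    row.names = NULL
  )
  report <- list(
    predictions = pred, truth = as.character(y),
    accuracy = 100 * mean(correct), per_class = per_class,
    chance = 100 / nlevels(y)
  )
  if (nlevels(y) == 2) {
    if (is.null(positive_class)) {
      sev <- intersect(GROUP_LEVELS, lev)
      positive_class <- if (length(sev)) sev[1] else lev[1]
    }
    pos <- per_class[per_class$class == positive_class, ]
    neg <- per_class[per_class$class != positive_class, ]
    report$positive_class <- positive_class
    report$sensitivity <- 100 * pos$correct / pos$total
    report$specificity <- 100 * neg$correct / neg$total
  }
  # full-sample classifiers for the nodal weight map
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    Xf <- standardize_cols(X, ctr, scl)
  } else {
    Xf <- X
  }
  report$ovr <- train_ovr(Xf, y, C_reg)
  structure(report, class = "classification_report")
}

#' Permutation p-value of the LOOCV accuracy
#'
#' Group labels are permuted once per iteration and the full LOOCV is
#' re-run; the p-value is the proportion of null accuracies greater than or
#' equal to the actual accuracy.
#'
#' @inheritParams loocv_classify
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `p`, `accuracy` (actual, %), `null_accuracies`.
#' @export
permutation_pvalue <- function(X, y, n_perm = 1000, seed = 1, C_reg = 1,
                               standardize = TRUE) {
  if (n_perm < 1) stopf("n_perm must be at least 1")
  actual <- loocv_classify(X, y, C_reg, standardize)$accuracy
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      yp <- sample(y)
      loocv_classify(X, yp, C_reg, standardize)$accuracy
    }, 1.0)
  })
  list(
    p = mean(null_acc >= actual - 1e-9),
    accuracy = actual, null_accuracies = null_acc
  )
}

#' Bookkeeping: overall accuracy from per-class correct counts
#'
#' @param correct,total Integer vectors of per-class correct predictions
#'   and class sizes.
#' @return Accuracy in percent.
#' @examples
#' accuracy_from_counts(c(9, 4, 6), c(11, 7, 11)) # 65.5%
#' @export
accuracy_from_counts <- function(correct, total) {
  if (length(correct) != length(total) || any(correct > total)) {
    stopf("invalid per-class counts")
  }
  100 * sum(correct) / sum(total)
}

#' Bookkeeping: binary accuracy from sensitivity/specificity
#'
#' The exact identity `accuracy = (sens * n_pos + spec * n_neg) /
#' (n_pos + n_neg)` with rates in percent.
#'
#' @param sensitivity,specificity Rates in percent.
#' @param n_pos,n_neg Class sizes.
#' @return Accuracy in percent.
#' @export
binary_accuracy_from_rates <- function(sensitivity, specificity,
                                       n_pos, n_neg) {
  (sensitivity * n_pos + specificity * n_neg) / (n_pos + n_neg)
}

#' Per-node SVM weight map
#'
#' Sums each node's feature weights (its three topological metrics) across
#' the one-vs-rest classifiers. Under the default convention the signed sum
#' is taken first and its absolute value reported; the alternative reading
#' sums absolute weights (`convention = "abs_then_sum"`).
#'
#' @param ovr An `ovr_classifiers` object (weights in standardized feature
#'   space).
#' @param feature_index The `feature_index` of the [build_features()]
#'   matrix the classifiers were trained on.
#' @param convention `"sum_then_abs"` (default) or `"abs_then_sum"`.
#' @return Named numeric vector, one non-negative weight per node.
#' @export
nodal_weight_map <- function(ovr, feature_index,
                             convention = c("sum_then_abs", "abs_then_sum")) {
  convention <- match.arg(convention)
  if (ncol(ovr$W) != nrow(feature_index)) {
    stopf("feature index does not match classifier weight dimension")
  }
  nodes <- unique(feature_index$node_id)
  out <- vapply(nodes, function(nd) {
    cols <- which(feature_index$node_id == nd)
    w <- ovr$W[, cols, drop = FALSE]
    if (convention == "sum_then_abs") abs(sum(w)) else sum(abs(w))
  }, 1.0)
  names(out) <- nodes
  out
}
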