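#' Remove per-node linear trends
#'
#' Removes the least-squares line (intercept + slope against the time index)
#' from each row; the output is orthogonal to both the constant and the
#' linear regressor.
#'
#' @param ts Numeric matrix, nodes x timepoints.
#' @return Detrended matrix of the same shape.
#' @export
detrend_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  T <- ncol(ts)
  if (T < 3) stopf("insufficient samples: detrending needs T >= 3, got %d", T)
  Q <- qr.Q(qr(cbind(1, seq_len(T))))
  ts - (ts %*% Q) %*% t(Q)
}

#' Zero-phase Chebyshev band-pass filter
#'
#' Type I Chebyshev filter, order 4 with 0.5 dB passband ripple, applied
#' forward and backward ([signal::filtfilt()]) for zero phase distortion.
#' Defaults select the 0.01-0.08 Hz band customary for resting-state BOLD
#' fluctuations at a repetition time of 2 s.
#'
#' @param ts Numeric matrix, nodes x timepoints.
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low < high < 1/(2 * tr_s)`.
#' @param tr_s Sampling interval (repetition time) in seconds.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_timeseries <- function(ts, low_hz = 0.01, high_hz = 0.08, tr_s = 2) {
  ts <- as.matrix(ts)
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stopf(
      "invalid band: need 0 < low < high < Nyquist (%.4g Hz), got [%g, %g]",
      nyq, low_hz, high_hz
    )
  }
  bf <- signal::cheby1(4, 0.5, c(low_hz, high_hz) / nyq, type = "pass")
  filtfilt_rows(bf$b, bf$a, ts)
}

# Zero-phase filtering of every row at once: the same pad/forward/reverse
# scheme as signal::filtfilt (zero-pad by 2 * filter length, filter, filter
# the reversal, truncate), with the direct-form-II-transposed recursion
# vectorized across rows.
filtfilt_rows <- function(b, a, ts) {
  T <- ncol(ts)
  pad <- 2 * max(length(a), length(b))
  y <- filter_rows(b, a, cbind(ts, matrix(0, nrow(ts), pad)))
  y <- filter_rows(b, a, y[, rev(seq_len(T + pad)), drop = FALSE])
  y[, rev(seq_len(T + pad)), drop = FALSE][, seq_len(T), drop = FALSE]
}

filter_rows <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  na <- length(a)
  T <- ncol(x)
  y <- matrix(0, nrow(x), T)
  for (t in seq_len(T)) {
    acc <- b[1] * x[, t]
    if (nb > 1 && t > 1) {
      for (k in 2:min(nb, t)) acc <- acc + b[k] * x[, t - k + 1]
    }
    if (na > 1 && t > 1) {
      for (k in 2:min(na, t)) acc <- acc - a[k] * y[, t - k + 1]
    }
    y[, t] <- acc
  }
  y
}

# backward-difference derivative, first element 0
backward_diff <- function(x) c(0, diff(x))

#' Regress nuisance confounds out of nodal time series
#'
#' Ordinary-least-squares residuals of each node series against an intercept,
#' all confound channels and (optionally) the backward-difference first
#' derivatives of the channels named in `deriv_channels`. Residuals are
#' orthogonal to every design column.
#'
#' @param ts Numeric matrix, nodes x timepoints.
#' @param confounds Numeric matrix, channels x timepoints, with rownames
#'   identifying the channels.
#' @param add_derivatives Add first-derivative terms of the
#'   global/white-matter/CSF channels (the conventional expansion)?
#' @param deriv_channels Channel names whose derivatives are added.
#' @return Residual matrix, nodes x timepoints.
#' @export
regress_confounds <- function(ts, confounds, add_derivatives = TRUE,
                              deriv_channels = c("global", "wm", "csf")) {
  ts <- as.matrix(ts)
  confounds <- as.matrix(confounds)
  if (ncol(confounds) != ncol(ts)) {
    stopf(
      "confound length mismatch: %d channels x %d timepoints vs T = %d",
      nrow(confounds), ncol(confounds), ncol(ts)
    )
  }
  if (is.null(rownames(confounds))) {
    rownames(confounds) <- paste0("channel", seq_len(nrow(confounds)))
  }
  X <- cbind(intercept = 1, t(confounds))
  if (add_derivatives) {
    dch <- intersect(deriv_channels, rownames(confounds))
    if (length(dch)) {
      D <- apply(confounds[dch, , drop = FALSE], 1, backward_diff)
      colnames(D) <- paste0("d_", dch)
      X <- cbind(X, D)
    }
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf(
      "collinear confound design; offending columns: %s",
      paste(bad, collapse = ", ")
    )
  }
  Q <- qr.Q(qx)
  ts - (ts %*% Q) %*% t(Q)
}

#' Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations between node time series, Fisher
#' z-transformed (`atanh`), with correlations clamped to `|r| <= 1 - 1e-15`
#' so perfectly correlated rows map to a large finite z rather than
#' infinity. The diagonal is fixed at zero.
#'
#' @param ts Numeric matrix, nodes x timepoints; every row must have
#'   nonzero variance.
#' @param subject_id,group Optional identifiers carried in the result.
#' @return A `connectivity_matrix`: list with the symmetric K x K matrix
#'   `z`, `subject_id` and `group`.
#' @examples
#' ts <- matrix(rnorm(40), 4)
#' C <- connectivity_matrix(ts)
#' all(abs(C$z - t(C$z)) == 0)
#' @export
connectivity_matrix <- function(ts, subject_id = NA_character_,
                                group = NA_character_) {
  ts <- as.matrix(ts)
  v <- apply(ts, 1, var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- which(v <= 0 | !is.finite(v))
    ids <- if (!is.null(rownames(ts))) rownames(ts)[bad] else bad
    stopf(
      "degenerate nodes with zero variance: %s",
      paste(ids, collapse = ", ")
    )
  }
  r <- cor(t(ts))
  clamp <- 1 - 1e-15
  r[r > clamp] <- clamp
  r[r < -clamp] <- -clamp
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  structure(
    list(z = z, subject_id = subject_id, group = group),
    class = "connectivity_matrix"
  )
}

#' Preprocess a subject into a Fisher-z connectivity matrix
#'
#' Runs the nodal-series pipeline in fixed order: linear detrend, Chebyshev
#' band-pass, confound regression (with derivative terms), Pearson
#' correlation and Fisher z transform.
#'
#' @param record A `subject_record` (see [simulate_subject()]), or any list
#'   with `timeseries`, `confounds`, `subject_id`, `group`.
#' @inheritParams bandpass_timeseries
#' @inheritParams regress_confounds
#' @return A `connectivity_matrix`.
#' @export
preprocess_subject <- function(record, low_hz = 0.01, high_hz = 0.08,
                               tr_s = NULL, add_derivatives = TRUE) {
  if (is.null(tr_s)) tr_s <- if (!is.null(record$tr_s)) record$tr_s else 2
  ts <- detrend_timeseries(record$timeseries)
  ts <- bandpass_timeseries(ts, low_hz, high_hz, tr_s)
  ts <- regress_confounds(ts, record$confounds, add_derivatives)
  connectivity_matrix(ts, record$subject_id, record$group)
}
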