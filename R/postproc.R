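#' Remove polynomial trends from component time courses
#'
#' Removes, per component, the least-squares polynomial fit (including the
#' intercept) of the given order.  Residuals are orthogonal to the
#' polynomial basis.
#'
#' @param tc a [component_tc] object.
#' @param order polynomial order, one of 1 (linear), 2 (quadratic) or
#'   3 (cubic; the default removes linear, quadratic and cubic trends).
#' @return A [component_tc] with detrended columns.
#' @export
detrend_polynomial <- function(tc, order = 3L) {
  stopifnot(inherits(tc, "component_tc"))
  order <- as.integer(order)
  if (!order %in% 1:3)
    stop("detrend_polynomial: order must be 1, 2 or 3")
  n <- nrow(tc$data)
  if (n <= order + 1L)
    stop("detrend_polynomial: need T > order + 1 (T = ", n, ", order = ",
         order, ")")
  basis <- cbind(1, stats::poly(seq_len(n), degree = order))
  res <- qr.resid(qr(basis), tc$data)
  out <- tc
  out$data <- res
  colnames(out$data) <- tc$component_names
  out
}

#' Regress nuisance signals out of component time courses
#'
#' Regresses each component on the supplied nuisance regressors (for example
#' the six rigid-body realignment parameters), optionally augmented with
#' their temporal derivatives (backward first difference with a leading
#' zero), plus an intercept.  Residuals are orthogonal to all regressors.
#'
#' @param tc a [component_tc] object.
#' @param regressors numeric `T x R` matrix of nuisance signals.
#' @param include_derivatives add first-difference derivatives of each
#'   regressor (default `TRUE`).
#' @return A [component_tc] of residuals.
#' @export
regress_nuisance <- function(tc, regressors, include_derivatives = TRUE) {
  stopifnot(inherits(tc, "component_tc"))
  regressors <- as.matrix(regressors)
  n <- nrow(tc$data)
  if (nrow(regressors) != n)
    stop("regress_nuisance: regressors have ", nrow(regressors),
         " rows but the time courses have ", n)
  if (is.null(colnames(regressors)))
    colnames(regressors) <- sprintf("reg%d", seq_len(ncol(regressors)))
  X <- regressors
  if (include_derivatives) {
    D <- rbind(0, diff(regressors))
    colnames(D) <- paste0("d_", colnames(regressors))
    X <- cbind(X, D)
  }
  X <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("regress_nuisance: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  out <- tc
  out$data <- qr.resid(qx, tc$data)
  colnames(out$data) <- tc$component_names
  out
}

#' Replace outlier spikes by a running median
#'
#' A point whose deviation from the column's running median exceeds
#' `z_threshold` robust standard deviations (1.4826 x MAD of the
#' deviations) is replaced by the running median; all other points are
#' unchanged.  Columns with zero MAD (for example a constant column with a
#' single spike) fall back to replacing any point that deviates at all.
#'
#' @param tc a [component_tc] object.
#' @param z_threshold robust z-score threshold (default 4).
#' @param half_width half-width of the running-median window (default 5, a
#'   window of 11 points).
#' @return A despiked [component_tc].
#' @export
despike <- function(tc, z_threshold = 4, half_width = 5L) {
  stopifnot(inherits(tc, "component_tc"))
  half_width <- as.integer(half_width)
  if (half_width < 1L) stop("despike: half_width must be >= 1")
  n <- nrow(tc$data)
  k <- 2L * half_width + 1L
  if (n <= k)
    stop("despike: need T > ", k, " time points (got ", n, ")")
  out <- tc
  out$data <- apply(tc$data, 2L, function(x) {
    med <- stats::runmed(x, k = k, endrule = "median")
    dev <- x - med
    s <- stats::mad(dev)
    spikes <- if (s > 0) abs(dev) > z_threshold * s else abs(dev) > 0
    x[spikes] <- med[spikes]
    x
  })
  colnames(out$data) <- tc$component_names
  out
}

#' Zero-phase low-pass filter component time courses
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (zero-phase) to every column, so timing of connectivity windows is
#' preserved.
#'
#' @param tc a [component_tc] object.
#' @param cutoff_hz cut-off frequency in Hz (default 0.15); must be below
#'   the Nyquist frequency `1 / (2 * tr_seconds)`.
#' @param order filter order (default 5).
#' @return A filtered [component_tc].
#' @export
lowpass_filter <- function(tc, cutoff_hz = 0.15, order = 5L) {
  stopifnot(inherits(tc, "component_tc"))
  nyquist <- 1 / (2 * tc$tr_seconds)
  if (cutoff_hz >= nyquist)
    stop("lowpass_filter: cutoff ", cutoff_hz, " Hz is at or above Nyquist ",
         signif(nyquist, 4), " Hz for TR = ", tc$tr_seconds, " s")
  if (cutoff_hz <= 0) stop("lowpass_filter: cutoff must be positive")
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  n <- nrow(tc$data)
  pad <- min(n - 1L, 3L * (2L * order + 1L))
  out <- tc
  # odd-reflection padding suppresses start-up transients of the
  # forward-backward pass
  out$data <- apply(tc$data, 2L, function(x) {
    ext <- c(2 * x[1L] - x[(pad + 1L):2L], x,
             2 * x[n] - x[(n - 1L):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1L):(pad + n)]
  })
  colnames(out$data) <- tc$component_names
  out
}

#' Full post-processing chain for component time courses
#'
#' Runs, in order: polynomial detrending, optional nuisance regression,
#' despiking, and zero-phase low-pass filtering.  Output shape always equals
#' input shape.
#'
#' @param tc a [component_tc] object.
#' @param detrend_order polynomial order for [detrend_polynomial] (default 3).
#' @param nuisance optional `T x R` nuisance regressor matrix for
#'   [regress_nuisance]; `NULL` skips the stage.
#' @param do_despike run [despike] (default `TRUE`).
#' @param cutoff_hz low-pass cut-off in Hz; `NULL` skips filtering.
#' @param ... further arguments passed to [despike].
#' @return A post-processed [component_tc].
#' @export
postprocess <- function(tc, detrend_order = 3L, nuisance = NULL,
                        do_despike = TRUE, cutoff_hz = 0.15, ...) {
  tc <- detrend_polynomial(tc, order = detrend_order)
  if (!is.null(nuisance))
    tc <- regress_nuisance(tc, nuisance)
  if (isTRUE(do_despike))
    tc <- despike(tc, ...)
  if (!is.null(cutoff_hz))
    tc <- lowpass_filter(tc, cutoff_hz = cutoff_hz)
  tc
}
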