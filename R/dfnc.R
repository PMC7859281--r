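#' Build a tapered sliding-window weight vector
#'
#' The taper is the central segment of a rectangle of ones (length
#' `window_trs`) convolved with a unit-area discrete Gaussian of standard
#' deviation `gaussian_sigma` (in TR units) evaluated on an integer grid
#' spanning +/- 4 sigma.  Weights are rescaled to sum to `window_trs`, so a
#' degenerate Gaussian (`sigma -> 0`) recovers the plain rectangle.
#'
#' @param window_trs window length in TRs (default 20, i.e. 44 s at
#'   TR = 2.2 s).
#' @param gaussian_sigma Gaussian standard deviation in TRs (default 3).
#' @return An object of class `dfnc_taper`: list with `window_trs`,
#'   `gaussian_sigma` and the weight vector `weights` (symmetric, strictly
#'   positive, maximal at the centre).
#' @examples
#' tap <- build_taper(20, 3)
#' plot(tap$weights, type = "h")
#' @export
build_taper <- function(window_trs = 20L, gaussian_sigma = 3) {
  window_trs <- as.integer(window_trs)
  if (window_trs < 1L) stop("build_taper: window_trs must be >= 1")
  if (gaussian_sigma <= 0) stop("build_taper: gaussian_sigma must be > 0")
  r <- max(1L, ceiling(4 * gaussian_sigma))
  g <- stats::dnorm(seq(-r, r), sd = gaussian_sigma)
  g <- g / sum(g)
  rect <- rep(1, window_trs)
  full <- stats::convolve(rect, rev(g), type = "open")  # length W + 2r
  w <- full[(r + 1L):(r + window_trs)]
  w <- w * window_trs / sum(w)
  # enforce exact symmetry (convolution of symmetric inputs)
  w <- (w + rev(w)) / 2
  structure(list(window_trs = window_trs, gaussian_sigma = gaussian_sigma,
                 weights = w),
            class = "dfnc_taper")
}

#' @export
print.dfnc_taper <- function(x, ...) {
  cat(sprintf("Tapered window: %d TRs, Gaussian sigma = %g TRs\n",
              x$window_trs, x$gaussian_sigma))
  invisible(x)
}

#' Weighted Pearson correlation of two vectors
#'
#' Covariance and variances are computed with weighted means and normalised;
#' with uniform weights this equals the plain Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param w non-negative weights, not all zero.
#' @return Correlation in `[-1, 1]`, or `NA` when either input has zero
#'   weighted variance.
#' @export
weighted_correlation <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("weighted_correlation: x, y, w must have equal length")
  if (any(w < 0) || sum(w) <= 0)
    stop("weighted_correlation: weights must be non-negative, not all zero")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  r <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
  min(1, max(-1, r))
}

# Weighted correlation matrix of the columns of X under weights w.
# Columns with zero weighted variance yield NA rows/cols (diagonal kept 1).
weighted_corr_matrix <- function(X, w) {
  w <- w / sum(w)
  mu <- colSums(X * w)
  Xc <- sweep(X, 2L, mu, "-")
  S <- crossprod(Xc * sqrt(w))
  v <- diag(S)
  d <- sqrt(pmax(v, 0))
  R <- S / tcrossprod(d)
  R[!is.finite(R)] <- NA_real_
  R[R > 1] <- 1
  R[R < -1] <- -1
  diag(R) <- 1
  R
}

#' Tapered sliding-window dynamic FNC
#'
#' Slides a tapered window over the time courses and computes, per window,
#' the weighted Pearson correlation matrix of all component pairs.  Windows
#' start at time index 0, `step`, `2*step`, ... while
#' `start + window_trs <= T - 1`, so at `step = 1` the window count is
#' `T - window_trs` (a 159-time-point scan with a 20-TR window yields 139
#' windows).
#'
#' @param tc a [component_tc] object.
#' @param taper a `dfnc_taper` from [build_taper].
#' @param step window step in TRs (default 1).
#' @param measure `"correlation"` (default) or `"covariance"` (weighted
#'   covariance, unbounded).
#' @return An object of class `dfnc_tensor`: list with `scan_id`, `values`
#'   (`W x P` matrix of vectorised windowed connectomes, `P = C(C-1)/2`,
#'   strict lower triangle in row-major pair order), `C`, `window_starts`
#'   (0-based), `taper`, `measure` and `component_names`.  Use
#'   [window_matrix] to recover a single `C x C` slice.
#' @export
sliding_window_fnc <- function(tc, taper = build_taper(), step = 1L,
                               measure = c("correlation", "covariance")) {
  stopifnot(inherits(tc, "component_tc"), inherits(taper, "dfnc_taper"))
  measure <- match.arg(measure)
  W <- taper$window_trs
  n <- nrow(tc$data)
  C <- ncol(tc$data)
  if (n <= W)
    stop("sliding_window_fnc: need T > window_trs (T = ", n, ", window = ",
         W, ")")
  step <- as.integer(step)
  starts <- seq.int(0L, n - W - 1L, by = step)
  idx <- lower_pairs(C)
  vals <- matrix(NA_real_, nrow = length(starts), ncol = nrow(idx))
  w <- taper$weights
  for (k in seq_along(starts)) {
    seg <- tc$data[(starts[k] + 1L):(starts[k] + W), , drop = FALSE]
    if (measure == "correlation") {
      R <- weighted_corr_matrix(seg, w)
    } else {
      ww <- w / sum(w)
      mu <- colSums(seg * ww)
      segc <- sweep(seg, 2L, mu, "-")
      R <- crossprod(segc * sqrt(ww))
    }
    vals[k, ] <- R[cbind(idx[, 1L], idx[, 2L])]
  }
  if (anyNA(vals))
    warning("sliding_window_fnc: zero-variance components in ",
            sum(apply(is.na(vals), 1L, any)), " window(s); entries set NA")
  structure(list(scan_id = tc$scan_id, values = vals, C = C,
                 window_starts = starts, taper = taper, measure = measure,
                 component_names = tc$component_names),
            class = "dfnc_tensor")
}

#' @export
print.dfnc_tensor <- function(x, ...) {
  cat(sprintf("dFNC tensor '%s': %d windows x %d x %d (%s, window %d TRs)\n",
              x$scan_id, nrow(x$values), x$C, x$C, x$measure,
              x$taper$window_trs))
  invisible(x)
}

#' Extract one window of a dFNC tensor as a C x C matrix
#'
#' @param tensor a `dfnc_tensor` from [sliding_window_fnc].
#' @param i window index (1-based).
#' @return Symmetric `C x C` matrix with unit diagonal.
#' @export
window_matrix <- function(tensor, i) {
  stopifnot(inherits(tensor, "dfnc_tensor"))
  unvectorize_fnc(tensor$values[i, ], tensor$C)
}

#' Static functional network connectivity
#'
#' Plain full-length Pearson correlation between every pair of component
#' time courses.
#'
#' @param tc a [component_tc] object with at least 3 time points.
#' @return Symmetric `C x C` correlation matrix with unit diagonal;
#'   entries involving zero-variance components are `NA`.
#' @export
static_fnc <- function(tc) {
  stopifnot(inherits(tc, "component_tc"))
  if (nrow(tc$data) < 3L) stop("static_fnc: need T >= 3")
  v <- apply(tc$data, 2L, stats::var)
  R <- suppressWarnings(stats::cor(tc$data))
  R[!is.finite(R)] <- NA_real_
  diag(R) <- ifelse(v > 0, 1, NA_real_)
  R
}

# Strict-lower-triangle pair index in row-major order:
# (2,1), (3,1), (3,2), (4,1), ... ; cached per C.
lower_pairs <- local({
  cache <- list()
  function(C) {
    key <- as.character(C)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- rep(2:C, times = 1:(C - 1L))
    j <- unlist(lapply(2:C, function(r) 1:(r - 1L)))
    m <- cbind(i = i, j = j)
    cache[[key]] <<- m
    m
  }
})

#' Vectorise a symmetric connectome matrix
#'
#' Maps a symmetric `C x C` matrix to its `C(C-1)/2` unique off-diagonal
#' values (strict lower triangle, row-major: (2,1), (3,1), (3,2), ...).
#' With `C = 53` this yields 1378 connectivity features.
#'
#' @param m symmetric square matrix.
#' @return Numeric vector of length `C(C-1)/2`.
#' @seealso [unvectorize_fnc], [fnc_pair_index]
#' @export
vectorize_fnc <- function(m) {
  m <- as.matrix(m)
  C <- nrow(m)
  if (ncol(m) != C) stop("vectorize_fnc: matrix must be square")
  if (max(abs(m - t(m)), na.rm = TRUE) > 1e-8)
    stop("vectorize_fnc: matrix must be symmetric")
  idx <- lower_pairs(C)
  m[cbind(idx[, 1L], idx[, 2L])]
}

#' Rebuild a symmetric connectome matrix from its vectorised form
#'
#' @param v numeric vector of length `C(C-1)/2` in the pair order of
#'   [vectorize_fnc].
#' @param C number of components; inferred from `length(v)` when missing.
#' @param diag_value value placed on the diagonal (default 1).
#' @return Symmetric `C x C` matrix.
#' @export
unvectorize_fnc <- function(v, C = NULL, diag_value = 1) {
  p <- length(v)
  if (is.null(C)) {
    C <- (1 + sqrt(1 + 8 * p)) / 2
    if (C != round(C))
      stop("unvectorize_fnc: length ", p, " is not C(C-1)/2 for integer C")
    C <- as.integer(C)
  }
  if (p != C * (C - 1L) / 2L)
    stop("unvectorize_fnc: expected length C(C-1)/2 = ", C * (C - 1L) / 2L,
         " for C = ", C, ", got ", p)
  m <- matrix(diag_value, C, C)
  idx <- lower_pairs(C)
  m[cbind(idx[, 1L], idx[, 2L])] <- v
  m[cbind(idx[, 2L], idx[, 1L])] <- v
  m
}

#' Pair index underlying the vectorised connectome
#'
#' @param C number of components.
#' @return Data frame with columns `feature` (1-based position), `i`, `j`
#'   (component indices, `i > j`).
#' @export
fnc_pair_index <- function(C) {
  idx <- lower_pairs(C)
  data.frame(feature = seq_len(nrow(idx)), i = idx[, 1L], j = idx[, 2L])
}
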