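# Row-standardise vectorised connectomes: zero mean, unit L2 norm, so that
# 1 - corr(a, b) = ||a~ - b~||^2 / 2 and Euclidean k-means implements
# correlation-distance k-means.
row_standardize <- function(X) {
  X <- as.matrix(X)
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc^2))
  if (any(nrm == 0))
    stop("row_standardize: constant row(s) have undefined correlation ",
         "distance: ", paste(utils::head(which(nrm == 0), 5L), collapse = ", "))
  Xc / nrm
}

# k-means++ seeding on rows of X (returns a k x P matrix of start centres)
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
  if (k > 1L) for (j in 2:k) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = p)
    }
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
  }
  centers
}

#' Cluster windowed connectomes into recurring states
#'
#' k-means under the correlation distance `d(a, b) = 1 - corr(a, b)`,
#' implemented by row-standardising each vectorised connectome (zero mean,
#' unit norm) and running Euclidean k-means on the standardised rows (the
#' two are equivalent; the equivalence is asserted in the test suite).
#' The best of `n_replicates` k-means++-seeded restarts by within-cluster
#' inertia is kept.  Set the random seed beforehand for a deterministic
#' fit.
#'
#' @param window_vectors `N x P` matrix of vectorised windowed connectomes
#'   (`P = C(C-1)/2`), e.g. stacked `values` of [sliding_window_fnc]
#'   tensors.
#' @param k number of states.
#' @param n_replicates number of restarts (default 20).
#' @param max_iter iteration cap per run (default 1000).
#' @return Object of class `dfnc_state_model`: `k`, `centroids` (`k x P`
#'   mean connectome per state, in correlation units), `centers_std`
#'   (standardised centres used for assignment), `labels` (cluster of each
#'   input row, in `1..k`), `sizes`, `inertia` (sum of correlation
#'   distances to the assigned centre) and `distance`
#'   (`"1 - Pearson correlation"`).
#' @seealso [predict.dfnc_state_model], [elbow_select_k], [match_states]
#' @export
cluster_windows <- function(window_vectors, k, n_replicates = 20L,
                            max_iter = 1000L) {
  X <- as.matrix(window_vectors)
  k <- as.integer(k)
  if (nrow(X) <= k)
    stop("cluster_windows: need more windows than clusters")
  if (ncol(X) < 2L) stop("cluster_windows: need P >= 2 features")
  if (nrow(unique(X)) < k)
    stop("cluster_windows: fewer distinct windows than clusters")
  Xs <- row_standardize(X)
  best <- NULL
  for (rep_i in seq_len(n_replicates)) {
    fit <- NULL
    for (try_i in 1:5) {
      ctr <- kmeanspp_centers(Xs, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(Xs, centers = ctr,
                                       iter.max = max_iter)),
        error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("cluster_windows: k-means failed on every restart")
  centroids <- rowsum(X, best$cluster) / as.vector(table(best$cluster))
  structure(list(k = k, centroids = unname(centroids),
                 centers_std = unname(best$centers),
                 labels = unname(best$cluster),
                 sizes = as.integer(table(factor(best$cluster,
                                                 levels = seq_len(k)))),
                 inertia = best$tot.withinss / 2,
                 distance = "1 - Pearson correlation",
                 n_replicates = n_replicates, max_iter = max_iter),
            class = "dfnc_state_model")
}

#' @export
print.dfnc_state_model <- function(x, ...) {
  cat(sprintf("dFNC state model: k = %d states over %d windows (%d features)\n",
              x$k, length(x$labels), ncol(x$centroids)))
  cat(sprintf("  distance: %s; inertia = %.3f\n", x$distance, x$inertia))
  cat("  state sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dfnc_state_model <- function(object, ...) {
  occ <- object$sizes / sum(object$sizes)
  cc <- stats::cor(t(object$centroids))
  out <- list(k = object$k, sizes = object$sizes, occupancy = occ,
              inertia = object$inertia,
              centroid_correlations = cc)
  class(out) <- "summary.dfnc_state_model"
  out
}

#' @export
print.summary.dfnc_state_model <- function(x, ...) {
  cat(sprintf("dFNC state model with k = %d states\n", x$k))
  cat("Pooled occupancy per state:\n")
  print(round(x$occupancy, 4))
  cat("Between-centroid Pearson correlations:\n")
  print(round(x$centroid_correlations, 3))
  invisible(x)
}

#' Assign new windowed connectomes to fitted states
#'
#' @param object a `dfnc_state_model`.
#' @param newdata `N x P` matrix of vectorised connectomes.
#' @param ... unused.
#' @return Integer state labels in `1..k` (nearest centre in correlation
#'   distance).
#' @export
predict.dfnc_state_model <- function(object, newdata, ...) {
  Xs <- row_standardize(as.matrix(newdata))
  # squared Euclidean distance to each standardised centre
  cross <- Xs %*% t(object$centers_std)
  c2 <- rowSums(object$centers_std^2)
  d2 <- outer(rowSums(Xs^2), c2, "+") - 2 * cross
  unname(apply(d2, 1L, which.min))
}

#' Plot state centroid connectomes
#'
#' Draws each state's mean connectome as a `C x C` image (blue negative,
#' red positive).
#'
#' @param x a `dfnc_state_model`.
#' @param ... passed to [graphics::image].
#' @export
plot.dfnc_state_model <- function(x, ...) {
  k <- x$k
  op <- graphics::par(mfrow = c(1, k), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  lim <- max(abs(x$centroids))
  for (s in seq_len(k)) {
    m <- unvectorize_fnc(x$centroids[s, ], diag_value = 0)
    graphics::image(t(m[nrow(m):1, ]), col = pal,
                    zlim = c(-lim, lim), axes = FALSE,
                    main = sprintf("State %d", s), ...)
  }
  invisible(x)
}

#' Select the number of states by the elbow criterion
#'
#' For each candidate `k` computes the cluster-validity ratio
#' `R(k) =` (mean within-cluster correlation distance) / (mean
#' between-centroid correlation distance).  The curve falls steeply until
#' the true structure is reached and then flattens (or rises again as
#' split clusters shrink the between-centroid distance), so the selected
#' `k` is the smallest one whose ratio lies within a tolerance (5% of the
#' curve's range) of the global minimum — a parsimony tie-break in the
#' spirit of the one-standard-error rule.  A selection is flagged
#' low-confidence when the curve is shallow (relative depth < 10%) or the
#' minimum sits on the boundary of `k_range` (no interior elbow).
#'
#' @param window_vectors `N x P` matrix of vectorised connectomes.
#' @param k_range candidate values of `k` (default `2:10`).
#' @param n_replicates restarts per `k` (default 20).
#' @param max_iter iteration cap per run.
#' @return List with `k` (selected), `curve` (data frame `k`, `ratio`)
#'   and `low_confidence` flag.
#' @export
elbow_select_k <- function(window_vectors, k_range = 2:10,
                           n_replicates = 20L, max_iter = 1000L) {
  X <- as.matrix(window_vectors)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range) || max(k_range) >= nrow(X))
    stop("elbow_select_k: k_range must be non-empty with max < N")
  ratio <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- cluster_windows(X, k, n_replicates = n_replicates,
                           max_iter = max_iter)
    within <- fit$inertia / length(fit$labels)
    if (k == 1L) {
      between <- NA_real_
    } else {
      cc <- stats::cor(t(fit$centroids))
      between <- mean(1 - cc[upper.tri(cc)])
    }
    ratio[i] <- within / between
  }
  span <- max(ratio) - min(ratio)
  tol <- 0.05 * span
  sel_i <- which(ratio <= min(ratio) + tol)[1L]
  sel <- k_range[sel_i]
  min_i <- which.min(ratio)
  low_conf <- span <= 0 ||
    span / max(ratio) < 0.1 ||
    min_i %in% c(1L, length(k_range))
  list(k = sel,
       curve = data.frame(k = k_range, ratio = ratio),
       low_confidence = low_conf)
}

#' Split pooled window labels back into per-scan state vectors
#'
#' @param labels integer labels for all windows, pooled across scans in
#'   the order they were stacked.
#' @param scan_ids character vector, same length as `labels`, giving the
#'   scan of each window.
#' @param window_index integer window position within each scan; used to
#'   verify the rows are in original temporal order (a shuffled input is
#'   an error, not a silent misassignment).
#' @return Named list of integer state vectors, one per scan, in original
#'   temporal order.
#' @export
assign_state_vectors <- function(labels, scan_ids, window_index = NULL) {
  if (length(labels) != length(scan_ids))
    stop("assign_state_vectors: labels and scan_ids lengths differ")
  idx <- split(seq_along(labels), factor(scan_ids, levels = unique(scan_ids)))
  if (!is.null(window_index)) {
    for (sc in names(idx)) {
      wi <- window_index[idx[[sc]]]
      if (!identical(as.integer(wi), seq_along(wi)))
        stop("assign_state_vectors: windows of scan '", sc,
             "' are not in temporal order 1..", length(wi))
    }
  }
  lapply(idx, function(i) as.integer(labels[i]))
}

#' Per-subject state-specific mean FNC
#'
#' For each state, the element-wise mean of the scan's windowed connectomes
#' whose label is that state; states the scan never visits are `NA`
#' (missing, not zero).
#'
#' @param tensor a `dfnc_tensor` from [sliding_window_fnc].
#' @param state_vector integer window labels for this scan.
#' @param k number of states.
#' @return `k x P` matrix; row `s` is the state-`s` mean vectorised FNC or
#'   `NA` if unvisited.
#' @export
subject_state_fnc <- function(tensor, state_vector, k) {
  stopifnot(inherits(tensor, "dfnc_tensor"))
  if (length(state_vector) != nrow(tensor$values))
    stop("subject_state_fnc: state vector length ", length(state_vector),
         " != window count ", nrow(tensor$values))
  out <- matrix(NA_real_, k, ncol(tensor$values))
  for (s in seq_len(k)) {
    rows <- which(state_vector == s)
    if (length(rows))
      out[s, ] <- colMeans(tensor$values[rows, , drop = FALSE])
  }
  out
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub) for (pos in 0:(n - 1L)) {
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

#' Match states across two independently fitted models
#'
#' Finds the one-to-one assignment of rows of `centroids_b` to rows of
#' `centroids_a` maximising the total Pearson correlation (exhaustive
#' search over all `k!` assignments for `k <= 8`, greedy beyond).
#'
#' @param centroids_a,centroids_b `k x P` centroid matrices.
#' @return List with `permutation` (`perm[i]` = row of `b` matched to row
#'   `i` of `a`) and `correlations` (per matched pair).
#' @export
match_states <- function(centroids_a, centroids_b) {
  A <- as.matrix(centroids_a); B <- as.matrix(centroids_b)
  if (!all(dim(A) == dim(B)))
    stop("match_states: centroid matrices must have equal dimensions")
  k <- nrow(A)
  cc <- stats::cor(t(A), t(B))  # cc[i, j] = corr(A_i, B_j)
  if (k <= 8L) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) sum(cc[cbind(seq_len(k), p)]),
                     numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k)
    left <- seq_len(k)
    for (i in order(apply(cc, 1L, max), decreasing = TRUE)) {
      j <- left[which.max(cc[i, left])]
      best[i] <- j
      left <- setdiff(left, j)
    }
  }
  list(permutation = as.integer(best),
       correlations = cc[cbind(seq_len(k), best)])
}
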