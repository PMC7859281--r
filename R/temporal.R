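#' Estimate the Markov transition matrix of a state vector
#'
#' Maximum-likelihood first-order Markov estimate from observed window
#' transitions: `counts[i, j] = #(s(t) = j, s(t+1) = i)` and
#' `a[i, j] = counts[i, j] / sum_i counts[i, j]`, i.e. the probability of
#' moving to state `i` given the current state `j` (column-stochastic).
#' Columns for states never departed from are filled according to
#' `empty_column_policy` and flagged.
#'
#' @param state_vector integer labels in `1..k`, length >= 2.
#' @param k number of states.
#' @param empty_column_policy `"uniform"` (default; fill with `1/k`, keeps
#'   feature tables rectangular) or `"missing"` (fill with `NA`).
#' @return Object of class `transition_matrix`: `a` (`k x k`), `counts`,
#'   `k`, `empty_columns` (indices of states with no observed departure).
#' @export
estimate_transition_matrix <- function(state_vector, k,
                                       empty_column_policy = c("uniform",
                                                               "missing")) {
  empty_column_policy <- match.arg(empty_column_policy)
  s <- as.integer(state_vector)
  if (length(s) < 2L)
    stop("estimate_transition_matrix: need a sequence of length >= 2")
  k <- as.integer(k)
  if (any(s < 1L) || any(s > k))
    stop("estimate_transition_matrix: labels outside 1..", k)
  from <- s[-length(s)]
  to <- s[-1L]
  counts <- matrix(0L, k, k)
  for (t in seq_along(from))
    counts[to[t], from[t]] <- counts[to[t], from[t]] + 1L
  dep <- colSums(counts)
  a <- matrix(NA_real_, k, k)
  nonempty <- dep > 0
  a[, nonempty] <- sweep(counts[, nonempty, drop = FALSE], 2L,
                         dep[nonempty], "/")
  empty <- which(!nonempty)
  if (length(empty) && empty_column_policy == "uniform")
    a[, empty] <- 1 / k
  structure(list(a = a, counts = counts, k = k,
                 empty_columns = as.integer(empty)),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Estimated transition matrix (k = %d), a[i,j] = p(next = i | current = j)\n",
              x$k))
  print(round(x$a, 3))
  if (length(x$empty_columns))
    cat("  no observed departures from state(s): ",
        paste(x$empty_columns, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Occupancy rate of a state vector
#'
#' Fraction of a scan's windows spent in each state.
#'
#' @param state_vector integer labels in `1..k`.
#' @param k number of states.
#' @param percent report percentages instead of fractions (default
#'   `FALSE`).
#' @return Numeric vector of length `k` summing to 1 (or 100); attribute
#'   `window_count` carries the sequence length.
#' @export
occupancy_rate <- function(state_vector, k, percent = FALSE) {
  s <- as.integer(state_vector)
  if (!length(s)) stop("occupancy_rate: empty state vector")
  k <- as.integer(k)
  if (any(s < 1L) || any(s > k))
    stop("occupancy_rate: labels outside 1..", k)
  ocr <- tabulate(s, nbins = k) / length(s)
  if (percent) ocr <- 100 * ocr
  attr(ocr, "window_count") <- length(s)
  ocr
}

#' Per-scan temporal feature table
#'
#' One row per scan: the `k^2` transition probabilities flattened row-major
#' (`a11, a12, ..., akk`, so 9 features for `k = 3`) followed by the `k`
#' occupancy rates (`ocr1..ocrk`).
#'
#' @param state_vectors named list of per-scan integer state vectors (as
#'   from [assign_state_vectors]).
#' @param k number of states.
#' @param empty_column_policy passed to [estimate_transition_matrix].
#' @return Data frame with columns `scan_id`, `a11..akk`, `ocr1..ocrk`.
#' @export
feature_table <- function(state_vectors, k,
                          empty_column_policy = "uniform") {
  k <- as.integer(k)
  scan_ids <- names(state_vectors)
  if (is.null(scan_ids)) scan_ids <- sprintf("scan%03d", seq_along(state_vectors))
  acols <- as.vector(t(outer(seq_len(k), seq_len(k),
                             function(i, j) sprintf("a%d%d", i, j))))
  rows <- lapply(state_vectors, function(sv) {
    tm <- estimate_transition_matrix(sv, k,
                                     empty_column_policy = empty_column_policy)
    c(as.vector(t(tm$a)), occupancy_rate(sv, k))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(acols, sprintf("ocr%d", seq_len(k)))
  out <- data.frame(scan_id = scan_ids, m, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
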