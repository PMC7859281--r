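#' Covariate-adjusted partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on an intercept plus the covariates, with the two-sided p
#' value from the t statistic `r * sqrt(df / (1 - r^2))`,
#' `df = n - q - 2`.  Rows with any missing value are dropped
#' (pairwise-complete).
#'
#' @param x,y numeric vectors.
#' @param covariates optional `n x q` matrix of covariates; `NULL` gives
#'   the plain Pearson correlation and its p value.
#' @return List with `r`, `p`, `n_used`, `degenerate`.  When a residual
#'   variance is zero (an input fully explained by the covariates) the
#'   result is flagged `degenerate = TRUE` with `r = 0` and `p = NA`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    Z <- as.matrix(covariates)
  }
  if (length(y) != length(x) || nrow(Z) != length(x))
    stop("partial_correlation: x, y and covariates must have equal rows")
  keep <- stats::complete.cases(x, y, Z)
  x <- x[keep]; y <- y[keep]
  Z <- Z[keep, , drop = FALSE]
  n <- length(x); q <- ncol(Z)
  if (n <= q + 2L)
    stop("partial_correlation: need n > q + 2 complete rows (n = ", n,
         ", q = ", q, ")")
  qz <- qr(cbind(1, Z))
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  vx <- sum(rx^2); vy <- sum(ry^2)
  if (vx <= n * .Machine$double.eps * max(1, sum(x^2)) ||
      vy <= n * .Machine$double.eps * max(1, sum(y^2)))
    # an input fully explained by the covariates carries no residual
    # association: report r = 0, flag the p value as undefined
    return(list(r = 0, p = NA_real_, n_used = n, degenerate = TRUE))
  r <- sum(rx * ry) / sqrt(vx * vy)
  r <- min(1, max(-1, r))
  df <- n - q - 2L
  p <- if (abs(r) >= 1) 0 else
    2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  list(r = r, p = p, n_used = n, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' Step-up false-discovery-rate control:
#' `adjusted_(i) = min_(j >= i) m * p_(j) / j` on the sorted p values,
#' mapped back to input order and clipped at 1.
#'
#' @param p_values numeric vector of p values in `[0, 1]` (`NA` allowed,
#'   propagated).
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("bh_adjust: p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# partial correlations of every column of X with y, adjusting for Z;
# vectorised over complete columns, per-column for columns with NAs
partial_correlation_matrix <- function(X, y, Z) {
  X <- as.matrix(X)
  n <- nrow(X)
  r <- rep(NA_real_, ncol(X)); p <- rep(NA_real_, ncol(X))
  nu <- rep(NA_integer_, ncol(X))
  base_keep <- stats::complete.cases(y, Z)
  col_ok <- !apply(is.na(X), 2L, any)
  if (any(col_ok)) {
    keep <- base_keep
    q <- ncol(Z)
    qz <- qr(cbind(1, Z[keep, , drop = FALSE]))
    ry <- qr.resid(qz, y[keep])
    RX <- qr.resid(qz, X[keep, col_ok, drop = FALSE])
    vy <- sum(ry^2)
    vx <- colSums(RX^2)
    num <- as.vector(crossprod(RX, ry))
    ri <- num / sqrt(vx * vy)
    ri[vx <= .Machine$double.eps * sum(keep)] <- NA_real_
    ri <- pmin(1, pmax(-1, ri))
    df <- sum(keep) - q - 2L
    pi_ <- ifelse(abs(ri) >= 1, 0,
                  2 * stats::pt(-abs(ri * sqrt(df / (1 - ri^2))), df))
    r[col_ok] <- ri; p[col_ok] <- pi_
    nu[col_ok] <- sum(keep)
  }
  for (j in which(!col_ok)) {
    keep <- base_keep & !is.na(X[, j])
    if (sum(keep) <= ncol(Z) + 2L) next
    res <- partial_correlation(X[keep, j], y[keep], Z[keep, , drop = FALSE])
    r[j] <- res$r; p[j] <- res$p; nu[j] <- res$n_used
  }
  list(r = r, p = p, n_used = nu)
}

#' Covariate-adjusted association of features with a clinical score
#'
#' For each feature family (for example per-state connectivity features,
#' occupancy rates, transition probabilities), computes the partial
#' correlation of every feature with the clinical score adjusting for the
#' covariates, applies Benjamini-Hochberg correction *within* the family,
#' and flags significance at adjusted `p < alpha`.  Scans missing a
#' feature (for example a state never visited) are dropped for that
#' feature only.
#'
#' @param features data frame or matrix of numeric features with a
#'   `scan_id` column (or rownames), one row per scan.
#' @param clinical data frame with columns `scan_id`, the score column and
#'   the covariate columns.
#' @param families named list mapping family name to the feature column
#'   names it contains; defaults to a single family `"features"` holding
#'   every numeric column.
#' @param score_col name of the clinical score column (default
#'   `"cdr_sob"`).
#' @param covariate_cols covariate column names (default
#'   `c("age", "gender")`).
#' @param alpha significance level on adjusted p values (default 0.05).
#' @return Data frame of class `association_table`: `feature`, `family`,
#'   `n_used`, `partial_r`, `p_raw`, `p_adjusted`, `significant`.
#' @export
run_association <- function(features, clinical, families = NULL,
                            score_col = "cdr_sob",
                            covariate_cols = c("age", "gender"),
                            alpha = 0.05) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (!"scan_id" %in% names(features)) {
    if (is.null(rownames(features)))
      stop("run_association: features need a scan_id column or rownames")
    features$scan_id <- rownames(features)
  }
  need <- c("scan_id", score_col, covariate_cols)
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("run_association: clinical table lacks column(s): ",
         paste(miss, collapse = ", "))
  merged <- merge(features, clinical[, need], by = "scan_id", sort = FALSE)
  if (nrow(merged) <= length(covariate_cols) + 2L)
    stop("run_association: too few scans after joining on scan_id (",
         nrow(merged), ")")
  feat_cols <- setdiff(names(features), "scan_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]
  if (is.null(families)) families <- list(features = feat_cols)
  y <- merged[[score_col]]
  Z <- as.matrix(merged[, covariate_cols, drop = FALSE])
  out <- list()
  for (fam in names(families)) {
    cols <- intersect(families[[fam]], feat_cols)
    if (!length(cols)) {
      warning("run_association: family '", fam, "' has no usable features")
      next
    }
    res <- partial_correlation_matrix(merged[, cols, drop = FALSE], y, Z)
    padj <- bh_adjust(res$p)
    out[[fam]] <- data.frame(
      feature = cols, family = fam, n_used = res$n_used,
      partial_r = res$r, p_raw = res$p, p_adjusted = padj,
      significant = !is.na(padj) & padj < alpha,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("association_table", "data.frame")
  attr(tab, "alpha") <- alpha
  attr(tab, "covariates") <- covariate_cols
  tab
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("Association table: %d features in %d families (alpha = %g, covariates: %s)\n",
              nrow(x), length(unique(x$family)), attr(x, "alpha"),
              paste(attr(x, "covariates"), collapse = ", ")))
  sig <- x[x$significant %in% TRUE, , drop = FALSE]
  cat(sprintf("  %d significant after within-family BH correction\n",
              nrow(sig)))
  if (nrow(sig)) print.data.frame(utils::head(sig, 10))
  invisible(x)
}
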