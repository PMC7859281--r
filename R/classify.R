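#' Adaptive synthetic (ADASYN) minority oversampling
#'
#' Generates `G = round((m_major - m_minor) * beta)` synthetic minority
#' samples.  Each minority point `i` receives a share of the synthetic
#' budget proportional to `r_i`, the fraction of its `k_neighbors` nearest
#' neighbours (in the full data) belonging to the majority class, so
#' synthesis concentrates where the minority class is hardest to learn.
#' Each synthetic sample is `x_i + lambda * (x_z - x_i)` with `x_z` a
#' random one of the `k_neighbors` nearest *minority* neighbours of `x_i`
#' and `lambda` uniform on `[0, 1]`; per-point allocations are corrected by
#' largest remainder so exactly `G` samples are emitted.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param labels two-level factor or vector; the rarer level is the
#'   minority class.
#' @param beta balance level in `[0, 1]` (default 1: fully balanced
#'   budget).
#' @param k_neighbors neighbourhood size (default 5); the minority class
#'   must have at least `k_neighbors + 1` members.
#' @return Matrix of `G` synthetic minority rows (0 rows when the classes
#'   are already balanced), with attributes `source` (minority row index
#'   each sample was grown from) and `minority_level`.
#' @examples
#' set.seed(1)
#' d <- generate_classification_cohort(85, 40, n_features = 5)
#' nrow(adasyn_oversample(d$x, d$labels))  # 45
#' @export
adasyn_oversample <- function(x, labels, beta = 1, k_neighbors = 5L) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x)))
    stop("adasyn_oversample: features must be finite")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("adasyn_oversample: need exactly two classes")
  tab <- table(labels)
  tab <- tab[tab > 0]
  minority <- names(tab)[which.min(tab)]
  m_minor <- min(tab); m_major <- max(tab)
  if (m_minor < k_neighbors + 1L)
    stop("adasyn_oversample: minority class needs >= k_neighbors + 1 = ",
         k_neighbors + 1L, " samples")
  G <- round((m_major - m_minor) * beta)
  empty <- matrix(numeric(0), 0L, ncol(x),
                  dimnames = list(NULL, colnames(x)))
  if (G <= 0L) {
    attr(empty, "source") <- integer(0)
    attr(empty, "minority_level") <- minority
    return(empty)
  }
  min_idx <- which(labels == minority)
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  # r_i: majority fraction among the k nearest neighbours in the full data
  r <- vapply(min_idx, function(i) {
    nn <- order(D[i, ])[seq_len(k_neighbors)]
    mean(labels[nn] != minority)
  }, numeric(1))
  if (sum(r) == 0) {
    warning("adasyn_oversample: minority class fully interior; ",
            "falling back to uniform allocation")
    r <- rep(1, length(min_idx))
  }
  rhat <- r / sum(r)
  g_exact <- rhat * G
  g <- floor(g_exact)
  rem <- G - sum(g)
  if (rem > 0) {
    extra <- order(g_exact - g, decreasing = TRUE)[seq_len(rem)]
    g[extra] <- g[extra] + 1L
  }
  syn <- matrix(NA_real_, G, ncol(x))
  src <- integer(G)
  row <- 0L
  for (ii in seq_along(min_idx)) {
    if (g[ii] == 0L) next
    i <- min_idx[ii]
    others <- setdiff(min_idx, i)
    nn_min <- others[order(D[i, others])][seq_len(min(k_neighbors,
                                                      length(others)))]
    for (rep_i in seq_len(g[ii])) {
      z <- nn_min[sample.int(length(nn_min), 1L)]
      lambda <- stats::runif(1)
      row <- row + 1L
      syn[row, ] <- x[i, ] + lambda * (x[z, ] - x[i, ])
      src[row] <- i
    }
  }
  colnames(syn) <- colnames(x)
  attr(syn, "source") <- src
  attr(syn, "minority_level") <- minority
  syn
}

#' Polynomial kernel
#'
#' `k(x1, x2) = (1 + x1' x2)^p` for a positive integer degree `p`.
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param p polynomial degree (positive integer).
#' @return Scalar kernel value.
#' @export
polynomial_kernel <- function(x1, x2, p) {
  if (length(x1) != length(x2))
    stop("polynomial_kernel: vectors must have equal length")
  p <- as.integer(p)
  if (p < 1L) stop("polynomial_kernel: degree must be >= 1")
  (1 + sum(x1 * x2))^p
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#' A rate with zero denominator is reported missing, not 0.
#'
#' @param tp,fn,tn,fp non-negative integer counts.
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion_metrics: counts must be non-negative integers")
  tot <- tp + fn + tn + fp
  list(
    accuracy = if (tot > 0) (tp + tn) / tot else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# rank-based (Mann-Whitney) AUC: P(score_pos > score_neg) + 0.5 P(tie)
rank_auc <- function(scores, is_positive) {
  n1 <- sum(is_positive); n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# decision scores oriented so larger = more evidence for `positive`;
# e1071 orients its decision values toward the class named first in the
# "A/B" column name of the decision-value attribute
oriented_scores <- function(model, newdata, positive) {
  pr <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  s <- as.vector(dv)
  if (first != positive) s <- -s
  list(class = pr, score = s)
}

svm_poly <- function(x, y, degree, cost) {
  e1071::svm(x = x, y = y, kernel = "polynomial", degree = degree,
             gamma = 1, coef0 = 1, cost = cost, scale = FALSE)
}

# grid-search hyperparameters by inner f-fold CV accuracy on (x, y)
inner_cv_select <- function(x, y, degree_grid, cost_grid, folds) {
  n <- nrow(x)
  fold_id <- sample(rep_len(seq_len(folds), n))
  best <- NULL
  for (d in degree_grid) for (cc in cost_grid) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < 2L) { acc[f] <- NA; next }
      fit <- svm_poly(x[tr, , drop = FALSE], y[tr], d, cc)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      acc[f] <- mean(pred == y[!tr])
    }
    m <- mean(acc, na.rm = TRUE)
    if (is.null(best) || m > best$acc)
      best <- list(degree = d, cost = cc, acc = m)
  }
  best
}

#' Repeated evaluation of conversion prediction with ADASYN balancing
#'
#' Implements the repeated train/test protocol for predicting conversion
#' from the healthy (majority, uc-HC) to the impaired (minority, c-HC)
#' group.  Per repeat: (1) a fraction `minority_holdout` of the minority
#' class is set aside for evaluation; (2) ADASYN generates `G` synthetic
#' minority samples from the remaining (seed) minority; (3) a random
#' majority subset of size `G` is drawn; (4) a polynomial-kernel SVM is
#' trained on the balanced set (majority subset + synthetic minority),
#' with hyperparameters chosen by inner `folds`-fold cross-validation
#' (80/20 at the default 5 folds) on the training set only; (5) the model
#' is evaluated on real unseen samples from both groups — the held-out
#' majority plus the held-out minority.  Synthetic samples never enter an
#' evaluation set, and minority points that seeded synthetic samples are
#' not evaluated either (setting `minority_holdout = 0` evaluates on all
#' real minority samples instead; that variant leaks minority geometry
#' into training through the synthetic interpolants and scores above
#' chance even on shuffled labels).  Accuracy, sensitivity and
#' specificity use the majority (uc-HC) class as positive reference (flip
#' with `positive`); AUC is rank-based on the decision scores.
#'
#' @param x numeric feature matrix (real samples only).
#' @param labels two-level factor; the rarer level is the minority class.
#' @param n_repeats number of repeats (default 10).
#' @param folds inner cross-validation folds (default 5).
#' @param degree_grid polynomial degrees searched (default `c(2, 3)`).
#' @param cost_grid regularisation costs searched (default
#'   `10^(-1:1)`).
#' @param beta,k_neighbors passed to [adasyn_oversample].
#' @param minority_holdout fraction of minority samples excluded from
#'   ADASYN seeding and reserved for evaluation, per repeat (default
#'   0.2).
#' @param positive class treated as positive in the confusion metrics;
#'   default the majority level.
#' @return Object of class `conversion_report`: per-repeat data frame
#'   (`accuracy`, `sensitivity`, `specificity`, `auc`, chosen
#'   hyperparameters), their means, and bookkeeping fields including the
#'   per-repeat test row indices (all referring to real input rows).
#' @export
evaluate_conversion <- function(x, labels, n_repeats = 10L, folds = 5L,
                                degree_grid = c(2L, 3L),
                                cost_grid = 10^(-1:1),
                                beta = 1, k_neighbors = 5L,
                                minority_holdout = 0.2,
                                positive = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nrow(x) != length(labels))
    stop("evaluate_conversion: features and labels row-mismatch")
  if (nlevels(droplevels(labels)) != 2L)
    stop("evaluate_conversion: need exactly two classes")
  tab <- table(labels); tab <- tab[tab > 0]
  majority <- names(tab)[which.max(tab)]
  minority <- names(tab)[which.min(tab)]
  if (is.null(positive)) positive <- majority
  negative <- setdiff(c(majority, minority), positive)
  maj_idx <- which(labels == majority)
  min_idx <- which(labels == minority)
  n_hold <- round(minority_holdout * length(min_idx))
  if (minority_holdout > 0) n_hold <- max(1L, n_hold)
  if (length(min_idx) - n_hold < k_neighbors + 1L)
    stop("evaluate_conversion: too few minority samples left for ADASYN ",
         "after the holdout")
  res <- vector("list", n_repeats)
  test_sets <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    test_min <- if (n_hold > 0) sample(min_idx, n_hold) else integer(0)
    seed_rows <- setdiff(seq_len(nrow(x)), test_min)
    syn <- adasyn_oversample(x[seed_rows, , drop = FALSE],
                             labels[seed_rows], beta = beta,
                             k_neighbors = k_neighbors)
    G <- nrow(syn)
    n_sub <- min(G, length(maj_idx) - 1L)
    maj_sub <- sample(maj_idx, n_sub)
    train_x <- rbind(x[maj_sub, , drop = FALSE], syn)
    train_y <- factor(rep(c(majority, minority), c(n_sub, G)),
                      levels = levels(labels))
    test_idx <- c(setdiff(maj_idx, maj_sub),
                  if (n_hold > 0) test_min else min_idx)
    # standardise with training statistics
    mu <- colMeans(train_x)
    sdv <- apply(train_x, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    scale_rows <- function(m) sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
    train_s <- scale_rows(train_x)
    test_s <- scale_rows(x[test_idx, , drop = FALSE])
    sel <- inner_cv_select(train_s, train_y, degree_grid, cost_grid, folds)
    fit <- svm_poly(train_s, train_y, sel$degree, sel$cost)
    pred <- oriented_scores(fit, test_s, positive)
    truth <- labels[test_idx]
    tp <- sum(pred$class == positive & truth == positive)
    fn <- sum(pred$class == negative & truth == positive)
    tn <- sum(pred$class == negative & truth == negative)
    fp <- sum(pred$class == positive & truth == negative)
    met <- confusion_metrics(tp, fn, tn, fp)
    auc <- rank_auc(pred$score, truth == positive)
    res[[rep_i]] <- data.frame(repeat_id = rep_i,
                               accuracy = met$accuracy,
                               sensitivity = met$sensitivity,
                               specificity = met$specificity,
                               auc = auc, degree = sel$degree,
                               cost = sel$cost)
    test_sets[[rep_i]] <- test_idx
  }
  per_repeat <- do.call(rbind, res)
  means <- colMeans(per_repeat[, c("accuracy", "sensitivity",
                                   "specificity", "auc")], na.rm = TRUE)
  structure(list(per_repeat = per_repeat, mean = as.list(means),
                 n_repeats = n_repeats, folds = folds,
                 positive = positive, minority = minority,
                 test_indices = test_sets,
                 n_real = nrow(x)),
            class = "conversion_report")
}

#' @export
print.conversion_report <- function(x, ...) {
  cat(sprintf("Conversion classification: %d repeats, inner %d-fold CV, positive class = '%s'\n",
              x$n_repeats, x$folds, x$positive))
  cat(sprintf("  mean accuracy    %.3f\n  mean sensitivity %.3f\n  mean specificity %.3f\n  mean AUC         %.3f\n",
              x$mean$accuracy, x$mean$sensitivity, x$mean$specificity,
              x$mean$auc))
  invisible(x)
}
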