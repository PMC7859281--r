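test_that("ADASYN emits the exact synthetic budget", {
  set.seed(71)
  d <- generate_classification_cohort(85, 40, n_features = 6)
  syn <- adasyn_oversample(d$x, d$labels)
  expect_equal(nrow(syn), 45)
  expect_length(attr(syn, "source"), 45)
  expect_equal(attr(syn, "minority_level"), "c_hc")

  balanced <- generate_classification_cohort(40, 40, n_features = 6)
  expect_equal(nrow(adasyn_oversample(balanced$x, balanced$labels)), 0)

  half <- adasyn_oversample(d$x, d$labels, beta = 0.5)
  expect_equal(nrow(half), round(45 * 0.5))
})

test_that("ADASYN concentrates synthesis on hard-to-learn minority points", {
  # one minority point surrounded by majority, the rest isolated together
  surrounded <- c(0, 0)
  ring <- rbind(c(0.1, 0), c(-0.1, 0), c(0, 0.1), c(0, -0.1), c(0.1, 0.1),
                c(-0.1, -0.1), c(5, 5), c(5.2, 5), c(5, 5.2))
  island <- matrix(rnorm(12, mean = 10, sd = 0.1), 6, 2)
  x <- rbind(surrounded, island, ring)
  labels <- c(rep("minor", 7), rep("major", 9))
  set.seed(72)
  syn <- adasyn_oversample(x, labels, k_neighbors = 5)
  expect_equal(nrow(syn), 2)
  expect_true(all(attr(syn, "source") == 1L))  # all weight on the hard point
})

test_that("synthetic samples are convex combinations within the minority envelope", {
  set.seed(73)
  d <- generate_classification_cohort(50, 20, n_features = 4)
  syn <- adasyn_oversample(d$x, d$labels)
  minority <- d$x[d$labels == "c_hc", ]
  lo <- apply(minority, 2, min); hi <- apply(minority, 2, max)
  expect_true(all(sweep(syn, 2, lo, ">=") & sweep(syn, 2, hi, "<=")))
})

test_that("the polynomial kernel matches its explicit monomial feature map", {
  expect_equal(polynomial_kernel(c(1, 0), c(0, 1), 3), 1)
  expect_equal(polynomial_kernel(c(1, 1), c(1, 1), 2), 9)
  set.seed(74)
  for (p in c(2L, 3L)) {
    u <- rnorm(2); v <- rnorm(2)
    expect_equal(polynomial_kernel(u, v, p),
                 sum(poly_feature_map(u, p) * poly_feature_map(v, p)),
                 tolerance = 1e-10)
  }
  expect_error(polynomial_kernel(1:2, 1:3, 2), "equal length")
})

test_that("confusion metrics implement the printed formulas", {
  m <- confusion_metrics(tp = 7, fn = 3, tn = 8, fp = 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$sensitivity, 0.70)
  expect_equal(m$specificity, 0.80)

  perfect <- confusion_metrics(5, 0, 9, 0)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  expect_true(is.na(confusion_metrics(0, 0, 4, 1)$sensitivity))

  # brute-force tally oracle on random small confusions
  set.seed(75)
  for (i in 1:10) {
    cts <- sample(0:20, 4, replace = TRUE)
    truth <- rep(c("pos", "pos", "neg", "neg"), cts)
    pred <- rep(c("pos", "neg", "neg", "pos"), cts)
    m2 <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    if (sum(cts) > 0)
      expect_equal(m2$accuracy, mean(pred == truth))
    if (cts[1] + cts[2] > 0)
      expect_equal(m2$sensitivity,
                   mean(pred[truth == "pos"] == "pos"))
    if (cts[3] + cts[4] > 0)
      expect_equal(m2$specificity,
                   mean(pred[truth == "neg"] == "neg"))
  }
})

test_that("rank AUC is invariant to monotone score transforms and matches pROC", {
  set.seed(76)
  scores <- rnorm(60)
  pos <- rbinom(60, 1, plogis(scores)) == 1
  a1 <- dfncstates:::rank_auc(scores, pos)
  expect_equal(dfncstates:::rank_auc(exp(scores), pos), a1)
  expect_equal(dfncstates:::rank_auc(2 * scores + 7, pos), a1)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                          predictor = scores,
                                          levels = c(FALSE, TRUE),
                                          direction = "<", quiet = TRUE)))
    expect_equal(a1, ref, tolerance = 1e-12)
  }
})

test_that("evaluation never tests on synthetic samples and scores sanely", {
  set.seed(77)
  d <- generate_classification_cohort(60, 30, n_features = 8,
                                      effect_size = 5)
  rep_sep <- evaluate_conversion(d$x, d$labels, n_repeats = 3)
  expect_gte(rep_sep$mean$accuracy, 0.95)
  # leakage guard: every test index refers to a real input row and each
  # evaluation set contains held-out members of both classes
  minority_rows <- which(d$labels == "c_hc")
  for (idx in rep_sep$test_indices) {
    expect_true(all(idx >= 1 & idx <= rep_sep$n_real))
    expect_gt(length(intersect(idx, minority_rows)), 0)
    expect_gt(length(setdiff(idx, minority_rows)), 0)
  }

  # chance level on shuffled labels (averaged over shuffles, since a
  # single shuffled data set carries sampling noise of its own)
  set.seed(78)
  aucs <- replicate(8, {
    shuffled <- sample(d$labels)
    evaluate_conversion(d$x, shuffled, n_repeats = 3)$mean$auc
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
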