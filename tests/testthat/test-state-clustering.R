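test_that("correlation distance equals half squared Euclidean distance after standardisation", {
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    X <- rbind(a, b)
    Xs <- dfncstates:::row_standardize(X)
    expect_equal(1 - cor(a, b), sum((Xs[1, ] - Xs[2, ])^2) / 2,
                 tolerance = 1e-12)
  }
})

test_that("well-separated clouds are recovered essentially perfectly", {
  set.seed(42)
  centres <- matrix(rnorm(3 * 10, sd = 3), 3, 10)
  d <- make_clouds(centres, n_per = 80, sd = 0.2)
  fit <- cluster_windows(d$x, 3, n_replicates = 10)
  expect_gte(ari(fit$labels, d$labels), 0.99)
  # predict() agrees with the fitted assignment
  expect_gte(mean(predict(fit, d$x) == fit$labels), 0.999)
})

test_that("k = 1 yields a single cluster at the standardised mean", {
  set.seed(43)
  X <- matrix(rnorm(50 * 8), 50, 8)
  fit <- cluster_windows(X, 1, n_replicates = 2)
  expect_true(all(fit$labels == 1))
  Xs <- dfncstates:::row_standardize(X)
  expect_equal(as.vector(fit$centers_std), colMeans(Xs), tolerance = 1e-8)
  expect_equal(as.vector(fit$centroids), colMeans(X), tolerance = 1e-8)
})

test_that("clustering recovers planted connectivity states from windowed data", {
  set.seed(44)
  co <- generate_cohort(8, 8, C = 20, stickiness = 0.9)
  tens <- lapply(co$timecourses, sliding_window_fnc)
  W <- do.call(rbind, lapply(tens, `[[`, "values"))
  fit <- cluster_windows(W, 3, n_replicates = 10)
  truth <- sapply(co$states, function(s) vectorize_fnc(s$matrix))
  m <- match_states(fit$centroids, t(truth))
  expect_true(all(m$correlations >= 0.9))
  lab_true <- unlist(lapply(co$truth, `[[`, "window_labels"),
                     use.names = FALSE)
  expect_gte(mean(m$permutation[fit$labels] == lab_true), 0.9)
})

test_that("relabelling states permutes centroids and temporal features consistently", {
  set.seed(45)
  centres <- matrix(rnorm(3 * 12, sd = 3), 3, 12)
  d <- make_clouds(centres, n_per = 50, sd = 0.2)
  fit <- cluster_windows(d$x, 3, n_replicates = 5)
  perm <- c(3L, 1L, 2L)           # relabel s -> perm[s]
  relab <- perm[fit$labels]
  occ1 <- occupancy_rate(fit$labels, 3)
  occ2 <- occupancy_rate(relab, 3)
  expect_equal(occ2[perm], as.vector(occ1), ignore_attr = TRUE)
  a1 <- estimate_transition_matrix(fit$labels, 3)$a
  a2 <- estimate_transition_matrix(relab, 3)$a
  expect_equal(a2[perm, perm], a1)
})

test_that("elbow criterion finds planted cluster counts and flags unstructured data", {
  set.seed(46)
  centres5 <- matrix(rnorm(5 * 10, sd = 4), 5, 10)
  d5 <- make_clouds(centres5, n_per = 60, sd = 0.2)
  sel5 <- elbow_select_k(d5$x, k_range = 2:8, n_replicates = 5)
  expect_equal(sel5$k, 5)

  set.seed(47)
  blob <- matrix(rnorm(250 * 10), 250, 10)
  sel1 <- elbow_select_k(blob, k_range = 2:6, n_replicates = 3)
  expect_true(sel1$low_confidence)
})

test_that("state vectors split pooled labels by scan and reject shuffled input", {
  labs <- c(1L, 2L, 2L)
  sv <- assign_state_vectors(labs, rep("s1", 3), 1:3)
  expect_equal(sv$s1, c(1L, 2L, 2L))

  labs2 <- rep(1:2, 139)
  sv2 <- assign_state_vectors(labs2, rep(c("a", "b"), each = 139),
                              rep(1:139, 2))
  expect_equal(lengths(sv2), c(a = 139L, b = 139L))

  expect_error(assign_state_vectors(labs2, rep(c("a", "b"), each = 139),
                                    rep(139:1, 2)),
               "temporal order")
})

test_that("state-specific mean FNC averages exactly and marks unvisited states missing", {
  set.seed(48)
  tc <- component_tc(matrix(rnorm(60 * 4), 60, 4))
  tens <- sliding_window_fnc(tc, build_taper(20, 3))
  W <- nrow(tens$values)
  sv_all1 <- rep(1L, W)
  sf <- subject_state_fnc(tens, sv_all1, 3)
  expect_equal(sf[1, ], colMeans(tens$values))
  expect_true(all(is.na(sf[2:3, ])))

  sv <- c(1L, 1L, rep(2L, W - 2L))
  sf2 <- subject_state_fnc(tens, sv, 2)
  expect_equal(sf2[1, ], (tens$values[1, ] + tens$values[2, ]) / 2)
})

test_that("state matching recovers permutations by exhaustive assignment", {
  set.seed(49)
  A <- matrix(rnorm(4 * 30), 4, 30)
  m_id <- match_states(A, A)
  expect_equal(m_id$permutation, 1:4)
  expect_equal(m_id$correlations, rep(1, 4), tolerance = 1e-12)

  p <- c(3L, 1L, 4L, 2L)
  B <- A[p, ]               # B_j = A_{p[j]}, so row i of A matches row
  inv <- order(p)           # inv[i] of B
  m <- match_states(A, B)
  expect_equal(m$permutation, inv)
  expect_equal(m$correlations, rep(1, 4), tolerance = 1e-12)
})

# The group-wise robustness check (healthy-only vs patient-only clustering
# yields matchable states at correlation >= 0.95) needs a full-size cohort
# for the centroid noise to settle; it runs on the 60-scan recovery cohort
# in test-acceptance.R.
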