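test_that("state covariances honour the block template and stay positive definite", {
  # zero coupling collapses to the identity
  spec0 <- list(blocks = list(all = 1:4),
                states = list(list(within = c(all = 0),
                                   between = matrix(0, 1, 1))))
  sc0 <- make_state_covariances(4, 1, block_spec = spec0)
  expect_equal(sc0[[1]]$matrix, diag(4))

  # default study conditions: 53 components, 3 states
  sc <- make_state_covariances(53, 3)
  expect_length(sc, 3)
  for (s in sc) {
    expect_equal(dim(s$matrix), c(53L, 53L))
    expect_equal(diag(s$matrix), rep(1, 53))
    expect_equal(s$matrix, t(s$matrix))
    expect_gt(min(eigen(s$matrix, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
  vecs <- sapply(sc, function(s) vectorize_fnc(s$matrix))
  cc <- cor(vecs)
  expect_lt(max(cc[upper.tri(cc)]), 0.9)  # pairwise distinguishable

  # opposite-signed between-block couplings give weakly (here negatively)
  # correlated connectomes, verified by direct Pearson correlation of the
  # vectorised matrices
  spec2 <- list(
    blocks = list(a = 1:3, b = 4:6),
    states = list(
      list(within = c(a = 0.8, b = 0.8),
           between = matrix(c(0, -0.3, -0.3, 0), 2)),
      list(within = c(a = 0.2, b = 0.2),
           between = matrix(c(0, 0.4, 0.4, 0), 2))))
  sc2 <- make_state_covariances(6, 2, block_spec = spec2)
  v <- sapply(sc2, function(s) vectorize_fnc(s$matrix))
  expect_lt(cor(v[, 1], v[, 2]), 0.5)

  expect_error(make_state_covariances(6, 2, block_spec = list(
    blocks = list(a = 1:3), states = list())), "partition|states")
})

test_that("state sequences follow the transition matrix", {
  expect_equal(simulate_state_sequence(diag(3), 10, initial = 2),
               rep(2L, 10))

  set.seed(31)
  u3 <- matrix(1 / 3, 3, 3)
  s <- simulate_state_sequence(u3, 30000)
  occ <- tabulate(s, 3) / 30000
  expect_lt(max(abs(occ - 1 / 3)), 0.01)

  a <- matrix(0.05, 3, 3); diag(a) <- 0.9
  s2 <- simulate_state_sequence(a, 20000)
  counts <- count_transitions_oracle(s2, 3)
  a11_hat <- counts[1, 1] / sum(counts[, 1])
  expect_lt(abs(a11_hat - 0.9), 0.02)

  bad <- matrix(c(0.5, 0.4, 0.3, 0.7), 2)
  expect_error(simulate_state_sequence(bad, 10), "column\\(s\\) 1")
})

test_that("empirical transition frequencies converge for arbitrary chains", {
  set.seed(32)
  for (rep_i in 1:3) {
    raw <- matrix(runif(9, 0.05, 1), 3)
    a <- sweep(raw, 2, colSums(raw), "/")
    s <- simulate_state_sequence(a, 20000)
    counts <- count_transitions_oracle(s, 3)
    a_hat <- sweep(counts, 2, colSums(counts), "/")
    expect_lt(max(abs(a_hat - a)), 0.02)
  }
})

test_that("simulated time courses reproduce the state correlation structure", {
  set.seed(33)
  sim0 <- simulate_timecourses(list(diag(2)), rep(1L, 500),
                               samples_per_step = 10, obs_noise_sd = 0)
  expect_equal(dim(sim0$tc$data), c(5000L, 2L))
  expect_lt(abs(cor(sim0$tc$data)[1, 2]), 0.05)

  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  sim1 <- simulate_timecourses(list(S), rep(1L, 500),
                               samples_per_step = 10, obs_noise_sd = 0)
  expect_lt(abs(cor(sim1$tc$data)[1, 2] - 0.8), 0.05)
  expect_equal(sim1$regime, rep(1L, 5000))

  expect_error(simulate_timecourses(list(diag(2)), c(1, 2), 5), "covariance")
})

test_that("cohorts are bitwise reproducible under a fixed seed", {
  set.seed(34)
  c1 <- generate_cohort(3, 3, C = 8, scan_length_tp = 60)
  set.seed(34)
  c2 <- generate_cohort(3, 3, C = 8, scan_length_tp = 60)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$timecourses[[1]]$data, c2$timecourses[[1]]$data)
  expect_identical(c1$truth, c2$truth)
})

test_that("cohort clinical scores respect the group contract", {
  set.seed(35)
  co <- generate_cohort(10, 0, C = 6, timecourses = FALSE)
  expect_true(all(co$metadata$cdr_sob == 0))

  co2 <- generate_cohort(10, 15, C = 6, timecourses = FALSE)
  imp <- co2$metadata$group == "impaired"
  expect_true(all(co2$metadata$cdr_sob[imp] >= 0.5 &
                    co2$metadata$cdr_sob[imp] <= 9))
  expect_true(all(co2$metadata$cdr_sob[!imp] == 0))
  expect_true(all(co2$metadata$gender %in% 0:1))

  # null configuration: no slope, identical dynamics across groups
  tm <- transition_from_stationary(c(0.3, 0.4, 0.3), 0.8)
  co3 <- generate_cohort(40, 40, C = 6, timecourses = FALSE,
                         transition_healthy = tm, transition_impaired = tm,
                         score_model = list(slope = 0, noise_sd = 0))
  occ <- sapply(co3$truth, function(t) t$occupancy[1])
  pc <- partial_correlation(occ, co3$metadata$cdr_sob,
                            cbind(co3$metadata$age, co3$metadata$gender))
  expect_lt(abs(pc$r), 0.3)   # no planted association
})

test_that("classification cohorts have the documented size and separability", {
  set.seed(36)
  d <- generate_classification_cohort(85, 40, n_features = 10)
  expect_equal(nrow(d$x), 125)
  expect_equal(as.vector(table(d$labels)), c(85, 40))

  # zero effect: chance-level AUC, averaged over data sets to smooth the
  # per-data-set sampling noise
  auc0 <- mean(replicate(8, {
    d0 <- generate_classification_cohort(60, 30, n_features = 10,
                                         effect_size = 0)
    evaluate_conversion(d0$x, d0$labels, n_repeats = 2)$mean$auc
  }))
  expect_gt(auc0, 0.35)
  expect_lt(auc0, 0.65)

  d3 <- generate_classification_cohort(120, 60, n_features = 10,
                                       effect_size = 3)
  r3 <- evaluate_conversion(d3$x, d3$labels, n_repeats = 3,
                            minority_holdout = 0.4)
  expect_gt(r3$mean$auc, 0.9)
})

test_that("written cohorts round-trip through the text formats", {
  set.seed(37)
  co <- generate_cohort(2, 2, C = 5, scan_length_tp = 50)
  dir <- file.path(tempdir(), "cohort_roundtrip")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  tc <- load_timecourses(file.path(dir, "timecourses",
                                   paste0(co$metadata$scan_id[1], ".csv")))
  expect_equal(tc$data, co$timecourses[[1]]$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(unlist(gt[[1]]$window_labels),
               co$truth[[1]]$window_labels, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
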