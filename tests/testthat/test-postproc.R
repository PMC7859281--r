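test_that("polynomial detrending removes exact polynomials and matches least squares", {
  n <- 100
  t <- seq_len(n)
  tc <- component_tc(cbind(5 * t + 2, rnorm(n)))
  out <- detrend_polynomial(tc, 1)
  expect_lt(max(abs(out$data[, 1])), 1e-9)

  tc3 <- component_tc(cbind(t^3, rnorm(n)))
  out3 <- detrend_polynomial(tc3, 3)
  expect_lt(max(abs(out3$data[, 1])), 1e-6)

  set.seed(21)
  x <- rnorm(n)
  tcx <- component_tc(cbind(x, rnorm(n)))
  got <- detrend_polynomial(tcx, 3)$data[, 1]
  B <- cbind(1, t, t^2, t^3)
  ref <- x - B %*% solve(crossprod(B), crossprod(B, x))
  expect_equal(got, as.vector(ref), tolerance = 1e-8)
  # residuals orthogonal to the basis
  expect_lt(max(abs(crossprod(B, got))) / sqrt(sum(got^2)) / n, 1e-8)
  expect_error(detrend_polynomial(component_tc(matrix(rnorm(8), 4, 2)), 3),
               "T > order")
})

test_that("nuisance regression residuals are orthogonal to the design", {
  set.seed(22)
  n <- 80
  reg <- matrix(rnorm(n * 6), n, 6)
  tc <- component_tc(cbind(reg[, 1], rnorm(n), rnorm(n)))
  out <- regress_nuisance(tc, reg, include_derivatives = FALSE)
  expect_lt(max(abs(out$data[, 1])), 1e-9)  # column equals a regressor

  # full design with derivatives matches the normal-equations oracle
  out2 <- regress_nuisance(tc, reg, include_derivatives = TRUE)
  X <- cbind(1, reg, rbind(0, diff(reg)))
  H <- X %*% solve(crossprod(X), t(X))
  ref <- (diag(n) - H) %*% tc$data
  expect_equal(unname(out2$data), unname(ref), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(X, out2$data))), 1e-6)

  expect_error(regress_nuisance(tc, cbind(reg, reg[, 1])),
               "collinear")
})

test_that("orthogonal regressors leave a demeaned signal", {
  n <- 128
  t <- seq_len(n)
  sig <- sin(2 * pi * 5 * t / n)
  reg <- cbind(cos(2 * pi * 11 * t / n), sin(2 * pi * 17 * t / n))
  tc <- component_tc(cbind(sig + 3, rnorm(n)))
  out <- regress_nuisance(tc, reg, include_derivatives = FALSE)
  expect_equal(out$data[, 1], sig - mean(sig), tolerance = 1e-6)
})

test_that("despiking replaces only threshold-crossing points", {
  set.seed(23)
  n <- 200
  # slowly varying signal with bounded noise: the running median tracks
  # it closely and no deviation can cross 4 robust standard deviations
  smooth <- sin(seq(0, 2 * pi, length.out = n)) + runif(n, -0.1, 0.1)
  tc <- component_tc(cbind(smooth, seq_len(n) / n))
  expect_equal(despike(tc)$data[, 1], smooth)  # nothing crosses threshold

  spiked <- smooth
  spiked[77] <- spiked[77] + 100 * sd(smooth)
  tcs <- component_tc(cbind(spiked, seq_len(n) / n))
  out <- despike(tcs)$data[, 1]
  med <- runmed(spiked, 11, endrule = "median")
  expect_identical(out[-77], spiked[-77])      # all others bit-identical
  expect_equal(out[77], med[77])

  const <- rep(2, n); const[50] <- 90
  tcc <- component_tc(cbind(const, seq_len(n) / n))
  expect_equal(despike(tcc)$data[, 1], rep(2, n))
  # all-constant column passes through unchanged (MAD 0 guarded)
  tcz <- component_tc(cbind(rep(2, n), seq_len(n) / n))
  expect_equal(despike(tcz)$data[, 1], rep(2, n))
})

test_that("low-pass filter has the specified pass/stop behaviour at TR 2.2", {
  n <- 512; tr <- 2.2
  t <- (seq_len(n) - 1) * tr
  dc <- rep(1, n)
  lo <- sin(2 * pi * 0.05 * t)
  hi <- sin(2 * pi * 0.22 * t)   # below Nyquist 0.227 Hz
  tc <- component_tc(cbind(dc, lo, hi), tr_seconds = tr)
  out <- lowpass_filter(tc, 0.15)
  expect_equal(out$data[, 1], dc, tolerance = 1e-6)
  expect_gte(fitted_amplitude(out$data[, 2], 0.05, tr), 0.95)
  expect_lte(fitted_amplitude(out$data[, 3], 0.22, tr), 0.05)
  expect_error(lowpass_filter(tc, 0.25), "Nyquist")
})

test_that("the post-processing chain preserves shape; projection stages are idempotent", {
  set.seed(24)
  n <- 300
  tc <- component_tc(matrix(rnorm(n * 4), n, 4) +
                       outer(seq_len(n) / n, c(3, -2, 0.5, 1)))
  full <- postprocess(tc)
  expect_equal(dim(full$data), dim(tc$data))

  # detrending and nuisance regression are least-squares projections:
  # reapplying each one changes nothing
  d1 <- detrend_polynomial(tc, 3)
  d2 <- detrend_polynomial(d1, 3)
  expect_lt(norm(d2$data - d1$data, "F") / norm(d1$data, "F"), 1e-6)
  reg <- matrix(rnorm(n * 6), n, 6)
  r1 <- regress_nuisance(d1, reg)
  r2 <- regress_nuisance(r1, reg)
  expect_lt(norm(r2$data - r1$data, "F") / norm(r1$data, "F"), 1e-6)

  # despike is idempotent: a cleaned series has no remaining spikes
  sm <- sin(seq(0, 2 * pi, length.out = n)) + runif(n, -0.1, 0.1)
  sm[100] <- sm[100] + 50
  tcs <- component_tc(cbind(sm, seq_len(n) / n))
  s1 <- despike(tcs)
  expect_equal(despike(s1)$data[, 1], s1$data[, 1])
})
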