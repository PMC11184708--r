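test_that("drop_initial_volumes drops exactly the leading volumes", {
  g <- make_grid(c(3L, 3L, 3L))
  s <- white_series(g, n_t = 230L)
  expect_equal(nrow(drop_initial_volumes(s, 10L)$data), 220L)
  expect_identical(drop_initial_volumes(s, 0L), s)
  expect_identical(drop_initial_volumes(s, 3L)$data, s$data[-(1:3), ])
  s20 <- white_series(g, n_t = 20L)
  expect_error(drop_initial_volumes(s20, 20L), "cannot drop")
})

test_that("motion exclusion rule uses strict per-axis limits", {
  tr <- matrix(0, 10, 6)
  expect_false(exceeds_motion_limit(tr))
  tr[4, 2] <- 2.6
  expect_true(exceeds_motion_limit(tr))
  tr[4, 2] <- 2.5                      # boundary: "exceeding" is strict
  expect_false(exceeds_motion_limit(tr))
  tr[7, 5] <- -2.5001                  # rotations count too, in degrees
  expect_true(exceeds_motion_limit(tr))
  expect_false(exceeds_motion_limit(tr, rot_limit = 3))
})

test_that("mean framewise displacement matches the step-sum oracle", {
  tr <- matrix(0, 5, 6)
  expect_equal(mean_framewise_displacement(tr), 0)
  tr2 <- matrix(0, 2, 6); tr2[2, 1] <- 0.3
  expect_equal(mean_framewise_displacement(tr2), 0.3)
  set.seed(8)
  tr3 <- matrix(rnorm(60, sd = 0.2), 10, 6)
  d <- abs(diff(tr3))
  oracle <- mean(rowSums(d[, 1:3]) + 50 * rowSums(d[, 4:6] * pi / 180))
  expect_equal(mean_framewise_displacement(tr3), oracle)
  expect_equal(mean_framewise_displacement(tr3, head_radius = 0),
               mean(rowSums(d[, 1:3])))
})

test_that("friston24 expands to params, lags, and squares", {
  set.seed(9)
  tr <- matrix(rnorm(30), 5, 6)
  X <- friston24(tr)
  expect_equal(dim(X), c(5L, 24L))
  expect_equal(X[, 1:6], tr)
  expect_equal(X[2:5, 7:12], tr[1:4, ])
  expect_equal(unname(X[1, 7:12]), rep(0, 6))
  expect_equal(X[, 13:18], tr^2)
})

test_that("nuisance regression projects out the design exactly", {
  g <- make_grid(c(3L, 3L, 3L))
  n_t <- 40L
  set.seed(10)
  trace <- simulate_motion(n_t, max_mm = 1)
  # a series equal to the linear trend is annihilated
  trend <- seq_len(n_t) - (n_t + 1) / 2
  s_tr <- series_4d(matrix(trend, n_t, 27), g)
  out <- regress_nuisance(s_tr, nuisance_model(), trace)
  expect_lt(max(abs(out$data)), 1e-8)
  # residuals orthogonal to every regressor
  s <- white_series(g, n_t = n_t, seed = 11L)
  res <- regress_nuisance(s, nuisance_model(), trace)
  X <- cbind(1, trend, friston24(trace))
  expect_lt(max(abs(crossprod(X, res$data))) / max(abs(s$data)), 1e-8)
  # equivalence with a normal-equations oracle on 5 voxels
  Y5 <- s$data[, 1:5]
  beta <- solve(crossprod(X), crossprod(X, Y5))
  expect_equal(res$data[, 1:5], Y5 - X %*% beta, tolerance = 1e-10)
  # tissue regressors join the design
  wm <- rnorm(n_t); csf <- rnorm(n_t)
  res2 <- regress_nuisance(s, nuisance_model(wm_signal = wm, csf_signal = csf),
                           trace)
  X2 <- cbind(X[, 1:2], wm, csf, friston24(trace))
  expect_lt(max(abs(crossprod(X2, res2$data))) / max(abs(s$data)), 1e-8)
  # rank-deficient design falls back to the pseudo-inverse with a warning
  const_trace <- matrix(1, n_t, 6)
  expect_warning(regress_nuisance(s, nuisance_model(), const_trace),
                 "rank-deficient")
})

test_that("bandpass keeps the passband and kills stopband and DC", {
  g <- make_grid(c(2L, 1L, 1L))
  n_t <- 200L; tr <- 2
  t_sec <- (seq_len(n_t) - 1) * tr
  amp_after <- function(f_hz) {
    s <- series_4d(cbind(sin(2 * pi * f_hz * t_sec),
                         cos(2 * pi * f_hz * t_sec)), g, tr = tr)
    out <- bandpass(s)
    # spectral oracle: amplitude at the probe frequency bin
    spec <- Mod(stats::fft(out$data[, 1]))[round(f_hz * n_t * tr) + 1]
    spec / (n_t / 2)
  }
  expect_gt(amp_after(0.05), 0.9)   # passband centre preserved
  expect_lt(amp_after(0.2), 0.1)    # stopband attenuated >= 90%
  s_const <- series_4d(matrix(5, n_t, 2), g, tr = tr)
  expect_lt(max(abs(bandpass(s_const)$data)), 1e-10)  # DC removed
  expect_error(bandpass(series_4d(matrix(rnorm(40), 20), make_grid(c(2L,1L,1L)),
                                  tr = 2), high = 0.3), "Nyquist")
  # near-idempotence: a second application changes the output < 5% RMS
  s <- white_series(g, n_t = n_t, seed = 12L)
  once <- bandpass(s)
  twice <- bandpass(once)
  rel <- sqrt(mean((twice$data - once$data)^2)) / sqrt(mean(once$data^2))
  expect_lt(rel, 0.05)
})

test_that("gaussian smoothing is mass-preserving and has the right width", {
  g <- make_grid(c(15L, 15L, 15L), vox = 3)
  imp <- numeric(prod(g$dims))
  ctr <- 8L + 15L * 7L + 225L * 7L
  imp[ctr] <- 1
  out <- smooth_gaussian(imp, fwhm_mm = 6, grid = g)
  expect_equal(sum(out), 1, tolerance = 1e-6)
  # profile half-maximum width ~ 2 voxels for 6 mm FWHM at 3 mm voxels
  arr <- array(out, c(15, 15, 15))
  prof <- arr[, 8, 8]                  # x-profile through the impulse
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # interpolated crossing points on either side
  f <- stats::approxfun(seq_len(15), prof)
  lo <- stats::uniroot(function(z) f(z) - half, c(above[1] - 1, above[1]))$root
  hi <- stats::uniroot(function(z) f(z) - half, c(above[2], above[2] + 1))$root
  expect_equal(hi - lo, 2, tolerance = 0.15)     # voxels = 6 mm / 3 mm
  # fwhm 0 is the identity
  s <- white_series(make_grid(c(4L, 4L, 4L)), n_t = 5L)
  expect_identical(smooth_gaussian(s, 0), s)
  # masked renormalization: constant field stays constant inside the mask
  inside <- rep(FALSE, prod(g$dims))
  inside[1:200] <- TRUE
  pm <- brain_mask(inside, g)
  cst <- as.numeric(pm$inside) * 3.7
  sm <- smooth_gaussian(cst, fwhm_mm = 6, mask = pm, grid = g)
  expect_equal(sm[pm$inside], rep(3.7, sum(pm$inside)), tolerance = 1e-8)
})
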