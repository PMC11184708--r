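test_that("pair_distance and fisher_z closed forms", {
  expect_equal(pair_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(pair_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(3, sd = 20); b <- rnorm(3, sd = 20)
    expect_equal(pair_distance(a, b), sqrt(sum((a - b)^2)))
  }
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(1)))
  v <- seq(0, 1, by = 0.05)
  expect_true(all(diff(fisher_z(v)) > 0))
  expect_error(fisher_z(1.2), "\\[-1, 1\\]")
  expect_error(fisher_z(-1.01), "\\[-1, 1\\]")
})

test_that("compute_fcd matches the exhaustive all-pairs oracle", {
  g <- make_grid(c(5L, 5L, 5L), vox = 3)
  s <- white_series(g, n_t = 50L, seed = 14L)
  m <- full_mask(g)
  for (dc in c(6, 12, 18)) {
    f <- compute_fcd(s, m, distance_config(dc))
    # brute-force oracle: full correlation and distance matrices
    R <- abs(stats::cor(s$data)); diag(R) <- 0
    D <- as.matrix(stats::dist(voxel_coordinates(g, m)))
    short <- D <= dc + 1e-8; diag(short) <- FALSE
    V <- ncol(R)
    n_s <- colSums(short)
    n_l <- V - 1 - n_s
    s_oracle <- ifelse(n_s > 0, colSums(R * short) / n_s, 0)
    long <- !short; diag(long) <- FALSE
    l_oracle <- ifelse(n_l > 0, colSums(R * long) / n_l, 0)
    expect_equal(f$g_raw, colSums(R) / (V - 1), tolerance = 1e-12)
    expect_equal(f$s_raw, unname(s_oracle), tolerance = 1e-12)
    expect_equal(f$l_raw, unname(l_oracle), tolerance = 1e-12)
    expect_equal(f$n_short, unname(colSums(short)))
    expect_equal(f$g_z, atanh(pmin(f$g_raw, 1 - 1e-7)))
  }
})

test_that("FCD results are independent of block size and voxel order", {
  g <- make_grid(c(5L, 4L, 4L), vox = 3)
  s <- white_series(g, n_t = 40L, seed = 15L)
  set.seed(16)
  m <- brain_mask(runif(prod(g$dims)) < 0.8, g)
  ref <- compute_fcd(s, m, block_size = 10000L)
  for (bs in c(7L, 64L)) {
    # defeat the cached fast path so the blocked branch really runs
    f <- compute_fcd(s, m, block_size = bs, partition_matrix_max = 1L)
    expect_equal(f$g_raw, ref$g_raw, tolerance = 1e-12)
    expect_equal(f$s_raw, ref$s_raw, tolerance = 1e-12)
    expect_identical(f$n_short, ref$n_short)
  }
})

test_that("per-voxel conservation identity holds everywhere", {
  g <- make_grid(c(6L, 6L, 6L), vox = 3)
  for (seed in 1:3) {
    s <- white_series(g, n_t = 30L, seed = seed)
    f <- compute_fcd(s, full_mask(g))
    lhs <- (f$n_short + f$n_long) * f$g_raw
    rhs <- f$n_short * f$s_raw + f$n_long * f$l_raw
    expect_lt(max(abs(lhs - rhs) / pmax(abs(lhs), 1e-12)), 1e-10)
    expect_true(all(f$n_short + f$n_long == sum(full_mask(g)$inside) - 1L))
    expect_true(all(f$g_raw >= 0 & f$g_raw <= 1))
  }
})

test_that("interior short-range neighbour count is 256 at 12 mm / 3 mm", {
  # lattice-enumeration oracle: integer points with i^2+j^2+k^2 <= 16
  offs <- expand.grid(i = -4:4, j = -4:4, k = -4:4)
  n_oracle <- sum(rowSums(offs^2) <= 16) - 1L
  expect_equal(n_oracle, 256L)
  g <- make_grid(c(12L, 12L, 12L), vox = 3)
  s <- white_series(g, n_t = 10L, seed = 17L)
  f <- compute_fcd(s, full_mask(g), distance_config(12))
  arr <- array(NA_integer_, g$dims)
  arr[f$voxel_index] <- f$n_short
  expect_equal(unname(arr[6, 6, 6]), n_oracle)
  # raising the criterion never shrinks the short set
  f6 <- compute_fcd(s, full_mask(g), distance_config(6))
  f18 <- compute_fcd(s, full_mask(g), distance_config(18))
  expect_true(all(f6$n_short <= f$n_short))
  expect_true(all(f$n_short <= f18$n_short))
})

test_that("degenerate and zero-variance inputs are handled", {
  g <- make_grid(c(3L, 3L, 3L), vox = 3)
  # identical signal everywhere: all raw maps 1, z finite via the clip
  sig <- sin(2 * pi * 0.05 * (0:39) * 2)
  s <- series_4d(matrix(sig, 40, 27), g)
  f <- compute_fcd(s, full_mask(g))
  expect_equal(f$g_raw, rep(1, 27))
  expect_equal(f$s_raw, rep(1, 27))
  expect_true(all(is.finite(f$g_z)))
  # zero-variance voxels dropped with a warning
  s2 <- white_series(g, n_t = 40L, seed = 18L)
  s2$data[, 5] <- 2.5
  expect_warning(f2 <- compute_fcd(s2, full_mask(g)), "zero-variance")
  expect_length(f2$g_raw, 26L)
  s3 <- series_4d(matrix(1, 20, 27) + 0, g)
  expect_error(suppressWarnings(compute_fcd(s3, full_mask(g))),
               "zero temporal variance")
})

test_that("null level of mean |r| matches the analytic approximation", {
  g <- make_grid(c(6L, 6L, 6L), vox = 3)
  n_t <- 80L
  means <- vapply(1:20, function(seed) {
    f <- compute_fcd(white_series(g, n_t = n_t, seed = 300 + seed),
                     full_mask(g))
    mean(f$g_raw)
  }, numeric(1))
  expect_lt(abs(mean(means) - sqrt(2 / (pi * (n_t - 1)))), 0.005)
})

test_that("whole_brain_mean averages in-mask values", {
  g <- make_grid(c(3L, 3L, 3L))
  m <- brain_mask(c(TRUE, TRUE, rep(FALSE, 25)), g)
  expect_equal(whole_brain_mean(c(0.2, 0.4), m), 0.3)
  full <- numeric(27); full[1:2] <- c(0.2, 0.4)
  expect_equal(whole_brain_mean(full, m), 0.3)
  set.seed(19)
  v <- rnorm(27)
  expect_equal(whole_brain_mean(v, full_mask(g)), sum(v) / 27)
  expect_error(whole_brain_mean(rnorm(5), m), "matches neither")
})

test_that("FCD maps round-trip through NIfTI with a sidecar", {
  g <- make_grid(c(5L, 5L, 5L), vox = 3)
  s <- white_series(g, n_t = 30L, seed = 20L)
  f <- compute_fcd(s, full_mask(g))
  prefix <- tempfile("maps")
  paths <- write_fcd_maps(f, prefix)
  gz <- read_nifti(paste0(prefix, "_g_z.nii.gz"))
  expect_equal(as.vector(gz$data), unname(f$g_z), tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"))
  expect_equal(meta$criterion_mm, 12)
})
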