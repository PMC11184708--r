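# Shared fixtures: tiny grids, white-noise series, small cohorts.

make_grid <- function(dims = c(5L, 5L, 5L), vox = 3,
                      origin = -vox * (dims - 1) / 2) {
  volume_grid(dims, rbind(cbind(diag(rep(vox, 3)), origin), c(0, 0, 0, 1)))
}

full_mask <- function(grid) brain_mask(rep(TRUE, prod(grid$dims)), grid)

white_series <- function(grid, n_t = 50L, tr = 2, seed = 1L) {
  set.seed(seed)
  series_4d(matrix(rnorm(n_t * prod(grid$dims)), n_t), grid, tr = tr)
}

# minimal valid cohort data frame (n subjects cycled over the 3 groups)
toy_cohort <- function(n = 12L, seed = 1L) {
  set.seed(seed)
  df <- data.frame(
    id = sprintf("S%02d", seq_len(n)),
    group = rep(c("LSS", "RSS", "HC"), length.out = n),
    age = round(rnorm(n, 57, 9)),
    gender = sample(c("male", "female"), n, replace = TRUE, prob = c(.8, .2)),
    education = round(rnorm(n, 10, 3)),
    head_motion = runif(n, 0.05, 0.3),
    stringsAsFactors = FALSE)
  df$lesion_volume <- ifelse(df$group == "HC", NA, runif(n, 1, 6))
  df$duration <- ifelse(df$group == "HC", NA, runif(n, 3, 36))
  df$fma_ue <- ifelse(df$group == "HC", NA, round(runif(n, 20, 60)))
  df$fma_le <- ifelse(df$group == "HC", NA, round(runif(n, 15, 34)))
  df$mbi_c <- ifelse(df$group == "HC", NA, round(runif(n, 50, 100)))
  cohort_table(df)
}

# small, fast cohort spec used across the downstream tests
small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_per_group = c(LSS = 6L, RSS = 6L, HC = 8L),
              dims = c(10L, 10L, 10L), n_volumes = 60L, n_drop = 5L,
              seed = seed, ...)
}
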