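# Synthetic three-group BOLD cohort generator with known ground truth.
#
# Generative model per subject: each "network" owns a set of spherical
# blobs sharing one latent band-limited (0.01-0.1 Hz) Gaussian signal of
# unit variance; a blob voxel's series is
#     y_v(t) = a_s * latent_net(t) + e_v(t)
# where a_s is the network loading (scaled by the subject's group
# multiplier and a lognormal subject jitter) and e_v is band-limited
# noise, optionally spatially smoothed, standardized to sd `noise_sd`.
# Two distinct voxels of the same network therefore correlate at
#     r = a_s^2 / (a_s^2 + noise_sd^2)
# (exactly, in expectation, when the noise is not spatially smoothed),
# which makes every downstream FCD statistic checkable against a closed
# form. Group differences are injected by multiplying one network's
# loading per group; clinical scores are linear in the subject's true
# regional FCD plus noise.

#' Network specification
#'
#' @param blobs List of blobs, each `list(center = c(i, j, k), radius = r)`
#'   in 1-based voxel indices / voxel units.
#' @param loading Coupling strength `a >= 0` of the shared latent signal.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(blobs, loading = 0.8) {
  if (loading < 0) stop("loading must be >= 0")
  for (b in blobs) {
    if (length(b$center) != 3L) stop("blob center must be a voxel index triple")
    if (is.null(b$radius) || b$radius < 1) stop("blob radius must be >= 1")
  }
  structure(list(blobs = blobs, loading = loading), class = "network_spec")
}

#' Cohort specification
#'
#' Defaults describe the desk-scale stated world: a 12x12x12 grid at 3 mm
#' isotropic, 220 analyzed volumes at TR 2 s (230 simulated, 10 dropped),
#' group sizes 25/22/39 (LSS/RSS/HC), one long-range two-blob network
#' carrying the group effect plus one neutral local network, band-limited
#' spatially smoothed noise, and clinical scores linear in true regional
#' FCD.
#'
#' @param n_per_group Named integer vector `c(LSS, RSS, HC)`.
#' @param dims Grid dimensions (voxels).
#' @param voxel_size_mm Isotropic voxel size, mm.
#' @param n_volumes Analyzed (post-drop) volumes.
#' @param n_drop Extra leading volumes simulated for the dropping step.
#' @param tr_seconds Repetition time, s.
#' @param networks List of [network_spec()]s; element `effect_network`
#'   carries the group effect.
#' @param effect_network Index into `networks`.
#' @param group_effect Named per-group multipliers on the effect network's
#'   loading; all equal gives a null cohort. The default multiplier for
#'   the patient groups was calibrated once so that the patient-vs-HC
#'   standardized difference of in-region gFCD z values is about 1.0.
#' @param smooth_fwhm_mm Spatial correlation scale of the noise, mm.
#' @param noise_sd Voxelwise noise standard deviation.
#' @param loading_jitter_sd Lognormal sd of the per-subject loading jitter
#'   (subject-level variance; makes true regional FCD identifiable).
#' @param band Passband of latent signals and noise, Hz.
#' @param motion_max_mm Bound of the simulated motion random walk.
#' @param score_model Per-score `c(intercept, slope, noise_sd)`; scores
#'   are `intercept + slope * (true_regional_fcd_z - z_ref) + noise`,
#'   where `z_ref` is the cohort's nominal healthy-control regional z
#'   (so the intercept is the score of a nominal HC and the defaults stay
#'   within instrument range at any grid scale).
#' @param seed Master seed; per-subject seeds are derived by stable
#'   hashing of (seed, subject id).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(LSS = 25L, RSS = 22L, HC = 39L),
                        dims = c(12L, 12L, 12L), voxel_size_mm = 3,
                        n_volumes = 220L, n_drop = 10L, tr_seconds = 2,
                        networks = NULL, effect_network = 1L,
                        group_effect = c(LSS = 1.35, RSS = 1.35, HC = 1),
                        smooth_fwhm_mm = 6, noise_sd = 1,
                        loading_jitter_sd = 0.2, band = c(0.01, 0.1),
                        motion_max_mm = 1.2,
                        score_model = list(
                          fma_ue = c(intercept = 45, slope = -450, noise_sd = 1.5),
                          fma_le = c(intercept = 28, slope = 150,  noise_sd = 1.0),
                          mbi_c  = c(intercept = 83, slope = 420,  noise_sd = 1.5)),
                        seed = 1L) {
  dims <- as.integer(dims)
  if (any(c(n_per_group, dims, n_volumes, n_drop) <= 0) && n_drop != 0)
    stop("counts must be positive")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(networks)) {
    hi <- pmax(dims - 3L, 2L)
    networks <- list(
      network_spec(list(list(center = c(4L, dims[2] %/% 2L, hi[3]), radius = 2),
                        list(center = c(hi[1], dims[2] %/% 2L, hi[3]), radius = 2)),
                   loading = 0.8),
      network_spec(list(list(center = c(dims[1] %/% 2L, dims[2] %/% 2L, 3L),
                             radius = 2)),
                   loading = 0.8))
  }
  if (!all(names(n_per_group) == c("LSS", "RSS", "HC")))
    names(n_per_group) <- c("LSS", "RSS", "HC")
  if (!all(c("LSS", "RSS", "HC") %in% names(group_effect)))
    stop("group_effect needs LSS, RSS and HC entries")
  grid <- volume_grid(dims, affine = rbind(
    cbind(diag(rep(voxel_size_mm, 3)), -voxel_size_mm * (dims - 1) / 2),
    c(0, 0, 0, 1)))
  spec <- structure(list(
    n_per_group = n_per_group, dims = dims, voxel_size_mm = voxel_size_mm,
    grid = grid, n_volumes = as.integer(n_volumes), n_drop = as.integer(n_drop),
    tr_seconds = tr_seconds, networks = networks,
    effect_network = as.integer(effect_network), group_effect = group_effect,
    smooth_fwhm_mm = smooth_fwhm_mm, noise_sd = noise_sd,
    loading_jitter_sd = loading_jitter_sd, band = band,
    motion_max_mm = motion_max_mm, score_model = score_model,
    seed = as.integer(seed)), class = "cohort_spec")
  for (net in networks) {
    for (b in net$blobs) {
      if (any(b$center < 1L) || any(b$center > dims))
        stop("network blob center outside the grid")
    }
  }
  spec
}

# linear voxel indices of a spherical blob (1-based center, voxel units)
blob_voxels <- function(center, radius, dims) {
  rng <- lapply(1:3, function(ax)
    max(1L, floor(center[ax] - radius)):min(dims[ax], ceiling(center[ax] + radius)))
  g <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  d2 <- rowSums((g - matrix(center, nrow(g), 3, byrow = TRUE))^2)
  g <- g[d2 <= radius^2 + 1e-9, , drop = FALSE]
  as.integer(g[, 1] + dims[1] * (g[, 2] - 1L) + dims[1] * dims[2] * (g[, 3] - 1L))
}

network_voxels <- function(net, dims)
  sort(unique(unlist(lapply(net$blobs, function(b)
    blob_voxels(b$center, b$radius, dims)))))

# deterministic 31-bit seed from a master seed and a subject id
derive_seed <- function(master, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.double(master) * 48271) %% 2147483647)
}

# white noise band-limited to [low, high] Hz, columns standardized to unit sd
band_limited_noise <- function(n_t, n_cols, tr, low, high) {
  w <- matrix(stats::rnorm(n_t * n_cols), n_t, n_cols)
  freqs <- seq(0, n_t - 1) / (n_t * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)
  H <- bandpass_response(freqs, low, high, transition = 0.005)
  H[1] <- 0
  out <- Re(stats::mvfft(stats::mvfft(w) * H, inverse = TRUE)) / n_t
  sds <- col_sds(out)
  sds[sds == 0] <- 1
  sweep(out, 2, sds, "/")
}

# expected null-level |r| between independent band-limited series:
# the band holds about 2 * (high - low) * T * tr effective dof
null_mean_abs_r <- function(n_t, tr, band) {
  dof <- max(3, 2 * (band[2] - band[1]) * n_t * tr)
  sqrt(2 / (pi * (dof - 1)))
}

# expected in-region gFCD (raw) for a subject with in-network |r| = r_in
true_regional_g_raw <- function(r_in, n_region, n_total, r0) {
  ((n_region - 1) * r_in + (n_total - n_region) * r0) / (n_total - 1)
}

# regional gFCD z of a nominal (multiplier 1, jitter 1) healthy control
nominal_regional_z <- function(spec) {
  eff <- spec$networks[[spec$effect_network]]
  a <- eff$loading
  r_in <- a^2 / (a^2 + spec$noise_sd^2)
  n_reg <- length(network_voxels(eff, spec$dims))
  r0 <- null_mean_abs_r(spec$n_volumes, spec$tr_seconds, spec$band)
  atanh(true_regional_g_raw(r_in, n_reg, prod(spec$dims), r0))
}

#' Simulate one subject's raw BOLD series
#'
#' Deterministic in `(spec, group, subject_seed)`. The returned series has
#' `n_volumes + n_drop` volumes (the initial-volume drop is part of
#' preprocessing, not generation).
#'
#' @param spec A [cohort_spec()].
#' @param group `"LSS"`, `"RSS"` or `"HC"`.
#' @param subject_seed Integer seed for this subject.
#' @return A list: `series` ([series_4d()]), `trace` (motion matrix),
#'   `covariates` (age, gender, education), `truth` (per-network subject
#'   loadings, in-network correlation `r_in`, and `regional_z`, the true
#'   regional gFCD z of the effect network).
#' @export
simulate_subject <- function(spec, group, subject_seed) {
  if (!group %in% COHORT_GROUPS) stop("unknown group: ", group)
  set.seed(subject_seed)
  n_t <- spec$n_volumes + spec$n_drop
  V <- prod(spec$dims)

  latents <- band_limited_noise(n_t, length(spec$networks), spec$tr_seconds,
                                spec$band[1], spec$band[2])
  noise <- band_limited_noise(n_t, V, spec$tr_seconds,
                              spec$band[1], spec$band[2])
  if (spec$smooth_fwhm_mm > 0) {
    sigma_vox <- spec$smooth_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$grid$voxel_size
    ops <- lapply(1:3, function(ax)
      gauss_operator_1d(spec$dims[ax], sigma_vox[ax]))
    arr <- separable_apply(array(t(noise), dim = c(spec$dims, n_t)), ops)
    noise <- t(matrix(arr, nrow = V))
    sds <- col_sds(noise)
    sds[sds == 0] <- 1
    noise <- sweep(noise, 2, sds, "/")
  }
  noise <- noise * spec$noise_sd

  loadings <- numeric(length(spec$networks))
  data <- noise
  for (ni in seq_along(spec$networks)) {
    net <- spec$networks[[ni]]
    a <- net$loading
    if (ni == spec$effect_network) a <- a * spec$group_effect[[group]]
    if (spec$loading_jitter_sd > 0)
      a <- a * exp(stats::rnorm(1, 0, spec$loading_jitter_sd))
    loadings[ni] <- a
    vox <- network_voxels(net, spec$dims)
    data[, vox] <- data[, vox] + a * latents[, ni]
  }
  series <- series_4d(data, spec$grid, tr = spec$tr_seconds)
  trace <- simulate_motion(n_t, max_mm = spec$motion_max_mm)

  covariates <- list(
    age = round(min(max(stats::rnorm(1, 57, 9), 30), 80)),
    gender = if (stats::runif(1) < 0.85) "male" else "female",
    education = round(min(max(stats::rnorm(1, 10, 3), 1), 20)))

  eff <- spec$networks[[spec$effect_network]]
  a_eff <- loadings[spec$effect_network]
  r_in <- a_eff^2 / (a_eff^2 + spec$noise_sd^2)
  n_reg <- length(network_voxels(eff, spec$dims))
  r0 <- null_mean_abs_r(spec$n_volumes, spec$tr_seconds, spec$band)
  g_raw <- true_regional_g_raw(r_in, n_reg, V, r0)
  truth <- list(loadings = loadings, r_in = r_in, regional_z = atanh(g_raw))
  list(series = series, trace = trace, covariates = covariates, truth = truth)
}

#' Simulate a bounded random-walk motion trace
#'
#' Six cumulative Gaussian random walks (3 translations mm, 3 rotations
#' degrees) with per-step sd `max_mm / 36`, folded back (reflected) into
#' `[-max_mm, max_mm]`. `max_mm = 0` yields an all-zero trace; values of
#' `max_mm` above 2.5 can produce traces violating the 2.5 mm / 2.5
#' degree exclusion rule.
#'
#' @param n_volumes Number of rows (volumes).
#' @param max_mm Reflection bound, mm (and degrees for rotations).
#' @param seed Optional integer seed; `NULL` continues the current RNG
#'   stream.
#' @return `n_volumes x 6` matrix.
#' @export
simulate_motion <- function(n_volumes, max_mm = 1.2, seed = NULL) {
  if (n_volumes < 2L) stop("n_volumes must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  if (max_mm == 0) {
    m <- matrix(0, n_volumes, 6L)
  } else {
    steps <- matrix(stats::rnorm((n_volumes - 1L) * 6L, sd = max_mm / 36),
                    n_volumes - 1L, 6L)
    walk <- rbind(0, apply(steps, 2, cumsum))
    # triangle fold into [-max_mm, max_mm]
    p <- (walk + max_mm) %% (4 * max_mm)
    m <- ifelse(p <= 2 * max_mm, p - max_mm, 3 * max_mm - p)
  }
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}

# random spherical lesion in the requested hemisphere half of the grid
simulate_lesion <- function(spec, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  dims <- spec$dims
  half <- dims[1] %/% 2L
  xr <- if (hemisphere == "left") c(2L, max(2L, half - 1L))
        else c(min(dims[1] - 1L, half + 2L), dims[1] - 1L)
  center <- c(sample(xr[1]:xr[2], 1),
              sample(2:(dims[2] - 1L), 1),
              sample(2:(dims[3] - 1L), 1))
  radius <- stats::runif(1, 1, 2)
  inside <- logical(prod(dims))
  inside[blob_voxels(center, radius, dims)] <- TRUE
  brain_mask(inside, spec$grid)
}

#' Simulate a full cohort
#'
#' Generates all subjects of the three groups with per-subject seeds
#' derived from the master seed, assembles the cohort table (head motion
#' as mean framewise displacement of the post-drop trace; patients get a
#' lesion mask in the lesioned hemisphere, a lesion volume, an illness
#' duration, and clinical scores linear in true regional FCD), and
#' returns the ground truth needed by recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `subjects` (list of `id`, `group`, `series`, `trace`),
#'   `cohort` ([cohort_table()]), `lesions` (named list of
#'   [brain_mask()]s, patients only), `truth` (effect-region voxel
#'   indices and logical mask, per-group expected in-network `r`, score
#'   model, per-subject `regional_z` / loadings table).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  ids <- unlist(lapply(names(spec$n_per_group), function(g)
    sprintf("%s%02d", g, seq_len(spec$n_per_group[[g]]))))
  subjects <- vector("list", length(ids))
  lesions <- list()
  rows <- vector("list", length(ids))
  truth_rows <- vector("list", length(ids))

  z_ref <- nominal_regional_z(spec)
  for (i in seq_along(ids)) {
    id <- ids[i]; group <- groups[i]
    sim <- simulate_subject(spec, group, derive_seed(spec$seed, id))
    subjects[[i]] <- list(id = id, group = group,
                          series = sim$series, trace = sim$trace)
    post_trace <- sim$trace[-seq_len(spec$n_drop), , drop = FALSE]
    row <- data.frame(
      id = id, group = group, age = sim$covariates$age,
      gender = sim$covariates$gender, education = sim$covariates$education,
      head_motion = mean_framewise_displacement(post_trace),
      lesion_volume = NA_real_, duration = NA_real_,
      fma_ue = NA_real_, fma_le = NA_real_, mbi_c = NA_real_,
      stringsAsFactors = FALSE)
    if (group != "HC") {
      # RNG state here continues the subject's stream: still deterministic
      lesion <- simulate_lesion(spec, if (group == "LSS") "left" else "right")
      lesions[[id]] <- lesion
      row$lesion_volume <- lesion_volume_ml(lesion)
      row$duration <- round(stats::runif(1, 3, 36), 1)
      for (sc in names(spec$score_model)) {
        sm <- spec$score_model[[sc]]
        val <- sm[["intercept"]] +
          sm[["slope"]] * (sim$truth$regional_z - z_ref) +
          (if (sm[["noise_sd"]] > 0) stats::rnorm(1, 0, sm[["noise_sd"]]) else 0)
        # instrument-range winsorization; the defaults leave wide margins,
        # so this is a safety net that essentially never engages
        rng <- SCORE_RANGES[[sc]]
        row[[sc]] <- min(max(val, rng[1]), rng[2])
      }
    }
    rows[[i]] <- row
    truth_rows[[i]] <- data.frame(id = id, group = group,
                                  loading = sim$truth$loadings[spec$effect_network],
                                  r_in = sim$truth$r_in,
                                  regional_z = sim$truth$regional_z,
                                  stringsAsFactors = FALSE)
  }

  cohort <- cohort_table(do.call(rbind, rows))
  eff_vox <- network_voxels(spec$networks[[spec$effect_network]], spec$dims)
  region <- logical(prod(spec$dims)); region[eff_vox] <- TRUE
  a0 <- spec$networks[[spec$effect_network]]$loading
  expected_r <- vapply(spec$group_effect, function(m) {
    a <- a0 * m; a^2 / (a^2 + spec$noise_sd^2)
  }, numeric(1))
  truth <- list(effect_voxels = eff_vox, effect_region = region,
                expected_r = expected_r, score_model = spec$score_model,
                z_ref = z_ref, subjects = do.call(rbind, truth_rows))
  list(subjects = subjects, cohort = cohort, lesions = lesions,
       truth = truth, spec = spec)
}
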