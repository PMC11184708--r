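# Gaussian-random-field cluster-level inference: smoothness estimation
# from model residuals, resel counting over the mask lattice,
# Euler-characteristic cluster expectations, and the Friston-style
# cluster-extent tail probability.

#' Estimate map smoothness from model residuals
#'
#' Residual maps are normalized per voxel to unit sum of squares across
#' maps; for each axis the mean squared derivative of the normalized
#' residual field over adjacent in-mask voxel pairs estimates the
#' roughness `lambda_k`, giving `FWHM_k = sqrt(4 ln 2 / lambda_k)` voxels
#' (through the Gaussian autocorrelation `rho = 1 - g/2`,
#' `lambda = -2 ln rho`, exact for a Gaussian ACF and equal to `g` to
#' first order). Resels are in-mask voxels divided by the FWHM product.
#'
#' @param residuals `N x V_in` matrix of residual maps (N >= 2) over
#'   in-mask voxels.
#' @param mask The [brain_mask()] the maps live on.
#' @return A list of class `smoothness_estimate`: `fwhm_mm`, `fwhm_vox`
#'   (per axis), `resels`, `resel_counts` (R0..R3 over the mask lattice).
#' @export
estimate_smoothness <- function(residuals, mask) {
  if (nrow(residuals) < 2L) stop("need at least 2 residual maps")
  grid <- mask$grid
  inside <- mask$inside
  if (ncol(residuals) != sum(inside)) stop("residual columns != in-mask voxels")
  ss <- colSums(residuals^2)
  ss[ss == 0] <- 1
  e <- sweep(residuals, 2, sqrt(ss), "/")
  dims <- grid$dims
  # scatter normalized residuals into full-grid arrays per axis pass
  full <- matrix(0, nrow(residuals), prod(dims))
  full[, which(inside)] <- e
  inside_arr <- array(inside, dim = dims)
  lambda <- numeric(3)
  for (ax in 1:3) {
    n_ax <- dims[ax]
    idx_lo <- slice_index(dims, ax, 1:(n_ax - 1))
    idx_hi <- slice_index(dims, ax, 2:n_ax)
    ok <- inside[idx_lo] & inside[idx_hi]
    if (!any(ok)) { lambda[ax] <- NA_real_; next }
    d <- full[, idx_hi[ok], drop = FALSE] - full[, idx_lo[ok], drop = FALSE]
    g <- mean(colSums(d^2))
    rho <- min(max(1 - g / 2, 1e-6), 1 - 1e-12)
    lambda[ax] <- -2 * log(rho)
  }
  lambda[is.na(lambda)] <- mean(lambda, na.rm = TRUE)
  fwhm_vox <- sqrt(4 * log(2) / lambda)
  fwhm_mm <- fwhm_vox * grid$voxel_size
  structure(list(fwhm_mm = fwhm_mm, fwhm_vox = fwhm_vox,
                 resels = sum(inside) / prod(fwhm_vox),
                 resel_counts = resel_counts(inside_arr, fwhm_vox)),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("<smoothness fwhm = (%.2f, %.2f, %.2f) mm, %.1f resels>\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3], x$resels))
  invisible(x)
}

# linear indices of all voxels whose coordinate along `ax` lies in `vals`
slice_index <- function(dims, ax, vals) {
  coord <- lapply(seq_along(dims), function(a) seq_len(dims[a]))
  coord[[ax]] <- vals
  g <- as.matrix(expand.grid(coord))
  as.integer(g[, 1] + dims[1] * (g[, 2] - 1L) + dims[1] * dims[2] * (g[, 3] - 1L))
}

# Worsley lattice resel counts for a 3D mask, given per-axis FWHM in voxels
resel_counts <- function(inside_arr, fwhm_vox) {
  d <- dim(inside_arr)
  A <- inside_arr
  cnt <- function(x) sum(x)
  P <- cnt(A)
  Ex <- cnt(A[-d[1], , , drop = FALSE] & A[-1, , , drop = FALSE])
  Ey <- cnt(A[, -d[2], , drop = FALSE] & A[, -1, , drop = FALSE])
  Ez <- cnt(A[, , -d[3], drop = FALSE] & A[, , -1, drop = FALSE])
  Fxy <- cnt(A[-d[1], -d[2], , drop = FALSE] & A[-1, -d[2], , drop = FALSE] &
             A[-d[1], -1, , drop = FALSE] & A[-1, -1, , drop = FALSE])
  Fxz <- cnt(A[-d[1], , -d[3], drop = FALSE] & A[-1, , -d[3], drop = FALSE] &
             A[-d[1], , -1, drop = FALSE] & A[-1, , -1, drop = FALSE])
  Fyz <- cnt(A[, -d[2], -d[3], drop = FALSE] & A[, -1, -d[3], drop = FALSE] &
             A[, -d[2], -1, drop = FALSE] & A[, -1, -1, drop = FALSE])
  C <- cnt(A[-d[1], -d[2], -d[3], drop = FALSE] & A[-1, -d[2], -d[3], drop = FALSE] &
           A[-d[1], -1, -d[3], drop = FALSE] & A[-d[1], -d[2], -1, drop = FALSE] &
           A[-1, -1, -d[3], drop = FALSE] & A[-1, -d[2], -1, drop = FALSE] &
           A[-d[1], -1, -1, drop = FALSE] & A[-1, -1, -1, drop = FALSE])
  r <- 1 / fwhm_vox
  c(R0 = P - (Ex + Ey + Ez) + (Fxy + Fxz + Fyz) - C,
    R1 = r[1] * (Ex - Fxy - Fxz + C) + r[2] * (Ey - Fxy - Fyz + C) +
         r[3] * (Ez - Fxz - Fyz + C),
    R2 = r[1] * r[2] * (Fxy - C) + r[1] * r[3] * (Fxz - C) +
         r[2] * r[3] * (Fyz - C),
    R3 = r[1] * r[2] * r[3] * C)
}

# Euler-characteristic densities of a unit Gaussian field at threshold u
ec_density <- function(u) {
  c(stats::pnorm(u, lower.tail = FALSE),
    sqrt(4 * log(2)) / (2 * pi) * exp(-u^2 / 2),
    (4 * log(2)) / (2 * pi)^1.5 * u * exp(-u^2 / 2),
    (4 * log(2))^1.5 / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2))
}

# 26-connectivity connected components among `active` voxels (logical
# over the full grid); returns a list of integer vectors of linear indices
connected_components_26 <- function(active, dims) {
  idx <- which(active)
  if (!length(idx)) return(list())
  lab <- integer(length(active))
  lab[idx] <- -1L  # active, unlabeled
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comps <- list()
  nxyz <- dims
  for (start in idx) {
    if (lab[start] != -1L) next
    comp_id <- length(comps) + 1L
    queue <- start
    lab[start] <- comp_id
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      ijk <- arrayInd(v, nxyz)
      nb <- sweep(offs, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= nxyz[1] &
            nb[, 2] >= 1 & nb[, 2] <= nxyz[2] &
            nb[, 3] >= 1 & nb[, 3] <= nxyz[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + nxyz[1] * (nb[, 2] - 1L) + nxyz[1] * nxyz[2] * (nb[, 3] - 1L)
      new <- lin[lab[lin] == -1L]
      if (length(new)) {
        lab[new] <- comp_id
        queue <- c(queue, new)
      }
    }
    comps[[comp_id]] <- sort(queue)
  }
  comps
}

# stat values -> equivalent Gaussian z (upper tail)
stat_to_z <- function(values, kind, df) {
  p <- switch(kind,
    F = stats::pf(values, df[1], df[2], lower.tail = FALSE),
    t = stats::pt(values, df[1], lower.tail = FALSE),
    z = stats::pnorm(values, lower.tail = FALSE),
    stop("unknown stat kind: ", kind))
  stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
}

#' GRF cluster-level correction
#'
#' Converts the stat map to an equivalent Gaussian field by probability
#' transform, thresholds it at the cluster-defining voxel level (upper
#' tail at `voxel_p` for F maps; `voxel_p / 2` per tail with separate
#' positive and negative clusters for two-tailed t maps), forms clusters
#' under 26-connectivity, and assigns each cluster a family-wise
#' cluster-level p from stationary Gaussian-field theory: expected
#' cluster count `E[m]` from the Euler-characteristic densities over the
#' mask's resel counts, extent tail `P(n >= k) = exp(-beta k^(2/3))`
#' with `beta = (gamma(5/2) / E[n])^(2/3)`, and
#' `p_FWE = 1 - exp(-E[m] P(n >= k))`. Clusters with `p_FWE` below the
#' cluster threshold are returned (for two-tailed t maps each tail is
#' tested at `cluster_p / 2`).
#'
#' @param stat A `stat_map` from [ancova_f_map()] or [posthoc_pairwise()].
#' @param smoothness A [estimate_smoothness()] result from the same
#'   model's residuals.
#' @param mask The analysis [brain_mask()].
#' @param voxel_p Cluster-defining voxel-level p (default 0.01).
#' @param cluster_p Cluster-level FWE threshold (default 0.05).
#' @param two_tailed Split the voxel threshold across both tails
#'   (default `TRUE` for t maps; F maps are always upper-tail).
#' @return A list of clusters, each a list with `voxels` (grid linear
#'   indices), `size`, `peak_stat`, `peak_mm`, `p_fwe`, `sign`.
#' @export
grf_cluster_correct <- function(stat, smoothness, mask,
                                voxel_p = 0.01, cluster_p = 0.05,
                                two_tailed = (stat$kind == "t")) {
  if (any(!is.finite(smoothness$fwhm_vox)) || any(smoothness$fwhm_vox <= 0))
    stop("non-finite smoothness estimate")
  inside_idx <- which(mask$inside)
  if (length(stat$values) != length(inside_idx))
    stop("stat map length != in-mask voxels")
  dims <- mask$grid$dims
  S <- length(inside_idx)
  R <- smoothness$resel_counts

  tails <- if (stat$kind == "F" || !two_tailed) {
    list(list(sign = 1, p_th = voxel_p, c_th = cluster_p))
  } else {
    list(list(sign = 1, p_th = voxel_p / 2, c_th = cluster_p / 2),
         list(sign = -1, p_th = voxel_p / 2, c_th = cluster_p / 2))
  }

  clusters <- list()
  for (tail in tails) {
    vals <- if (tail$sign > 0) stat$values else -stat$values
    df <- if (stat$kind == "F") stat$df else c(stat$df, NA)
    z <- stat_to_z(vals, stat$kind, df)
    u <- stats::qnorm(tail$p_th, lower.tail = FALSE)
    supra <- z > u
    if (!any(supra)) next
    active <- logical(prod(dims))
    active[inside_idx[supra]] <- TRUE
    comps <- connected_components_26(active, dims)

    Em <- max(sum(R * ec_density(u)), 1e-12)
    En <- max(S * stats::pnorm(u, lower.tail = FALSE) / Em, 1e-12)
    beta <- (gamma(2.5) / En)^(2 / 3)
    for (comp in comps) {
      k <- length(comp)
      p_ext <- exp(-beta * k^(2 / 3))
      p_fwe <- 1 - exp(-Em * p_ext)
      if (p_fwe < tail$c_th) {
        pos <- match(comp, inside_idx)
        pk <- pos[which.max(vals[pos])]
        peak_ijk <- arrayInd(inside_idx[pk], dims) - 1L
        peak_mm <- as.vector(mask$grid$affine[1:3, ] %*% c(peak_ijk, 1))
        clusters[[length(clusters) + 1L]] <- list(
          voxels = comp, size = k,
          peak_stat = tail$sign * vals[pk],
          peak_mm = peak_mm, p_fwe = p_fwe, sign = tail$sign)
      }
    }
  }
  clusters[order(vapply(clusters, function(cl) -cl$size, numeric(1)))]
}

#' Tabulate clusters as a data frame
#'
#' @param clusters Result of [grf_cluster_correct()].
#' @return Data frame with size, peak statistic, peak mm coordinates,
#'   cluster-level FWE p and sign (one row per cluster).
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(size = integer(0), peak_stat = numeric(0),
                      peak_x = numeric(0), peak_y = numeric(0),
                      peak_z = numeric(0), p_fwe = numeric(0),
                      sign = integer(0)))
  }
  do.call(rbind, lapply(clusters, function(cl)
    data.frame(size = cl$size, peak_stat = cl$peak_stat,
               peak_x = cl$peak_mm[1], peak_y = cl$peak_mm[2],
               peak_z = cl$peak_mm[3], p_fwe = cl$p_fwe, sign = cl$sign)))
}
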