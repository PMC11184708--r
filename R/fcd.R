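# Distance-dependent functional connectivity density (FCD).
#
# For every in-mask voxel i, the global FCD is the mean absolute Pearson
# correlation between its time series and every other in-mask voxel
# ("weighted" FCD: no correlation threshold, no connection count). The
# short-/long-range split classifies each pair by Euclidean distance
# between voxel centers in mm against a distance criterion d_c (12 mm by
# default; 6 and 18 mm as validation settings). Maps are Fisher
# r-to-z transformed with the raw value clipped at 1 - eps before atanh.

#' Distance partition settings
#'
#' @param criterion_mm Distance criterion d_c in mm; pairs with
#'   `D_ij <= d_c` are short-range, `D_ij > d_c` long-range. 12 mm is the
#'   primary setting, 6 and 18 mm the validation settings.
#' @param eps Clip applied to raw values before `atanh` (default 1e-7).
#' @return An object of class `distance_config`.
#' @export
distance_config <- function(criterion_mm = 12, eps = 1e-7) {
  if (!is.finite(criterion_mm) || criterion_mm <= 0)
    stop("criterion_mm must be positive")
  structure(list(criterion_mm = criterion_mm, eps = eps),
            class = "distance_config")
}

#' Euclidean distance between two mm coordinates
#'
#' @param c_i,c_j Length-3 coordinate triples in mm.
#' @return Distance in mm.
#' @export
pair_distance <- function(c_i, c_j) {
  sqrt(sum((as.double(c_i) - as.double(c_j))^2))
}

#' Fisher r-to-z transform with clipping
#'
#' `atanh(min(v, 1 - eps))`, defined on `[0, 1]`; values of exactly 1
#' (degenerate, perfectly coupled inputs) map to the finite
#' `atanh(1 - eps)`. Signed values in `[-1, 1]` are supported for seed
#' correlation maps (clipped symmetrically).
#'
#' @param v Values in `[-1, 1]`.
#' @param eps Clip width (default 1e-7).
#' @return Transformed values; monotone increasing in `v`.
#' @export
fisher_z <- function(v, eps = 1e-7) {
  if (any(!is.finite(v)) || any(v < -1) || any(v > 1))
    stop("fisher_z is defined on [-1, 1]")
  atanh(pmax(pmin(v, 1 - eps), -1 + eps))
}

# Cache of distance partitions keyed by (grid, mask, criterion): cohorts
# share one grid, so the O(V^2) distance classification is done once.
.partition_cache <- new.env(parent = emptyenv())

# n_short per in-mask voxel, plus the full V x V short-pair indicator
# (diagonal FALSE) when the mask is small enough to keep it around
short_partition <- function(grid, mask, criterion_mm, keep_matrix_max = 3000L) {
  idx <- which(mask$inside)
  key <- paste(paste(grid$dims, collapse = ","),
               paste(signif(grid$affine, 8), collapse = ","),
               signif(criterion_mm, 8), length(idx), sum(as.double(idx)),
               sum(as.double(idx)^2) %% 1e15, sep = "|")
  hit <- .partition_cache[[key]]
  if (!is.null(hit)) return(hit)
  coords <- voxel_coordinates(grid, mask)
  V <- nrow(coords)
  d2c <- criterion_mm^2 + 1e-8
  sq <- rowSums(coords^2)
  if (V <= keep_matrix_max) {
    D2 <- outer(sq, rep(1, V)) + outer(rep(1, V), sq) - 2 * tcrossprod(coords)
    short <- D2 <= d2c
    diag(short) <- FALSE
    out <- list(n_short = colSums(short), short = short)
  } else {
    n_short <- integer(V)
    for (b0 in seq(1L, V, by = 2048L)) {
      cols <- b0:min(b0 + 2047L, V)
      D2 <- outer(sq, rep(1, length(cols))) +
        outer(rep(1, V), sq[cols]) - 2 * coords %*% t(coords[cols, , drop = FALSE])
      short <- D2 <= d2c
      short[cbind(cols, seq_along(cols))] <- FALSE
      n_short[cols] <- colSums(short)
    }
    out <- list(n_short = n_short, short = NULL)
  }
  # bounded cache: drop everything if it grows past a few entries
  if (length(ls(.partition_cache)) > 8L)
    rm(list = ls(.partition_cache), envir = .partition_cache)
  .partition_cache[[key]] <- out
  out
}

#' Compute gFCD/sFCD/lFCD maps for one subject
#'
#' Pearson correlations are computed between every pair of in-mask voxels
#' in column blocks (results are independent of `block_size`), classified
#' as short- or long-range by the Euclidean distance between voxel
#' centers, and summarized per voxel as the mean absolute correlation over
#' all other voxels (`g_raw`), the short set (`s_raw`), and the long set
#' (`l_raw`). Zero-variance voxels are dropped from the mask with a
#' warning. `z` maps are `atanh(min(raw, 1 - eps))`.
#'
#' @param series A preprocessed [series_4d()].
#' @param mask A [brain_mask()] on the series grid.
#' @param config A [distance_config()].
#' @param block_size Number of voxels per block (memory/speed trade-off).
#' @param partition_matrix_max Largest mask size for which the full
#'   pairwise distance partition is cached as a matrix; above it the
#'   partition is recomputed blockwise.
#' @return An object of class `fcd_maps`: per in-mask voxel vectors
#'   `g_raw, s_raw, l_raw, g_z, s_z, l_z, n_short, n_long`, plus
#'   `voxel_index` (linear indices into the grid), `mask`, and `config`.
#' @export
compute_fcd <- function(series, mask, config = distance_config(),
                        block_size = 512L, partition_matrix_max = 3000L) {
  if (!grid_equal(series$grid, mask$grid))
    stop("mask grid does not match series grid")
  X <- series$data[, mask$inside, drop = FALSE]
  sds <- col_sds(X)
  keep <- sds > 0
  if (!any(keep)) stop("all in-mask voxels have zero temporal variance")
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance voxel(s) dropped from the mask")
    inside <- mask$inside
    inside[which(inside)[!keep]] <- FALSE
    mask <- brain_mask(inside, mask$grid)
    X <- X[, keep, drop = FALSE]
  }
  Tn <- nrow(X)
  V <- ncol(X)
  if (V < 2L) stop("need at least 2 usable in-mask voxels")
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, col_sds(X), "/")
  coords <- voxel_coordinates(series$grid, mask)
  d2c <- config$criterion_mm^2
  sq <- rowSums(coords^2)

  g_sum <- numeric(V); s_sum <- numeric(V)
  part <- short_partition(series$grid, mask, config$criterion_mm,
                          keep_matrix_max = partition_matrix_max)
  n_short <- part$n_short
  if (!is.null(part$short)) {
    # small-mask fast path: the full V x V partition is cached per
    # (grid, mask, criterion), and one symmetric crossprod suffices
    R <- abs(crossprod(Xs)) / (Tn - 1)
    diag(R) <- 0
    g_sum <- colSums(R)
    s_sum <- colSums(R * part$short)
  } else {
    starts <- seq(1L, V, by = as.integer(block_size))
    for (b0 in starts) {
      b1 <- min(b0 + block_size - 1L, V)
      cols <- b0:b1
      R <- abs(crossprod(Xs, Xs[, cols, drop = FALSE])) / (Tn - 1)
      # squared distances between all voxels and the block voxels
      D2 <- outer(sq, rep(1, length(cols))) +
        outer(rep(1, V), sq[cols]) - 2 * coords %*% t(coords[cols, , drop = FALSE])
      short <- D2 <= d2c + 1e-8   # tolerance guards exact-boundary pairs
      # drop self-pairs from both the global and the short-range sums
      R[cbind(cols, seq_along(cols))] <- 0
      short[cbind(cols, seq_along(cols))] <- FALSE
      g_sum[cols] <- colSums(R)
      s_sum[cols] <- colSums(R * short)
    }
  }
  n_long <- (V - 1L) - n_short
  g_raw <- g_sum / (V - 1)
  s_raw <- ifelse(n_short > 0, s_sum / n_short, 0)
  l_raw <- ifelse(n_long > 0, (g_sum - s_sum) / n_long, 0)
  structure(list(
    g_raw = g_raw, s_raw = s_raw, l_raw = l_raw,
    g_z = fisher_z(pmin(g_raw, 1), config$eps),
    s_z = fisher_z(pmin(s_raw, 1), config$eps),
    l_z = fisher_z(pmin(l_raw, 1), config$eps),
    n_short = n_short, n_long = n_long,
    voxel_index = which(mask$inside), mask = mask, config = config
  ), class = "fcd_maps")
}

#' @export
print.fcd_maps <- function(x, ...) {
  cat(sprintf("<fcd_maps %d voxels, d_c = %g mm; mean g_z = %.3f>\n",
              length(x$g_raw), x$config$criterion_mm, mean(x$g_z)))
  invisible(x)
}

#' Mean in-mask value of an FCD z-map
#'
#' @param values Per-voxel map: a vector over in-mask voxels, or over the
#'   full grid (subset by the mask).
#' @param mask The [brain_mask()] defining the average.
#' @return Arithmetic mean over in-mask voxels.
#' @export
whole_brain_mean <- function(values, mask) {
  n_in <- sum(mask$inside)
  if (length(values) == n_in) return(mean(values))
  if (length(values) == length(mask$inside)) return(mean(values[mask$inside]))
  stop("map length matches neither the mask interior nor the grid")
}

#' Write the six FCD maps of a subject to NIfTI plus a JSON sidecar
#'
#' @param maps An [compute_fcd()] result.
#' @param out_prefix Path prefix; files `<prefix>_{g,s,l}_{raw,z}.nii.gz`
#'   and `<prefix>_meta.json` are written.
#' @return Character vector of paths written, invisibly.
#' @export
write_fcd_maps <- function(maps, out_prefix) {
  grid <- maps$mask$grid
  paths <- character(0)
  for (m in c("g", "s", "l")) for (kind in c("raw", "z")) {
    vals <- numeric(n_voxels(grid))
    vals[maps$voxel_index] <- maps[[paste0(m, "_", kind)]]
    p <- paste0(out_prefix, "_", m, "_", kind, ".nii.gz")
    write_volume(vals, p, grid = grid)
    paths <- c(paths, p)
  }
  meta <- list(criterion_mm = maps$config$criterion_mm, eps = maps$config$eps,
               n_voxels = length(maps$voxel_index),
               mask_checksum = sum(maps$mask$inside * seq_along(maps$mask$inside)))
  mp <- paste0(out_prefix, "_meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
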