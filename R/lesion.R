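# Lesion overlap mapping and lesion volume.

#' Lesion overlap map
#'
#' Sums binary lesion masks voxelwise: the value at a voxel is the number
#' of subjects lesioned there. All masks must share one grid.
#'
#' @param masks List of [brain_mask()]s.
#' @return Integer vector over the grid's linear voxel index, with
#'   attribute `grid`.
#' @export
overlap_map <- function(masks) {
  if (length(masks) < 1L) stop("need at least one mask")
  grid <- masks[[1]]$grid
  counts <- integer(n_voxels(grid))
  for (m in masks) {
    if (!grid_equal(grid, m$grid)) stop("lesion masks are on different grids")
    counts <- counts + as.integer(m$inside)
  }
  attr(counts, "grid") <- grid
  counts
}

#' Lesion volume in millilitres
#'
#' Number of lesioned voxels times the voxel volume in mm^3, divided by
#' 1000.
#'
#' @param mask A [brain_mask()].
#' @return Volume in ml.
#' @export
lesion_volume_ml <- function(mask) {
  sum(mask$inside) * prod(mask$grid$voxel_size) / 1000
}
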