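# Core containers and file I/O: volume geometry, 4D series, masks,
# cohort tables, motion traces.
#
# Internal layout convention: a 3D volume is stored as a vector over the
# linear voxel index with the first axis fastest (NIfTI on-disk order); a
# 4D series is a T x V matrix (rows = time points, columns = voxels), which
# keeps every temporal operation a plain matrix operation.

#' Volume geometry
#'
#' A `volume_grid` couples the array dimensions of a volume with the 4x4
#' affine mapping *0-based* voxel indices `(i, j, k, 1)` to mm coordinates
#' (RAS+ for standard-space data). Voxel size is derived from the affine
#' column norms.
#'
#' @param dims Integer triple `(nx, ny, nz)`, all positive.
#' @param affine 4x4 invertible matrix; bottom row `(0, 0, 0, 1)`.
#' @return An object of class `volume_grid` with fields `dims`, `affine`,
#'   `voxel_size`.
#' @export
volume_grid <- function(dims, affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims <= 0L)) stop("dims must be 3 positive integers")
  if (is.null(affine)) affine <- diag(4)
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) || !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps)
    stop("affine is not invertible")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  structure(list(dims = dims, affine = affine, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %dx%dx%d, voxels %.3gx%.3gx%.3g mm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-5) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) <= tol
}

n_voxels <- function(grid) prod(grid$dims)

#' 4D BOLD series
#'
#' @param data `T x V` numeric matrix (rows = time points, columns =
#'   voxels in linear index order, first spatial axis fastest), or a 4D
#'   array which is reshaped accordingly.
#' @param grid A [volume_grid()] whose voxel count matches `ncol(data)`.
#' @param tr Repetition time, seconds.
#' @return An object of class `series_4d` with fields `grid`, `data`, `tr`.
#' @export
series_4d <- function(data, grid, tr = 2.0) {
  if (is.array(data) && length(dim(data)) == 4L) {
    dims <- dim(data)
    data <- t(matrix(data, nrow = prod(dims[1:3]), ncol = dims[4]))
  }
  if (!is.matrix(data)) stop("data must be a T x V matrix or 4D array")
  if (ncol(data) != n_voxels(grid))
    stop("data has ", ncol(data), " voxels but grid expects ", n_voxels(grid))
  if (nrow(data) < 2L) stop("a series needs at least 2 time points")
  if (!all(is.finite(data))) stop("series data must be finite")
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive")
  structure(list(grid = grid, data = data, tr = tr), class = "series_4d")
}

#' @export
print.series_4d <- function(x, ...) {
  cat(sprintf("<series_4d %d volumes, TR %.3g s on %dx%dx%d grid>\n",
              nrow(x$data), x$tr, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

n_volumes <- function(series) nrow(series$data)

# T x V matrix -> 4D array in grid layout
series_array <- function(series) {
  array(t(series$data), dim = c(series$grid$dims, nrow(series$data)))
}

#' Binary analysis mask
#'
#' @param inside Logical vector over linear voxel index (or 3D array).
#' @param grid The [volume_grid()] the mask lives on.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(inside, grid) {
  if (is.array(inside)) inside <- as.vector(inside)
  inside <- as.logical(inside)
  if (length(inside) != n_voxels(grid))
    stop("mask length ", length(inside), " does not match grid (", n_voxels(grid), ")")
  inside[is.na(inside)] <- FALSE
  if (sum(inside) < 2L) stop("mask must contain at least 2 voxels")
  structure(list(grid = grid, inside = inside), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask %d/%d voxels inside>\n", sum(x$inside), length(x$inside)))
  invisible(x)
}

#' Read a 4D series from a NIfTI-1 file
#'
#' @param path `.nii`/`.nii.gz` file holding a 4D image.
#' @param tr Repetition time override (seconds); defaults to the header
#'   value, or 2.0 if the header stores none.
#' @return A [series_4d()].
#' @export
read_series <- function(path, tr = NULL) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 4L)
    stop("expected a 4D image, got ", length(dim(img$data)), "D: ", path)
  grid <- volume_grid(dim(img$data)[1:3], img$affine)
  if (is.null(tr)) tr <- if (is.finite(img$tr)) img$tr else 2.0
  series_4d(img$data, grid, tr = tr)
}

#' Write a 4D series to NIfTI-1
#' @param series A [series_4d()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param datatype Storage type, see [write_nifti()].
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, datatype = "float32") {
  write_nifti(series_array(series), series$grid$affine, path,
              tr = series$tr, datatype = datatype)
}

#' Read a binary mask from NIfTI-1
#' @param path 3D NIfTI file; nonzero voxels are inside.
#' @return A [brain_mask()].
#' @export
read_mask <- function(path) {
  img <- read_nifti(path)
  if (length(dim(img$data)) != 3L)
    stop("expected a 3D mask image: ", path)
  grid <- volume_grid(dim(img$data), img$affine)
  brain_mask(img$data != 0, grid)
}

#' Write a mask (or any 3D map) to NIfTI-1
#' @param x A `brain_mask`, or a numeric vector/3D array of per-voxel values.
#' @param grid Required when `x` is a bare vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "brain_mask")) {
    write_nifti(array(as.integer(x$inside), dim = x$grid$dims),
                x$grid$affine, path, datatype = "uint8")
  } else {
    if (is.null(grid)) stop("grid is required for bare per-voxel values")
    vals <- if (is.array(x)) as.vector(x) else as.vector(x)
    if (length(vals) != n_voxels(grid)) stop("value length does not match grid")
    write_nifti(array(as.double(vals), dim = grid$dims), grid$affine, path,
                datatype = "float64")
  }
  invisible(path)
}

#' mm coordinates of in-mask voxels
#'
#' Applies the grid affine to every in-mask voxel index (0-based, per the
#' NIfTI convention) in ascending linear-index order (first axis fastest),
#' yielding the stereotaxic coordinates used for the Euclidean distance
#' partition.
#'
#' @param grid A [volume_grid()].
#' @param mask A [brain_mask()] on the same grid; `NULL` for all voxels.
#' @return `V_in x 3` matrix of mm coordinates.
#' @export
voxel_coordinates <- function(grid, mask = NULL) {
  if (!is.null(mask)) {
    if (!grid_equal(grid, mask$grid)) stop("mask grid does not match volume grid")
    idx <- which(mask$inside)
  } else {
    idx <- seq_len(n_voxels(grid))
  }
  ijk <- arrayInd(idx, grid$dims) - 1L   # 0-based voxel indices
  xyz <- cbind(ijk, 1) %*% t(grid$affine[1:3, ])
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

# ---- cohort table ----------------------------------------------------------

COHORT_GROUPS <- c("LSS", "RSS", "HC")
SCORE_RANGES <- list(fma_ue = c(0, 66), fma_le = c(0, 34), mbi_c = c(0, 100))
PATIENT_COLS <- c("lesion_volume", "duration", "fma_ue", "fma_le", "mbi_c")

#' Validate a cohort table
#'
#' Checks group labels, gender coding, and clinical score ranges
#' (FMA-UE 0-66, FMA-LE 0-34, MBI-C 0-100). Patient-only fields may be
#' `NA` for HC rows (and are forced to `NA` there).
#'
#' @param df Data frame with columns `id`, `group`, `age`, `gender`,
#'   `education`, `head_motion` and optionally the patient columns
#'   `lesion_volume`, `duration`, `fma_ue`, `fma_le`, `mbi_c`.
#' @return The validated data frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  req <- c("id", "group", "age", "gender", "education", "head_motion")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort table lacks columns: ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$group <- as.character(df$group)
  bad <- which(!df$group %in% COHORT_GROUPS)
  if (length(bad))
    stop("row ", bad[1], " (id ", df$id[bad[1]], "): unknown group label '",
         df$group[bad[1]], "'")
  bad <- which(!df$gender %in% c("male", "female"))
  if (length(bad))
    stop("row ", bad[1], " (id ", df$id[bad[1]], "): gender must be male/female")
  for (col in PATIENT_COLS) if (!col %in% names(df)) df[[col]] <- NA_real_
  for (col in c("age", "education", "head_motion", PATIENT_COLS))
    df[[col]] <- as.numeric(df[[col]])
  df[df$group == "HC", PATIENT_COLS] <- NA_real_
  for (sc in names(SCORE_RANGES)) {
    rng <- SCORE_RANGES[[sc]]
    bad <- which(!is.na(df[[sc]]) & (df[[sc]] < rng[1] | df[[sc]] > rng[2]))
    if (length(bad))
      stop("row ", bad[1], " (id ", df$id[bad[1]], "): ", sc, " = ",
           df[[sc]][bad[1]], " outside [", rng[1], ", ", rng[2], "]")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from tab-separated text
#' @param path TSV file with a header row naming the cohort fields.
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohort_table(df)
}

#' Write a cohort table to tab-separated text
#' @param cohort A [cohort_table()] (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

# ---- motion traces ---------------------------------------------------------

#' Read a 6-column rigid-body motion trace
#'
#' Plain-text file, one row per volume: 3 translations (mm) then 3
#' rotations (degrees).
#'
#' @param path Whitespace-delimited text file.
#' @return `n_volumes x 6` numeric matrix with columns
#'   `trans_x..trans_z, rot_x..rot_z`.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns, found ", ncol(m))
  dimnames(m) <- list(NULL, c("trans_x", "trans_y", "trans_z",
                              "rot_x", "rot_y", "rot_z"))
  m
}

#' Write a motion trace
#' @param trace `n x 6` matrix (translations mm, rotations degrees).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion <- function(trace, path) {
  utils::write.table(format(trace, digits = 10, trim = TRUE), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# fast column standard deviations (denominator n - 1)
col_sds <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
}
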