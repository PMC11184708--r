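# Minimal NIfTI-1 reader/writer.
#
# The package only needs single-file .nii/.nii.gz volumes with a plain
# scalar datatype, which is what every tool in this analysis chain emits.
# Header is the fixed 348-byte NIfTI-1 struct; gzip is handled by R's
# gzfile() connection (which reads uncompressed files transparently).

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE, name = "uint8"),
  `4`   = list(what = "integer", size = 2, signed = TRUE,  name = "int16"),
  `8`   = list(what = "integer", size = 4, signed = TRUE,  name = "int32"),
  `16`  = list(what = "double",  size = 4, signed = TRUE,  name = "float32"),
  `64`  = list(what = "double",  size = 8, signed = TRUE,  name = "float64")
)

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) into an R array
#' together with its voxel-to-mm affine. The affine is taken from the sform
#' when `sform_code > 0`, else from the qform quaternion, else from
#' `pixdim`. Data are returned with the NIfTI on-disk axis order (first
#' index fastest), scaled by `scl_slope`/`scl_inter` when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (array of 3 or 4 dimensions),
#'   `affine` (4x4 matrix, maps 0-based voxel indices to mm), `pixdim`
#'   (voxel dimensions, mm), and `tr` (repetition time in seconds when the
#'   file stores one, else `NA`).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("malformed NIfTI header (truncated): ", path)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("malformed NIfTI header (sizeof_hdr != 348): ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "integer", n = n, size = 4, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4, endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI header (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported: ", path)

  dim0 <- rd_i16(40, 8)
  ndim <- dim0[1]
  if (ndim < 3 || ndim > 4) stop("expected a 3D or 4D image, got ", ndim, "D: ", path)
  dims <- dim0[2:(1 + ndim)]
  datatype <- rd_i16(70, 1)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  qform_code <- rd_i16(252, 1)
  sform_code <- rd_i16(254, 1)

  if (sform_code > 0) {
    srow <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4))
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    q <- rd_f32(256, 6) # b c d, qoffset x y z
    affine <- .quaternion_affine(q[1], q[2], q[3], q[4:6],
                                 pixdim[2:4], qfac = pixdim[1])
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }

  # skip any extension bytes between the header and the data
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n_vals <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vals, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vals) stop("malformed NIfTI (truncated data): ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  tr <- if (ndim == 4 && is.finite(pixdim[5]) && pixdim[5] > 0) pixdim[5] else NA_real_
  list(data = array(vals, dim = dims), affine = affine,
       pixdim = pixdim[2:(1 + ndim)], tr = tr)
}

# Build an affine from the NIfTI qform quaternion (b, c, d), offsets and
# pixdim; qfac flips the z column when -1.
.quaternion_affine <- function(b, c, d, offset, pixdim, qfac = 1) {
  a2 <- 1 - b * b - c * c - d * d
  a <- sqrt(max(a2, 0))
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c - a * d),         2 * (b * d + a * c),
    2 * (b * c + a * d),           a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
    2 * (b * d - a * c),           2 * (c * d + a * b),         a * a + d * d - b * b - c * c
  ), nrow = 3, byrow = TRUE)
  if (!is.finite(qfac) || qfac == 0) qfac <- 1
  R <- R %*% diag(c(pixdim[1], pixdim[2], pixdim[3] * qfac))
  rbind(cbind(R, offset), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D array as a single-file NIfTI-1 volume. The affine is
#' stored in the sform (code 2) and mirrored into pixdim; the qform is left
#' unset. Gzip compression is chosen from the file extension.
#'
#' @param data Numeric array with 3 or 4 dimensions.
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel indices).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param tr Repetition time in seconds, stored in `pixdim[4]` for 4D data.
#' @param datatype `"float32"` (default), `"float64"`, `"int16"`, or
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, tr = NA_real_,
                        datatype = c("float32", "float64", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L, uint8 = 2L)
  dt <- NIFTI_DATATYPES[[as.character(code)]]
  dims <- dim(data)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L))
    stop("data must be a 3D or 4D array")
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  ndim <- length(dims)
  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(1, voxdim, rep(1, 4))
  if (ndim == 4 && is.finite(tr)) pixdim[5] <- tr

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw(36L)                                    # data_type..dim_info
  w_i16(c(ndim, dims, rep(1L, 7 - ndim)))       # dim[8]
  w_f32(c(0, 0, 0))                             # intent_p1..p3
  w_i16(0L)                                     # intent_code
  w_i16(code)                                   # datatype
  w_i16(8L * dt$size)                           # bitpix
  w_i16(0L)                                     # slice_start
  w_f32(pixdim)                                 # pixdim[8]
  w_f32(352)                                    # vox_offset
  w_f32(c(1, 0))                                # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                          # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  w_f32(0)                                      # toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw(104L)                                   # descrip[80] + aux_file[24]
  w_i16(c(0L, 2L))                              # qform_code, sform_code
  w_f32(rep(0, 6))                              # quatern b c d, qoffset x y z
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                                    # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)    # magic
  w_raw(4L)                                     # extension flag

  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
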