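## Minimal NIfTI-1 I/O.
##
## None of the pre-installed R packages reads NIfTI, so the package carries a
## small single-file reader/writer restricted to what the pipeline needs:
## 3D volumes, common datatypes, spacing in pixdim, identity-orientation sform.
## Affines beyond a diagonal voxel-size matrix are carried through untouched
## on read (stored as an attribute) but never interpreted: all computations
## are voxel-space.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

#' Write a 3D volume as NIfTI-1
#'
#' @param x 3D numeric/integer/logical array.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param datatype one of `"auto"`, `"uint8"`, `"int16"`, `"int32"`,
#'   `"float32"`, `"float64"`. `"auto"` picks `int32` for integer/logical
#'   input and `float64` otherwise.
#' @return `path`, invisibly.
#' @export
nifti_write <- function(x, path, spacing = c(1, 1, 1), datatype = "auto") {
  stopifnot(length(dim(x)) == 3L, length(spacing) == 3L, all(spacing > 0))
  if (datatype == "auto")
    datatype <- if (is.logical(x) || is.integer(x)) "int32" else "float64"
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f4 <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348L)                    # sizeof_hdr
  w_raw(35L)                    # data_type, db_name, extents, session_error, regular
  w_raw(1L)                     # dim_info
  w_i2(c(3L, dim(x), 1L, 1L, 1L, 1L))  # dim[8]
  w_f4(c(0, 0, 0))              # intent_p1..p3
  w_i2(0L)                      # intent_code
  w_i2(dt)                      # datatype
  w_i2(NIFTI_BITPIX[[as.character(dt)]])  # bitpix
  w_i2(0L)                      # slice_start
  w_f4(c(1, spacing, 0, 0, 0, 0))  # pixdim[8], qfac = 1
  w_f4(352)                     # vox_offset
  w_f4(1); w_f4(0)              # scl_slope, scl_inter
  w_i2(0L); w_raw(1L)           # slice_end, slice_code
  writeBin(as.raw(2L), con)     # xyzt_units = mm
  w_f4(c(0, 0, 0, 0))           # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))               # glmax, glmin
  w_raw(80L); w_raw(24L)        # descrip, aux_file
  w_i2(0L); w_i2(1L)            # qform_code, sform_code
  w_f4(c(0, 0, 0, 0, 0, 0))     # quatern_b/c/d, qoffset_x/y/z
  w_f4(c(spacing[1], 0, 0, 0))  # srow_x
  w_f4(c(0, spacing[2], 0, 0))  # srow_y
  w_f4(c(0, 0, spacing[3], 0))  # srow_z
  w_raw(16L)                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                     # extension flag

  if (dt %in% c(2L, 4L, 8L)) {
    size <- NIFTI_BITPIX[[as.character(dt)]] / 8L
    writeBin(as.integer(x), con, size = size, endian = "little")
  } else {
    size <- NIFTI_BITPIX[[as.character(dt)]] / 8L
    writeBin(as.double(x), con, size = size, endian = "little")
  }
  invisible(path)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a 3D array with attributes `spacing` (mm per axis) and `affine`
#'   (4x4 sform-style matrix, identity-orientation if absent).
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  r_i4 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  r_i2 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  r_f4 <- function(n) readBin(con, "double", n, size = 4L, endian = "little")

  hdr <- r_i4(1L)
  if (!identical(hdr, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)
  dims <- r_i2(8L)
  r_f4(3L); r_i2(1L)
  dt <- r_i2(1L); r_i2(2L)
  pixdim <- r_f4(8L)
  vox_offset <- r_f4(1L)
  scl_slope <- r_f4(1L); scl_inter <- r_f4(1L)
  readBin(con, "raw", 132L)                  # slice_end through aux_file
  r_i2(2L); r_f4(6L)
  srow <- rbind(r_f4(4L), r_f4(4L), r_f4(4L))
  readBin(con, "raw", 16L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) stop("unsupported NIfTI magic in ", path)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  nd <- dims[1]
  if (nd < 3L) stop("expected a 3D volume in ", path)
  shape <- dims[2:4]
  n <- prod(shape)
  vals <- switch(as.character(dt),
    `2`  = readBin(con, "integer", n, size = 1L, signed = FALSE),
    `4`  = readBin(con, "integer", n, size = 2L, endian = "little"),
    `8`  = readBin(con, "integer", n, size = 4L, endian = "little"),
    `16` = readBin(con, "double",  n, size = 4L, endian = "little"),
    `64` = readBin(con, "double",  n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code ", dt, " in ", path))
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, dim = shape)
  affine <- rbind(srow, c(0, 0, 0, 1))
  if (all(affine[1:3, 1:3] == 0))
    affine[1:3, 1:3] <- diag(pixdim[2:4])
  attr(out, "spacing") <- abs(pixdim[2:4])
  attr(out, "affine") <- affine
  out
}

## internal: voxel volume in mm^3
voxel_volume <- function(spacing) prod(spacing)

## internal: coerce to logical without dropping array dims
as_mask <- function(x) array(as.logical(x), dim(x))

## internal: shape agreement guard used across modules
check_same_shape <- function(...) {
  vols <- list(...)
  d <- lapply(vols, dim)
  if (length(unique(vapply(d, paste, "", collapse = "x"))) != 1L)
    stop("volume shapes disagree: ",
         paste(vapply(d, paste, "", collapse = "x"), collapse = " vs "))
  invisible(TRUE)
}
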