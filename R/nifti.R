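#' Minimal NIfTI-1 input/output
#'
#' A small, dependency-free reader and writer for uncompressed and gzipped
#' single-file NIfTI-1 volumes (`.nii`, `.nii.gz`). Little-endian files are
#' written; both endiannesses are read. Supported on-disk datatypes: uint8 (2),
#' int16 (4), int32 (8), float32 (16), float64 (64). `scl_slope`/`scl_inter`
#' scaling is applied on read.
#'
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti()` returns a list with elements `data` (numeric array),
#'   `affine` (4x4 voxel-to-world matrix, from the sform when present, else the
#'   qform, else a pixdim diagonal), `pixdim` (numeric, grid spacings) and
#'   `tr` (repetition time in seconds taken from `pixdim[4]`, `NA` if absent).
#' @name nifti_io
NULL

NIFTI_HDR_SIZE <- 348L

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

open_nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- open_nifti_con(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = NIFTI_HDR_SIZE)
  if (length(hdr_raw) < NIFTI_HDR_SIZE) stop("truncated NIfTI header in ", path)

  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)], "integer",
                                     n = n, size = 4, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)], "double",
                                     n = n, size = 4, endian = endian)

  dim_field <- rd_i16(40L, 8L)
  ndim <- dim_field[1]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0]: ", ndim)
  dims <- dim_field[2:(1 + ndim)]
  datatype <- rd_i16(70L, 1L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  quatern <- rd_f32(256L, 3L)
  qoffset <- rd_f32(268L, 3L)
  srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic string: ", magic)

  n_vox <- prod(dims)
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(as.double(vals), dim = dims)

  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    qform_to_affine(quatern, qoffset, pixdim)
  } else {
    diag(c(abs(pixdim[2:4]), 1))
  }
  tr <- if (ndim >= 4L) pixdim[5] else NA_real_
  if (!is.na(tr) && tr <= 0) tr <- NA_real_
  list(data = data, affine = affine, pixdim = pixdim[2:(1 + ndim)], tr = tr)
}

qform_to_affine <- function(q, offset, pixdim) {
  b <- q[1]; c_ <- q[2]; d <- q[3]
  a2 <- 1 - b^2 - c_^2 - d^2
  a <- if (a2 > 0) sqrt(a2) else 0
  R <- matrix(c(
    a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
    2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
  ), nrow = 3, byrow = TRUE)
  qfac <- if (!is.na(pixdim[1]) && pixdim[1] < 0) -1 else 1
  sp <- c(abs(pixdim[2:3]), qfac * abs(pixdim[4]))
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% diag(sp)
  aff[1:3, 4] <- offset
  aff
}

#' @rdname nifti_io
#' @param data Numeric 3D or 4D array.
#' @param affine 4x4 voxel-to-world matrix written as the sform (and mirrored
#'   into the pixdim spacings).
#' @param tr Repetition time in seconds for 4D data, stored in `pixdim[4]`.
#' @param datatype `"float32"` (default) or `"float64"`.
#' @export
write_nifti <- function(data, path, affine = diag(4), tr = NA_real_,
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L))) {
    stop("write_nifti() expects a 3D or 4D array")
  }
  if (!all(is.finite(data))) stop("non-finite values in data; refusing to write")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  dt_code <- if (datatype == "float32") 16L else 64L
  dt_size <- if (datatype == "float32") 4L else 8L

  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- rep(0, 8)
  pixdim[1] <- 1
  pixdim[2:4] <- spacing
  if (length(dims) == 4L) pixdim[5] <- if (is.na(tr)) 0 else tr

  dim_field <- integer(8)
  dim_field[1] <- length(dims)
  dim_field[2:(1 + length(dims))] <- dims
  dim_field[dim_field == 0L] <- 1L
  dim_field[1] <- length(dims)

  con <- open_nifti_con(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_i8  <- function(x) writeBin(as.integer(x), con, size = 1, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")

  w_i32(348L)                       # sizeof_hdr
  w_i8(rep(0L, 36))                 # data_type[10], db_name[18], extents, session_error, regular, dim_info
  w_i16(dim_field)                  # dim[8]
  w_f32(c(0, 0, 0))                 # intent_p1..p3
  w_i16(0L)                         # intent_code
  w_i16(dt_code)                    # datatype
  w_i16(8L * dt_size)               # bitpix
  w_i16(0L)                         # slice_start
  w_f32(pixdim)                     # pixdim[8]
  w_f32(352)                        # vox_offset
  w_f32(1)                          # scl_slope
  w_f32(0)                          # scl_inter
  w_i16(0L)                         # slice_end
  w_i8(0L)                          # slice_code
  w_i8(10L)                         # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_i8(rep(0L, 104))                # descrip[80] + aux_file[24]
  w_i16(0L)                         # qform_code
  w_i16(1L)                         # sform_code
  w_f32(rep(0, 6))                  # quatern_b/c/d, qoffset_x/y/z
  w_f32(affine[1, ])                # srow_x
  w_f32(affine[2, ])                # srow_y
  w_f32(affine[3, ])                # srow_z
  w_i8(rep(0L, 16))                 # intent_name
  writeBin(charToRaw("n+1"), con)
  w_i8(0L)                          # magic terminator
  w_i8(rep(0L, 4))                  # extension flag
  writeBin(as.double(data), con, size = dt_size, endian = "little")
  invisible(path)
}
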