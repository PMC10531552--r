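# Minimal NIfTI-1 I/O.
#
# The analysis only needs axis-aligned 3D volumes with positive spacing, so
# this layer deliberately supports a restricted slice of the standard:
# single-file .nii / .nii.gz, datatypes uint8 / int16 / int32 / float32 /
# float64, a diagonal sform affine, and scl_slope/scl_inter scaling on read.
# Written files carry both qform (identity quaternion) and a diagonal sform.

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into a 3D
#' array plus grid metadata. Only 3D images are accepted; byte order is
#' auto-detected from the header size field.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (3D array, x/y/z in header order),
#'   `spacing` (mm per axis, from `pixdim`), `origin` (mm, from the sform
#'   translation when `sform_code > 0`, else the qoffset fields) and
#'   `datatype` (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, size, n = 1L) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim8 <- rd(40L, "integer", 2L, 8L)
  ndim <- dim8[1]
  shape <- dim8[2:4]
  if (ndim > 3L && any(dim8[5:(ndim + 1L)] > 1L))
    stop("only 3D images are supported; got dim = ",
         paste(dim8[2:(ndim + 1L)], collapse = "x"))
  if (ndim < 3L) stop("only 3D images are supported")
  datatype <- rd(70L, "integer", 2L)
  spec <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76L, "double", 4L, 8L)
  vox_offset <- rd(108L, "double", 4L)
  scl_slope <- rd(112L, "double", 4L)
  scl_inter <- rd(116L, "double", 4L)
  sform_code <- rd(254L, "integer", 2L)
  srow_x <- rd(280L, "double", 4L, 4L)
  srow_y <- rd(296L, "double", 4L, 4L)
  srow_z <- rd(312L, "double", 4L, 4L)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)

  n_vox <- prod(shape)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  origin <- if (sform_code > 0L) {
    c(srow_x[4], srow_y[4], srow_z[4])
  } else {
    c(rd(268L, "double", 4L), rd(272L, "double", 4L), rd(276L, "double", 4L))
  }
  list(data = array(vals, dim = shape),
       spacing = abs(pixdim[2:4]),
       origin = origin,
       datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array as a little-endian single-file NIfTI-1 image with a
#' diagonal sform affine. Gzip compression is chosen from the file extension.
#'
#' @param data 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm, length 3, strictly positive.
#' @param origin World coordinates of voxel (0,0,0) in mm.
#' @param datatype One of `"float64"`, `"float32"`, `"int16"`, `"uint8"`.
#'   `float64` round-trips doubles bit-exactly.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing, origin = c(0, 0, 0),
                        datatype = "float64") {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  code <- switch(datatype,
                 float64 = 64L, float32 = 16L, int16 = 4L, uint8 = 2L,
                 stop("unsupported datatype: ", datatype))
  spec <- .nifti_datatypes[[as.character(code)]]

  hdr <- raw(348L)
  put <- function(off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <<- b
    hdr
  }
  hdr <- put(0L, 348L, "integer", 4L)
  hdr <- put(40L, as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), "integer", 2L)
  hdr <- put(70L, code, "integer", 2L)
  hdr <- put(72L, spec$bitpix, "integer", 2L)
  hdr <- put(76L, c(1, spacing, 1, 1, 1, 1), "double", 4L)
  hdr <- put(108L, 352, "double", 4L)          # vox_offset
  hdr <- put(112L, c(1, 0), "double", 4L)      # scl_slope, scl_inter
  hdr <- put(252L, 1L, "integer", 2L)          # qform_code
  hdr <- put(254L, 1L, "integer", 2L)          # sform_code
  hdr <- put(256L, c(0, 0, 0), "double", 4L)   # quaternion b,c,d (identity)
  hdr <- put(268L, as.double(origin), "double", 4L)
  hdr <- put(280L, c(spacing[1], 0, 0, origin[1]), "double", 4L)
  hdr <- put(296L, c(0, spacing[2], 0, origin[2]), "double", 4L)
  hdr <- put(312L, c(0, 0, spacing[3], origin[3]), "double", 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))

  vals <- as.vector(data)
  if (code %in% c(2L, 4L, 8L)) {
    vals <- as.integer(round(vals))
  } else {
    vals <- as.double(vals)
  }
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con) # extension flag
  writeBin(vals, con, size = spec$size, endian = "little")
  invisible(path)
}
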