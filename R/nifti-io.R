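# Minimal single-file NIfTI-1 I/O.
#
# Only what the map pipeline needs: 3-D volumes in .nii or .nii.gz, datatypes
# uint8 / int16 / int32 / float32 / float64, little- or big-endian detection
# via sizeof_hdr, scl_slope/scl_inter applied on read, affine taken from the
# sform (srow_x/y/z) with a qform-free fallback to a pixdim-scaled identity.
# No reorientation, ever: voxel order and orientation follow the header.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, name = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  name = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  name = "float64")
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) into a
#' [voxel_map()]. Data are returned as doubles with `scl_slope`/`scl_inter`
#' applied (when `scl_slope != 0`); `NaN` values become `NA`. Only 3-D
#' volumes (or higher-dimensional images whose trailing dims are 1) are
#' supported.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param kind optional label describing what the map holds.
#' @return a [voxel_map()].
#' @export
read_nifti <- function(path, kind = NULL) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    stop("file too short for a NIfTI-1 header: ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path, call. = FALSE)
  }
  int16 <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1):(off + 2L * n)], "integer", n = n, size = 2L,
            endian = endian)
  flt32 <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1):(off + 4L * n)], "double", n = n, size = 4L,
            endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic: ", magic, call. = FALSE)
  if (magic == "ni1")
    stop("two-file (.hdr/.img) NIfTI is not supported", call. = FALSE)
  dim <- int16(40, 8L)
  ndim <- dim[1]
  shape <- dim[2:(ndim + 1)]
  if (any(shape[-(1:3)] > 1L) && ndim > 3L)
    stop("only 3-D volumes are supported", call. = FALSE)
  shape3 <- c(shape, 1L, 1L, 1L)[1:3]
  datatype <- int16(70)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  pixdim <- flt32(76, 8L)
  vox_offset <- flt32(108)
  scl_slope <- flt32(112)
  scl_inter <- flt32(116)
  sform_code <- int16(254)
  srow <- rbind(flt32(280, 4L), flt32(296, 4L), flt32(312, 4L))
  affine <- if (sform_code > 0) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  n_vox <- prod(shape3)
  # header was read from the stream already; skip any extension bytes
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vox)
    stop("truncated NIfTI data section: ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0)
    vals <- vals * scl_slope + scl_inter
  vals[is.nan(vals)] <- NA_real_
  voxel_map(array(vals, dim = shape3), affine = affine, kind = kind)
}

#' Write a [voxel_map()] as a NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 image. Missing values (`NA`) are stored as
#' `NaN`, which requires a floating-point datatype; integer datatypes reject
#' maps containing missing values.
#'
#' @param map a [voxel_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype one of `"float32"` (default), `"float64"`, `"uint8"`,
#'   `"int16"`, `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(map, path, datatype = c("float32", "float64",
                                                "uint8", "int16", "int32")) {
  stopifnot(inherits(map, "voxel_map"))
  datatype <- match.arg(datatype)
  code <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)[datatype]
  dt <- NIFTI_DTYPES[[as.character(code)]]
  vals <- as.vector(map$values)
  if (dt$what == "integer" && anyNA(vals))
    stop("integer datatypes cannot store missing values", call. = FALSE)
  shape <- dim(map$values)
  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wf32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi32(348L)                                   # sizeof_hdr
  wraw(36L)                                    # data_type[10]+db_name[18]+extents+session_error+regular+dim_info
  wi16(c(3L, shape, 1L, 1L, 1L, 1L))           # dim[8]
  wf32(c(0, 0, 0))                             # intent_p1..p3
  wi16(0L)                                     # intent_code
  wi16(code)                                   # datatype
  wi16(8L * dt$size)                           # bitpix
  wi16(0L)                                     # slice_start
  pd <- sqrt(colSums(map$affine[1:3, 1:3]^2))  # voxel sizes from the affine
  wf32(c(1, pd, 1, 1, 1, 1))                   # pixdim[8]
  wf32(352)                                    # vox_offset
  wf32(1)                                      # scl_slope
  wf32(0)                                      # scl_inter
  wi16(0L); wraw(2L)                           # slice_end, slice_code, xyzt_units
  wf32(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  wf32(0)                                      # toffset
  wi32(c(0L, 0L))                              # glmax, glmin
  wraw(104L)                                   # descrip[80] + aux_file[24]
  wi16(c(0L, 2L))                              # qform_code = 0, sform_code = 2
  wf32(rep(0, 6))                              # quatern b,c,d + qoffset x,y,z
  wf32(t(map$affine[1:3, ]))                   # srow_x, srow_y, srow_z
  wraw(16L)                                    # intent_name[16]
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  wraw(1L)                                     # magic terminator
  wraw(4L)                                     # extension flag (none)

  vals[is.na(vals)] <- NaN
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
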