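# Minimal single-file NIfTI-1 (.nii / .nii.gz) input/output.
#
# Only the subset of the format this package produces and consumes is
# supported: 3-D volumes, world-aligned sform (diagonal rotation part),
# little-endian, datatypes uint8 / int16 / int32 / float32 / float64.
# Voxel spacing is carried in pixdim and in the sform diagonal; world
# coordinates follow the package convention world = origin + index *
# spacing (0-based indices).

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nii_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D volume as NIfTI-1
#'
#' Writes a single-file NIfTI-1 image (gzipped when the path ends in
#' `.gz`) with spacing in `pixdim`, an sform encoding spacing and
#' origin, and datatype float32 (or uint8 for logical data).
#'
#' @param vol a [volume3d].
#' @param path output path, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path) {
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  logical_in <- is.logical(vol$data)
  datatype <- if (logical_in) 2L else 16L
  bitpix <- NIFTI_DTYPES[[as.character(datatype)]]$bitpix
  con <- nii_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p1-3, intent_code
  wi(datatype, 2); wi(bitpix, 2); wi(0L, 2)     # datatype, bitpix, slice_start
  wf(c(1, vol$spacing, 0, 0, 0, 0))             # pixdim[8] (qfac 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                             # cal_max, cal_min, slice_duration, toffset
  wi(0L, 4); wi(0L, 4)                          # glmax, glmin
  writeBin(raw(80), con)                        # descrip
  writeBin(raw(24), con)                        # aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code 0, sform_code 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quatern b,c,d, qoffset x,y,z
  wf(c(vol$spacing[1], 0, 0, vol$origin[1]))    # srow_x
  wf(c(0, vol$spacing[2], 0, vol$origin[2]))    # srow_y
  wf(c(0, 0, vol$spacing[3], vol$origin[3]))    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  dat <- as.vector(vol$data)
  if (datatype == 2L) {
    writeBin(as.integer(dat), con, size = 1L, endian = "little")
  } else {
    writeBin(as.numeric(dat), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file 3-D NIfTI-1 image written by [write_nifti()] or a
#' compatible tool. Applies `scl_slope`/`scl_inter` when set; requires a
#' world-aligned (diagonal) sform or, failing that, falls back to
#' `pixdim` spacing with a zero origin.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume3d].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) abort("read_nifti: no such file: ", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 352L)
  if (length(hdr) < 348L) abort("read_nifti: truncated header in ", path)
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L) abort("read_nifti: not a NIfTI-1 file (sizeof_hdr)")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) abort("read_nifti: bad magic '", magic, "'")
  dims <- ri(40L, 2L, 8L)
  if (dims[1] < 3L || any(dims[2:4] < 1L))
    abort("read_nifti: expected a 3-D image, got dim ", paste(dims, collapse = " "))
  if (dims[1] > 3L && any(dims[5:(1 + dims[1])] > 1L))
    abort("read_nifti: only 3-D volumes are supported")
  datatype <- ri(70L, 2L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) abort("read_nifti: unsupported datatype code ", datatype)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  sform_code <- ri(254L, 2L)
  spacing <- pixdim[2:4]
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    srow <- rbind(rf(280L, 4L), rf(296L, 4L), rf(312L, 4L))
    rot <- srow[, 1:3]
    if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))))
      warning("read_nifti: non-diagonal sform; using absolute diagonal spacing")
    spacing <- abs(diag(rot))
    origin <- srow[, 4]
  }
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  n <- prod(dims[2:4])
  skip <- as.integer(round(vox_offset)) - 352L
  if (skip > 0L) readBin(con, "raw", n = skip)
  if (dt$what == "integer" && dt$size == 1L) {
    dat <- as.numeric(readBin(con, "integer", n = n, size = 1L,
                              endian = "little", signed = FALSE))
  } else {
    dat <- as.numeric(readBin(con, dt$what, n = n, size = dt$size,
                              endian = "little"))
  }
  if (length(dat) != n) abort("read_nifti: truncated data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  volume3d(array(dat, dims[2:4]), spacing = spacing, origin = origin)
}
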