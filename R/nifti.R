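#' Minimal NIfTI-1 input/output
#'
#' The package stores gray-matter volume maps, masks and statistic maps as
#' single-file NIfTI-1 (`.nii` or `.nii.gz`). Since no NIfTI reader is
#' available among the package's allowed dependencies, a small, strict codec
#' for the subset of the format this pipeline needs is implemented here:
#' 3D volumes, RAS-aligned diagonal affine (sform code 1), data types uint8,
#' int16, int32, float32 and float64, and optional gzip compression decided
#' by the file extension. Scaling (`scl_slope`/`scl_inter`) is applied on
#' read when set.
#'
#' @name nifti-io
NULL

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [volume_image()] object (logical data is written as uint8).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype one of "float32" (default), "float64", "int16", "uint8".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  stopifnot(inherits(vol, "volume"))
  if (!datatype %in% names(NIFTI_DT)) stop("unsupported datatype ", datatype)
  dat <- vol$data
  if (is.logical(dat)) { dat <- dat + 0L; if (missing(datatype)) datatype <- "uint8" }
  d <- dim(dat)
  dt_code <- NIFTI_DT[[datatype]]
  bitpix <- NIFTI_BITPIX[[as.character(dt_code)]]
  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)

  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }

  wi(348L, 4)                         # sizeof_hdr
  wc("", 10); wc("", 18)              # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2)                # extents, session_error
  writeBin(charToRaw("r"), con); writeBin(raw(1), con)  # regular, dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)     # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)           # intent_p1..p3, intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(c(1, vol$voxel_size, 1, 1, 1, 1))       # pixdim[8], qfac=1
  wf(352); wf(1); wf(0)               # vox_offset, scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)    # slice_end, slice_code, xyzt_units=0
  wf(c(0, 0, 0, 0))                   # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                    # glmax, glmin
  wc("vrfmed", 80); wc("", 24)        # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                # qform_code=0, sform_code=1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))      # quaternions, qoffset
  wf(c(vol$voxel_size[1], 0, 0, vol$origin[1]))   # srow_x
  wf(c(0, vol$voxel_size[2], 0, vol$origin[2]))   # srow_y
  wf(c(0, 0, vol$voxel_size[3], vol$origin[3]))   # srow_z
  wc("", 16)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)      # magic
  writeBin(raw(4), con)               # extension indicator

  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(dat), con, size = bitpix / 8, endian = "little")
  } else {
    writeBin(as.integer(dat), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file written by this package or any
#'   NIfTI-1 writer using a single 3D image.
#' @return a [volume_image()] object.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)

  endian <- "little"
  rd_i <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size > 2 || size == 2)
  rd_f <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = endian)

  if (rd_i(0, 4) != 348L) {
    endian <- "big"
    if (rd_i(0, 4) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported")

  dims <- rd_i(40, 2, 8)
  ndim <- dims[1]
  d <- dims[2:(1 + max(ndim, 3))]
  if (ndim > 3 && any(dims[(2 + 3):(1 + ndim)] > 1))
    stop("only 3D NIfTI volumes are supported")
  d <- dims[2:4]
  datatype <- rd_i(70, 2)
  pixdim <- rd_f(76, 8)
  vox_offset <- rd_f(108)
  scl_slope <- rd_f(112); scl_inter <- rd_f(116)
  sform_code <- rd_i(254, 2)
  origin <- if (sform_code > 0)
    c(rd_f(280, 4)[4], rd_f(296, 4)[4], rd_f(312, 4)[4]) else c(0, 0, 0)

  n_vox <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  dat <- switch(as.character(datatype),
    `2`  = readBin(con, "integer", n = n_vox, size = 1, signed = FALSE,
                   endian = endian),
    `4`  = readBin(con, "integer", n = n_vox, size = 2, endian = endian),
    `8`  = readBin(con, "integer", n = n_vox, size = 4, endian = endian),
    `16` = readBin(con, "numeric", n = n_vox, size = 4, endian = endian),
    `64` = readBin(con, "numeric", n = n_vox, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(dat) < n_vox) stop("truncated NIfTI data in ", path)
  dat <- as.numeric(dat)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    dat <- dat * scl_slope + scl_inter
  volume_image(array(dat, dim = d), voxel_size = pixdim[2:4],
               origin = origin,
               id = sub("\\.nii(\\.gz)?$", "", basename(path)))
}
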