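# Minimal NIfTI-1 single-file I/O (.nii / .nii.gz).
#
# No NIfTI reader ships with the supported dependency set, so the package
# carries a small, strict implementation of the fixed 348-byte NIfTI-1
# header: little-endian, sform affine (sform_code 1), float64 volumes and
# uint8 masks, millimetre units.  Files written here load in nibabel /
# SimpleITK and vice versa for these datatypes.

NIFTI_DT_UINT8 <- 2L
NIFTI_DT_INT16 <- 4L
NIFTI_DT_INT32 <- 8L
NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L

#' Write a 3D volume or mask as NIfTI-1
#'
#' @param data numeric or logical 3D array.
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @param spacing voxel spacing in mm, length 3.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices);
#'   default `diag(c(spacing, 1))`.
#' @param datatype `"float64"` (volumes) or `"uint8"` (masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), affine = NULL,
                        datatype = c("float64", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  dt <- if (datatype == "uint8") NIFTI_DT_UINT8 else NIFTI_DT_FLOAT64
  bitpix <- if (datatype == "uint8") 8L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                              # sizeof_hdr
  wc(34); writeBin(as.raw(114L), con)      # data_type/db_name/extents/..., regular='r'
  wc(1)                                    # dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2)  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                # intent_p*, intent_code
  wi(dt, 2); wi(bitpix, 2); wi(0L, 2)      # datatype, bitpix, slice_start
  wf(c(1, spacing, 1, 1, 1, 1))            # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                    # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc(1)                         # slice_end, slice_code
  writeBin(as.raw(10L), con)               # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)      # cal_max/min, slice_dur, toffset, glmax/glmin
  wc(80); wc(24)                           # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                     # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                  # quatern b/c/d, qoffset x/y/z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  wc(16)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)     # magic
  wc(4)                                    # extension flag

  if (datatype == "uint8") {
    writeBin(as.integer(as.logical(data)), con, size = 1, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or compatible tools)
#'
#' Supports 3D single-file NIfTI-1 with datatypes uint8, int16, int32,
#' float32 and float64.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array), `spacing` (length 3) and `affine`
#'   (4x4; sform when present, otherwise diagonal spacing).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_radscore(paste0("file not found: ", path),
                                        "radscore_io_error")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  rc <- function(n) readBin(con, "raw", n = n)

  sizeof_hdr <- ri(1, 4)
  if (length(sizeof_hdr) != 1 || sizeof_hdr != 348L)
    stop_radscore(paste0("not a NIfTI-1 file (sizeof_hdr != 348): ", path),
                  "radscore_io_error")
  rc(36)
  dims <- ri(8, 2)
  if (dims[1] < 3) stop_radscore("expected a 3D volume", "radscore_io_error")
  shape <- dims[2:4]
  rf(3); ri(1, 2)
  datatype <- ri(1, 2); ri(1, 2); ri(1, 2)
  pixdim <- rf(8)
  vox_offset <- rf(1); rf(2)
  ri(1, 2); rc(2)
  rf(4); ri(2, 4)
  rc(104)
  ri(1, 2); sform_code <- ri(1, 2)
  rf(6)
  srow <- matrix(rf(12), nrow = 3, byrow = TRUE)
  rc(16)
  magic <- rawToChar(rc(4)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop_radscore(paste0("bad NIfTI magic string in: ", path),
                  "radscore_io_error")

  skip <- vox_offset - 348
  if (skip > 0) rc(skip)
  n <- prod(shape)
  data <- switch(as.character(datatype),
    "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE,
                  endian = "little"),
    "4" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop_radscore(paste0("unsupported NIfTI datatype code: ", datatype),
                  "radscore_io_error"))
  if (length(data) != n)
    stop_radscore(paste0("truncated NIfTI data section in: ", path,
                         " (expected ", n, " voxels, got ", length(data), ")"),
                  "radscore_io_error")
  spacing <- pixdim[2:4]
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(spacing, 1))
  list(data = array(as.double(data), dim = shape), spacing = spacing,
       affine = affine)
}
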