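# Minimal NIfTI-1 volume I/O.
#
# The pipeline exchanges standard-space volumes as gzipped NIfTI-1 files
# (single-file .nii.gz). Only the features the pipeline needs are supported:
# 3D images, float32/float64/int8..int32 storage, scl_slope/scl_inter
# rescaling, both endiannesses on read. Written files use float32, RAS-ish
# identity orientation and a zeroed gzip timestamp so that byte-identical
# reruns produce byte-identical files.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),
  `4`  = list(what = "integer", size = 2, signed = TRUE),
  `8`  = list(what = "integer", size = 4, signed = TRUE),
  `16` = list(what = "double",  size = 4, signed = TRUE),
  `64` = list(what = "double",  size = 8, signed = TRUE)
)

#' Write a 3D array as a gzipped NIfTI-1 volume
#'
#' Stores the array as float32 with an identity-scaled header. The gzip
#' stream is produced by [memCompress()], which embeds no modification time,
#' so identical arrays always yield byte-identical files.
#'
#' @param img 3D numeric array of finite values.
#' @param path output path; conventionally ending in `.nii.gz`.
#' @param voxdim voxel edge lengths in mm (length 3).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxdim = c(1, 1, 1)) {
  stopifnot(is.array(img), length(dim(img)) == 3L, all(is.finite(img)))
  dm <- dim(img)
  wi <- function(x, size) writeBin(as.integer(x), raw(), size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), raw(), size = 4, endian = "little")
  hdr <- c(
    wi(348L, 4),                                 #   0 sizeof_hdr
    raw(36),                                     #   4 data_type..dim_info
    wi(c(3L, dm, 1L, 1L, 1L, 1L), 2),            #  40 dim
    wf(c(0, 0, 0)),                              #  56 intent_p1..p3
    wi(0L, 2),                                   #  68 intent_code
    wi(16L, 2),                                  #  70 datatype = float32
    wi(32L, 2),                                  #  72 bitpix
    wi(0L, 2),                                   #  74 slice_start
    wf(c(1, voxdim, 1, 1, 1, 1)),                #  76 pixdim (qfac = 1)
    wf(352),                                     # 108 vox_offset
    wf(1),                                       # 112 scl_slope
    wf(0),                                       # 116 scl_inter
    wi(0L, 2), raw(2),                           # 120 slice_end, slice_code, xyzt
    wf(c(0, 0, 0, 0)),                           # 124 cal_max..toffset
    wi(c(0L, 0L), 4),                            # 140 glmax, glmin
    raw(80 + 24),                                # 148 descrip, aux_file
    wi(c(1L, 1L), 2),                            # 252 qform_code, sform_code
    wf(c(0, 0, 0, 0, 0, 0)),                     # 256 quatern, qoffset
    # srow_x/y/z: identity scaled by voxdim
    wf(c(voxdim[1], 0, 0, 0,  0, voxdim[2], 0, 0,  0, 0, voxdim[3], 0)),
    raw(16),                                     # 328 intent_name
    charToRaw("n+1"), as.raw(0)                  # 344 magic
  )
  stopifnot(length(hdr) == 348L)
  payload <- c(hdr, raw(4),                     # empty extension field
               writeBin(as.double(img), raw(), size = 4, endian = "little"))
  con <- gzcon(file(path, "wb"))                # gzip with zeroed mtime: deterministic
  on.exit(close(con), add = TRUE)
  writeBin(payload, con)
  invisible(path)
}

#' Read a (gzipped) NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` single-file NIfTI-1 volume.
#' @return a 3D numeric array with attribute `voxdim`.
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  szof <- readBin(hdr[1:4], "integer", size = 4, endian = "little")
  endian <- "little"
  if (szof != 348L) {
    szof_b <- readBin(hdr[1:4], "integer", size = 4, endian = "big")
    if (szof_b != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
    endian <- "big"
  }
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size, endian = endian)
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)],
                                 "double", n = n, size = 4, endian = endian)
  dm_all <- ri(40, 8, 2)
  ndim <- dm_all[1]
  if (ndim < 3L) stop("expected a 3D volume: ", path)
  dm <- dm_all[2:4]
  if (ndim > 3L && any(dm_all[5:(ndim + 1)] > 1L))
    stop("expected a 3D volume, got ", ndim, "D: ", path)
  datatype <- ri(70, 1, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  voxdim <- rf(80, 3)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1)
  scl_inter <- rf(116, 1)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dm)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data: ", path)
  vals <- as.double(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, dim = dm)
  attr(out, "voxdim") <- voxdim
  out
}
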