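# Minimal NIfTI-1 single-file (.nii) reader/writer.
#
# The offline R toolchain ships no NIfTI package, so the format support needed
# by the pipeline is implemented here directly against the NIfTI-1.1 header
# layout: 348-byte header, vox_offset 352, sform affine (srow_x/y/z), scalar
# datatypes uint8/int16/int32/float32/float64. Volumes are written as float64
# with an sform affine so that write -> read round-trips voxel values and the
# affine exactly. Compressed (.nii.gz) files and extensions are not supported.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Construct an image volume
#'
#' A lightweight container for a 3-D intensity array together with its
#' voxel-to-world affine. This is the in-memory currency of the imaging
#' module: readers produce it, writers and filters consume it.
#'
#' @param data numeric 3-D array of voxel intensities.
#' @param voxel_size numeric length-3, mm per axis (used to build a diagonal
#'   affine when `affine` is not given).
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices). Must be
#'   invertible.
#' @return An object of class `image_volume` with fields `data`, `affine`,
#'   `voxel_size`.
#' @export
image_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (mm)", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be an invertible 4x4 matrix", call. = FALSE)
  }
  structure(list(data = data, affine = affine, voxel_size = voxel_size),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path path to an uncompressed `.nii` file.
#' @return An [image_volume()].
#' @details A file whose data are 4-D (or higher, with a non-singleton extra
#'   dimension) is rejected: this pipeline operates on one 3-D volume per
#'   subject. `scl_slope`/`scl_inter` scaling is applied when set.
#' @export
read_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("NIfTI file does not exist: '%s'", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    # retry big-endian
    seek(con, 0L)
    sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    endian <- "big"
    if (sizeof_hdr != 348L) {
      stop(sprintf("malformed NIfTI header in '%s' (sizeof_hdr != 348)", path),
           call. = FALSE)
    }
  }
  seek(con, 40L)
  dim0 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  ndim <- dim0[1L]
  if (ndim < 1L || ndim > 7L) {
    stop(sprintf("malformed NIfTI dim field in '%s'", path), call. = FALSE)
  }
  dims <- dim0[2L:(1L + ndim)]
  if (ndim > 3L && any(dims[4L:ndim] > 1L)) {
    stop(sprintf("'%s' holds %d-D data; a single 3-D volume was expected",
                 path, ndim), call. = FALSE)
  }
  dims3 <- c(dims, 1L, 1L)[1:3]

  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) {
    stop(sprintf("unsupported NIfTI datatype %d in '%s'", datatype, path),
         call. = FALSE)
  }
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  seek(con, 108L)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) {
    stop(sprintf("malformed NIfTI magic in '%s'", path), call. = FALSE)
  }
  seek(con, 254L)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 280L)
  srow <- readBin(con, "double", 12L, size = 4L, endian = endian)

  n <- prod(dims3)
  seek(con, vox_offset)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) {
    stop(sprintf("truncated NIfTI data in '%s'", path), call. = FALSE)
  }
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  vox <- pixdim[2:4]
  vox[!is.finite(vox) | vox <= 0] <- 1
  if (sform_code > 0L) {
    affine <- rbind(matrix(srow, nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(vox, 1))
  }
  image_volume(array(vals, dim = dims3), voxel_size = vox, affine = affine)
}

#' Write a 3-D volume as NIfTI-1
#'
#' Writes an uncompressed single-file `.nii` (float64 data, sform affine).
#'
#' @param volume an [image_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  dims <- dim(volume$data)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)

  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x, size) writeBin(as.double(x), con, size = size, endian = "little")

  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type, db_name, extents, session_error, regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)            # dim[8]
  wd(c(0, 0, 0), 4L)                             # intent_p1..p3
  wi(0L, 2L)                                     # intent_code
  wi(64L, 2L)                                    # datatype float64
  wi(64L, 2L)                                    # bitpix
  wi(0L, 2L)                                     # slice_start
  wd(c(1, volume$voxel_size, 1, 1, 1, 1), 4L)    # pixdim[8]
  wd(352, 4L)                                    # vox_offset
  wd(1, 4L)                                      # scl_slope
  wd(0, 4L)                                      # scl_inter
  wi(0L, 2L)                                     # slice_end
  writeBin(raw(2L), con)                         # slice_code, xyzt_units
  wd(c(0, 0, 0, 0), 4L)                          # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(104L), con)                       # descrip[80] + aux_file[24]
  wi(0L, 2L)                                     # qform_code
  wi(1L, 2L)                                     # sform_code
  wd(c(0, 0, 0, 0, 0, 0), 4L)                    # quatern b,c,d + qoffset x,y,z
  wd(t(volume$affine[1:3, ]), 4L)                # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extender
  wd(volume$data, 8L)
  invisible(path)
}
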