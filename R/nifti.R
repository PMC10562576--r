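# Minimal NIfTI-1 I/O.
#
# The package only needs binary occupancy volumes with isotropic voxels, so a
# small single-file reader/writer is used rather than a full neuroimaging
# stack.  Supported on read: datatypes uint8 (2), int16 (4), int32 (8),
# float32 (16), float64 (64), int8 (256), uint16 (512); plain .nii or
# gzip-compressed .nii.gz; either byte order.  Written files are uint8 .nii
# (or .nii.gz), voxel offset 352, identity orientation.

NIFTI_HDR_SIZE <- 348L

nifti_connection <- function(path, open) {
  # gzfile transparently reads uncompressed files as well
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3-D binary mask from a NIfTI-1 file
#'
#' Any voxel with a nonzero (after applying the NIfTI scaling slope and
#' intercept, when set) value is treated as foreground.  The three spatial
#' voxel dimensions must be isotropic to within 1%, otherwise an error is
#' raised, because box-counting scales are expressed in voxel units.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3-D volume.
#' @return a [voxel_mask] whose `voxel_size` is the (common) spatial voxel
#'   edge length from the file header.
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_nifti_mask(make_phantom("cube", size = 8), f)
#' mask <- read_nifti_mask(f)
#' sum(mask$occupancy)  # 512
read_nifti_mask <- function(path) {
  if (!file.exists(path))
    stop_fracdem("NIfTI file not found: ", path, class = "fracdem_io_error")
  con <- nifti_connection(path, "rb")
  on.exit(close(con))

  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    if (bitwAnd(bitwShiftR(sizeof_hdr, 24L), 255L) != 92L)  # 348 byte-swapped
      stop_fracdem("not a NIfTI-1 file (bad sizeof_hdr): ", path,
                   class = "fracdem_io_error")
  }
  readBin(con, "raw", 36L)                                  # unused fields
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                  # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)   # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)   # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  # we are at byte 120 (after scl_inter); skip the rest of the header and
  # any extensions up to the data offset
  readBin(con, "raw", as.integer(round(vox_offset)) - 120L)

  ndim <- dim8[1L]
  if (ndim < 3L || any(dim8[2:4] < 1L))
    stop_fracdem("expected a 3-D volume, got dim = (",
                 paste(dim8[-1][seq_len(max(ndim, 1))], collapse = ", "), ")",
                 class = "fracdem_io_error")
  if (ndim > 3L && any(dim8[5:(1L + ndim)] > 1L))
    stop_fracdem("4-D (or higher) NIfTI volumes are not supported",
                 class = "fracdem_io_error")
  dims <- dim8[2:4]
  n <- prod(dims)

  vox <- pixdim[2:4]
  if (any(vox <= 0) || diff(range(vox)) > 0.01 * min(vox))
    stop_fracdem("anisotropic voxels (pixdim = ",
                 paste(signif(vox, 6), collapse = " x "),
                 "); box counting requires isotropic voxels (1% tolerance)",
                 class = "fracdem_io_error")

  vals <- switch(as.character(datatype),
    "2"   = readBin(con, "integer", n, size = 1L, signed = FALSE),
    "4"   = readBin(con, "integer", n, size = 2L, endian = endian),
    "8"   = readBin(con, "integer", n, size = 4L, endian = endian),
    "16"  = readBin(con, "double",  n, size = 4L, endian = endian),
    "64"  = readBin(con, "double",  n, size = 8L, endian = endian),
    "256" = readBin(con, "integer", n, size = 1L, signed = TRUE),
    "512" = readBin(con, "integer", n, size = 2L, signed = FALSE,
                    endian = endian),
    stop_fracdem("unsupported NIfTI datatype code: ", datatype,
                 class = "fracdem_io_error"))
  if (length(vals) < n)
    stop_fracdem("truncated NIfTI data in ", path, class = "fracdem_io_error")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  voxel_mask(array(vals != 0, dim = dims), voxel_size = vox[1L])
}

#' Write a binary mask to a NIfTI-1 file
#'
#' Foreground voxels are written as 1, background as 0 (uint8), with isotropic
#' `pixdim` taken from the mask's `voxel_size`.  A `.gz` suffix selects gzip
#' compression.
#'
#' @param mask a [voxel_mask].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_mask <- function(mask, path) {
  mask <- as_voxel_mask(mask)
  dims <- dim(mask$occupancy)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))

  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(nbytes) writeBin(raw(nbytes), con)

  wi(NIFTI_HDR_SIZE, 4L)                      # sizeof_hdr
  wc(36L)                                     # data_type..dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)         # dim[8]
  wc(14L)                                     # intent_p1..intent_code
  wi(2L, 2L)                                  # datatype = uint8
  wi(8L, 2L)                                  # bitpix
  wi(0L, 2L)                                  # slice_start
  wf(c(1, rep(mask$voxel_size, 3L), 1, 1, 1, 1))  # pixdim[8]
  wf(352)                                     # vox_offset
  wf(1); wf(0)                                # scl_slope, scl_inter
  wc(20L)                                     # slice_end..toffset
  wi(c(0L, 0L), 4L)                           # glmax, glmin
  wc(104L)                                    # descrip, aux_file
  wi(c(0L, 1L), 2L)                           # qform_code, sform_code
  wf(rep(0, 6L))                              # quaternion/offsets
  wf(c(mask$voxel_size, 0, 0, 0))             # srow_x
  wf(c(0, mask$voxel_size, 0, 0))             # srow_y
  wf(c(0, 0, mask$voxel_size, 0))             # srow_z
  wc(16L)                                     # intent_name
  writeBin(charToRaw("n+1"), con); wc(1L)     # magic
  wc(4L)                                      # extender flag = no extensions
  writeBin(as.integer(mask$occupancy), con, size = 1L)
  invisible(path)
}
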