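#' 3-D binary voxel mask
#'
#' The elementary input of the fractal analysis: a 3-D occupancy grid for a
#' single (segmented) brain structure or phantom.  A voxel is identified with
#' its integer corner coordinate (0-based) for box-membership tests, which
#' makes box counting exact and translation of the mask by integer vectors a
#' pure relabelling.
#'
#' @param occupancy a 3-D `logical` (or coercible numeric, nonzero =
#'   foreground) array.
#' @param voxel_size isotropic voxel edge length (arbitrary units; box sizes
#'   are always expressed in voxel units, so this is carried as metadata).
#' @return an object of class `voxel_mask` with fields `occupancy` and
#'   `voxel_size`.
#' @export
#' @examples
#' m <- voxel_mask(array(TRUE, dim = c(4, 4, 4)))
#' n_foreground(m)  # 64
voxel_mask <- function(occupancy, voxel_size = 1) {
  if (is.numeric(occupancy)) occupancy <- array(occupancy != 0,
                                                dim = dim(occupancy))
  if (!is.logical(occupancy) || length(dim(occupancy)) != 3L)
    stop_fracdem("occupancy must be a 3-D logical array",
                 class = "fracdem_mask_error")
  if (anyNA(occupancy))
    stop_fracdem("occupancy must not contain NA", class = "fracdem_mask_error")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop_fracdem("voxel_size must be a positive scalar",
                 class = "fracdem_mask_error")
  structure(list(occupancy = occupancy, voxel_size = as.numeric(voxel_size)),
            class = "voxel_mask")
}

as_voxel_mask <- function(x) {
  if (inherits(x, "voxel_mask")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(voxel_mask(x))
  stop_fracdem("cannot interpret object of class ",
               paste(class(x), collapse = "/"), " as a voxel mask",
               class = "fracdem_mask_error")
}

#' Number of foreground voxels in a mask
#' @param mask a [voxel_mask].
#' @return integer count of foreground voxels.
#' @export
n_foreground <- function(mask) sum(as_voxel_mask(mask)$occupancy)

# 0-based integer corner coordinates of foreground voxels, n x 3 matrix
foreground_coords <- function(mask) {
  mask <- as_voxel_mask(mask)
  idx <- which(mask$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop_fracdem("mask has no foreground voxels", class = "fracdem_empty_mask")
  idx - 1L
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("<voxel_mask> %d x %d x %d grid, %d foreground voxels, voxel size %g\n",
              d[1], d[2], d[3], sum(x$occupancy), x$voxel_size))
  invisible(x)
}
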