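# Analytic phantoms: binary volumes whose box-counting dimension is known in
# closed form, used to validate the FD estimator.

PHANTOM_KINDS <- c("cube", "slab", "line", "menger")

#' Theoretical fractal dimension of a phantom family
#'
#' @param kind one of `"cube"`, `"slab"`, `"line"`, `"menger"`.
#' @return the self-similarity (box-counting) dimension: 3, 2, 1, or
#'   `log(20)/log(3)` (about 2.7268) respectively.
#' @export
theoretical_fd <- function(kind) {
  kind <- match.arg(kind, PHANTOM_KINDS)
  switch(kind, cube = 3, slab = 2, line = 1, menger = log(20) / log(3))
}

#' Generate a deterministic validation phantom
#'
#' `cube` is a solid `size^3` block; `slab` a one-voxel-thick
#' `size x size x 1` plane; `line` a `size x 1 x 1` segment.  `menger` is the
#' standard Menger sponge at `iterations` levels on a `3^iterations` grid:
#' starting from a solid cube, each refinement keeps the 20 of 27 subcubes
#' whose ternary digit triple never has two or more digits equal to 1.
#'
#' @param kind phantom family, see [theoretical_fd].
#' @param size edge length in voxels for cube/slab/line (>= 8).
#' @param iterations recursion depth for the Menger sponge (1..5).
#' @return a [voxel_mask].
#' @export
#' @examples
#' n_foreground(make_phantom("menger", iterations = 2))  # 20^2 = 400
make_phantom <- function(kind, size = 64L, iterations = 4L) {
  kind <- match.arg(kind, PHANTOM_KINDS)
  if (kind == "menger") {
    if (!is_count(iterations) || iterations < 1L || iterations > 5L)
      stop_fracdem("menger iterations must be in 1..5",
                   class = "fracdem_phantom_error")
    n <- 3L^as.integer(iterations)
    ax <- 0:(n - 1L)
    # per-axis indicator of "digit == 1" at each ternary level
    digit1 <- vapply(seq_len(iterations),
                     function(l) (ax %/% 3L^(l - 1L)) %% 3L == 1L,
                     logical(n))                       # n x iterations
    occ <- array(TRUE, dim = c(n, n, n))
    for (l in seq_len(iterations)) {
      d <- digit1[, l]
      # removed at level l iff >= 2 of the 3 axis digits equal 1
      s <- outer(outer(d + 0L, d + 0L, `+`), d + 0L, `+`)
      occ <- occ & (s < 2L)
    }
    return(voxel_mask(occ))
  }
  if (!is_count(size) || size < 8L)
    stop_fracdem("size must be an integer >= 8 for ", kind,
                 class = "fracdem_phantom_error")
  size <- as.integer(size)
  dims <- switch(kind,
                 cube = c(size, size, size),
                 slab = c(size, size, 1L),
                 line = c(size, 1L, 1L))
  voxel_mask(array(TRUE, dim = dims))
}
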