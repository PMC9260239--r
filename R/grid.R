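#' Symmetric voxel grid
#'
#' A `volume_grid` describes the 3D voxel lattice shared by all volumes of a
#' study: its shape, voxel size in mm, and which array axis runs left-right.
#' Homotopic (mirror) pairing reflects voxel indices across the mid-plane of
#' the left-right axis, so the grid must have an even number of voxels along
#' that axis: every voxel then has a distinct mirror and no voxel is its own
#' mirror. Grids with an odd left-right extent are rejected outright rather
#' than giving the midline plane special treatment, which would contaminate
#' homotopic connectivity with self-correlations of exactly 1.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param lr_axis which axis (1, 2 or 3) is the left-right axis. The working
#'   convention follows MNI space, where the first axis is left-right; it is
#'   declared per grid rather than inferred from NIfTI orientation codes.
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' g <- volume_grid(c(10, 10, 8), voxel_size = c(3, 3, 3))
#' mirror_index(g, c(1, 5, 5))  # -> c(10, 5, 5)
volume_grid <- function(shape, voxel_size = c(3, 3, 3), lr_axis = 1L) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    nvc_config_error("'shape' must be 3 positive integers")
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    nvc_config_error("'voxel_size' must be 3 strictly positive lengths (mm)")
  lr_axis <- as.integer(lr_axis)
  if (!lr_axis %in% 1:3)
    nvc_config_error("'lr_axis' must be 1, 2 or 3")
  if (shape[lr_axis] %% 2L != 0L)
    nvc_grid_error(sprintf(
      "grid extent along the left-right axis must be even (got %d): odd grids would contain self-mirrored midline voxels",
      shape[lr_axis]))
  structure(list(shape = shape, voxel_size = voxel_size, lr_axis = lr_axis),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %dx%dx%d, %.3gx%.3gx%.3g mm, left-right axis %d>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$lr_axis))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && a$lr_axis == b$lr_axis &&
    all(abs(a$voxel_size - b$voxel_size) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    nvc_grid_error(sprintf("%s do not share a grid", what))
  invisible(TRUE)
}

#' Mirror a voxel index across the left-right mid-plane
#'
#' Reflects 1-based voxel indices across the mid-plane of the grid's
#' left-right axis: coordinate i maps to n + 1 - i on that axis, the other
#' coordinates are unchanged. On an even grid this pairing is a fixed-point
#' free involution: applying it twice returns the input and no voxel maps to
#' itself.
#'
#' @param grid a [volume_grid()].
#' @param voxel integer vector of length 3, or an n x 3 matrix of voxel
#'   indices (1-based).
#' @return Index (or matrix of indices) of the mirrored voxel(s).
#' @export
mirror_index <- function(grid, voxel) {
  v <- if (is.matrix(voxel)) voxel else matrix(as.integer(voxel), nrow = 1L)
  if (ncol(v) != 3L) nvc_index_error("voxel indices must have 3 coordinates")
  for (a in 1:3) {
    if (any(v[, a] < 1L | v[, a] > grid$shape[a]))
      nvc_index_error("voxel index out of bounds")
  }
  a <- grid$lr_axis
  v[, a] <- grid$shape[a] + 1L - v[, a]
  if (is.matrix(voxel)) v else as.integer(v[1L, ])
}

## Linear-index permutation sending each voxel to its mirror; used to
## vectorize homotopic operations. mirror_perm(grid)[i] is the linear index
## of the mirror of linear index i (column-major, axis 1 fastest).
mirror_perm <- function(grid) {
  n <- grid$shape
  idx <- lapply(1:3, function(a) {
    if (a == grid$lr_axis) rev(seq_len(n[a])) else seq_len(n[a])
  })
  array(seq_len(prod(n)), dim = n)[idx[[1]], idx[[2]], idx[[3]]]
}

## Linear indices of the "left half": voxels with left-right coordinate
## <= n/2. Each homotopic pair has exactly one member in this set.
left_half_indices <- function(grid) {
  n <- grid$shape
  coord <- slice.index(array(0L, dim = n), grid$lr_axis)
  which(coord <= n[grid$lr_axis] %/% 2L)
}
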