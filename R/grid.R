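#' Regular voxel grids with a world affine
#'
#' A `volume_grid` carries the geometry shared by every volumetric object in
#' the package: integer dimensions, voxel size in mm, a 4x4 affine mapping
#' 0-based voxel indices to world mm (NIfTI convention, RAS-oriented), and an
#' optional logical brain mask. The anatomical midline is the world plane
#' x = 0; all mirroring operations reflect about it.
#'
#' @param dims Integer vector of length 3, voxels per axis.
#' @param voxel_size Numeric vector of length 3 (or scalar), voxel edge mm.
#' @param affine 4x4 matrix mapping 0-based voxel index to world mm. If
#'   `NULL`, an axis-aligned affine is built from `voxel_size` and `origin`.
#' @param origin World mm of voxel (1,1,1). Defaults to centering the grid on
#'   the world origin.
#' @param mask Optional logical array of dimension `dims`; `NULL` means all
#'   voxels in-mask.
#' @return A `volume_grid` object.
#' @examples
#' g <- symmetric_grid(c(8, 8, 8), 2)
#' is_mirror_closed(g)
#' @export
volume_grid <- function(dims, voxel_size, affine = NULL, origin = NULL,
                        mask = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  stopifnot(all(voxel_size > 0))
  if (is.null(affine)) {
    if (is.null(origin)) {
      origin <- -(dims - 1) / 2 * voxel_size
    }
    affine <- diag(4)
    affine[cbind(1:3, 1:3)] <- voxel_size
    affine[1:3, 4] <- origin
  } else {
    affine <- as.matrix(affine)
    stopifnot(identical(dim(affine), c(4L, 4L)))
  }
  if (abs(det(affine)) < 1e-12) {
    stop("grid affine is not invertible", call. = FALSE)
  }
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dims)
  }
  structure(
    list(dims = dims, voxel_size = voxel_size, affine = affine, mask = mask),
    class = "volume_grid"
  )
}

#' Build a mirror-closed grid centred on the midline
#'
#' Constructs an axis-aligned grid whose voxel-centre x coordinates are
#' symmetric about the world plane x = 0, so that every voxel has an exact
#' on-grid mirror. This is the geometry assumed by symmetric templates in
#' homotopic-connectivity work.
#'
#' @inheritParams volume_grid
#' @return A mirror-closed `volume_grid`.
#' @export
symmetric_grid <- function(dims, voxel_size = 2, mask = NULL) {
  g <- volume_grid(dims, voxel_size, mask = mask)
  stopifnot(is_mirror_closed(g))
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %d x %d x %d voxels @ %s mm%s\n",
    x$dims[1], x$dims[2], x$dims[3],
    paste(format(x$voxel_size), collapse = " x "),
    if (is.null(x$mask)) "" else sprintf(", %d in mask", sum(x$mask))
  ))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) <= tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("maps are not defined on the same grid", call. = FALSE)
}

axis_aligned <- function(grid) {
  off <- grid$affine[1:3, 1:3]
  diag(off) <- 0
  max(abs(off)) < 1e-9
}

#' World coordinates of voxel centres along one axis
#' @param grid A `volume_grid` (must be axis-aligned).
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of length `dims[axis]`.
#' @export
grid_axis_coords <- function(grid, axis = 1L) {
  stopifnot(axis_aligned(grid))
  grid$affine[axis, axis] * (seq_len(grid$dims[axis]) - 1) +
    grid$affine[axis, 4]
}

#' Convert between 1-based voxel indices and world mm
#'
#' @param grid A `volume_grid`.
#' @param ijk Matrix (n x 3) of 1-based voxel indices.
#' @param xyz Matrix (n x 3) of world mm coordinates.
#' @return `voxel_to_world()` returns an n x 3 matrix of world mm;
#'   `world_to_voxel()` an n x 3 matrix of continuous 1-based indices.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  t(grid$affine[1:3, 1:3] %*% t(ijk - 1) + grid$affine[1:3, 4])
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  inv <- solve(grid$affine)
  t(inv[1:3, 1:3] %*% t(xyz) + inv[1:3, 4]) + 1
}

#' Does every voxel have an exact on-grid x-mirror?
#' @param grid A `volume_grid`.
#' @param tol Matching tolerance in mm.
#' @return Logical scalar.
#' @export
is_mirror_closed <- function(grid, tol = 1e-6) {
  if (!axis_aligned(grid)) return(FALSE)
  xs <- grid_axis_coords(grid, 1L)
  all(vapply(xs, function(x) any(abs(xs + x) <= tol), logical(1)))
}

# Permutation p such that slice i along x mirrors to slice p[i] (world x -> -x).
mirror_index_perm <- function(grid, tol = 1e-6) {
  if (!is_mirror_closed(grid, tol)) {
    stop("grid is not mirror-closed; resample onto a symmetric grid first",
         call. = FALSE)
  }
  xs <- grid_axis_coords(grid, 1L)
  vapply(xs, function(x) which.min(abs(xs + x)), integer(1))
}

# Linear-index permutation sending each voxel to its x-mirror voxel.
mirror_linear_perm <- function(grid) {
  p <- mirror_index_perm(grid)
  d <- grid$dims
  rest <- rep(seq_len(d[2] * d[3]) - 1L, each = d[1]) * d[1]
  rep(p, times = d[2] * d[3]) + rest
}

grid_mask <- function(grid) {
  if (is.null(grid$mask)) array(TRUE, dim = grid$dims) else grid$mask
}
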