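#' Regular isotropic voxel grid
#'
#' Defines the discretization domain shared by media, fluorophore maps,
#' fluence fields and reconstructions. The tissue surface is the plane
#' z = 0, with z increasing into the medium; x is the stage-scan direction
#' and y runs along the illumination line. Voxel `i` (0-based) spans the
#' half-open interval `[i * voxel_size, (i + 1) * voxel_size)` on each axis.
#'
#' @param nx,ny,nz positive integer voxel counts.
#' @param voxel_size isotropic voxel edge length in mm.
#' @return An object of class `flot_grid`.
#' @examples
#' g <- voxel_grid(128, 64, 100, voxel_size = 0.01)
#' grid_extent(g)  # physical extent in mm
#' @export
voxel_grid <- function(nx, ny, nz, voxel_size) {
  for (nm in c("nx", "ny", "nz")) {
    v <- get(nm)
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      stop(nm, " must be a positive integer", call. = FALSE)
  }
  if (length(voxel_size) != 1 || !is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be > 0", call. = FALSE)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         voxel_size = as.numeric(voxel_size)),
    class = "flot_grid"
  )
}

#' @exportS3Method print flot_grid
print.flot_grid <- function(x, ...) {
  cat(sprintf("<flot_grid> %d x %d x %d voxels @ %g mm (%g x %g x %g mm)\n",
              x$nx, x$ny, x$nz, x$voxel_size,
              x$nx * x$voxel_size, x$ny * x$voxel_size, x$nz * x$voxel_size))
  invisible(x)
}

#' Physical extent of a grid in mm
#' @param grid a [voxel_grid()].
#' @return Named numeric vector with the x, y, z extents.
#' @export
grid_extent <- function(grid) {
  c(x = grid$nx, y = grid$ny, z = grid$nz) * grid$voxel_size
}

#' Voxel-centre coordinates along one axis
#' @param grid a [voxel_grid()].
#' @param axis one of "x", "y", "z".
#' @return Numeric vector of centre coordinates in mm.
#' @export
voxel_centers <- function(grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  n <- switch(axis, x = grid$nx, y = grid$ny, z = grid$nz)
  (seq_len(n) - 0.5) * grid$voxel_size
}

grids_equal <- function(a, b) {
  identical(a[c("nx", "ny", "nz")], b[c("nx", "ny", "nz")]) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

grid_dims <- function(grid) c(grid$nx, grid$ny, grid$nz)
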