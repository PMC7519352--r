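#' Homogeneous optical medium
#'
#' Builds a voxelized turbid medium with uniform absorption, scattering,
#' anisotropy and refractive index. This is the digital analog of an
#' intralipid phantom: a homogeneous scattering slab bounded above by the
#' air interface at z = 0.
#'
#' @param grid a [voxel_grid()].
#' @param mua absorption coefficient, mm^-1 (>= 0).
#' @param mus scattering coefficient, mm^-1. Must be > 0 for transport;
#'   `mus = 0` is permitted only with `allow_zero_scatter = TRUE`, the
#'   analytic Beer-Lambert test mode (flagged in the object).
#' @param g scattering anisotropy, -1 < g < 1 (Henyey-Greenstein).
#' @param n refractive index, >= 1 (ambient above the surface is 1).
#' @param allow_zero_scatter permit a non-scattering medium (test mode).
#' @return An object of class `flot_medium`. Optical properties are stored
#'   as scalars for homogeneous media; [as_medium_arrays()] expands them.
#' @examples
#' g <- voxel_grid(64, 32, 50, 0.02)
#' m <- make_homogeneous_medium(g, mua = 0.01, mus = 15, g = 0.9, n = 1.33)
#' reduced_scattering(m)  # mus * (1 - g) = 1.5 mm^-1
#' @export
make_homogeneous_medium <- function(grid, mua, mus, g, n,
                                    allow_zero_scatter = FALSE) {
  stopifnot(inherits(grid, "flot_grid"))
  if (!is.finite(mua) || mua < 0) stop("mua must be >= 0", call. = FALSE)
  if (!is.finite(mus) || mus < 0 || (mus == 0 && !allow_zero_scatter))
    stop("mus must be > 0 (zero-scatter only in analytic test mode)",
         call. = FALSE)
  if (!is.finite(g) || g <= -1 || g >= 1)
    stop("g must satisfy -1 < g < 1", call. = FALSE)
  if (!is.finite(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  structure(
    list(grid = grid, mua = mua, mus = mus, g = g, n = n,
         exterior = NULL, disabled_scatter = (mus == 0)),
    class = "flot_medium"
  )
}

#' Uniform slab medium with an optional curved surface
#'
#' Stand-in for tissue such as an ex vivo brain treated as a uniform
#' attenuator. If a surface height field is supplied, voxels whose centre
#' lies above the local surface are marked exterior (no interaction,
#' ambient index); transport through them is free flight.
#'
#' @inheritParams make_homogeneous_medium
#' @param surface_height optional `nx x ny` matrix of surface depths (mm,
#'   measured from z = 0 downward); `NULL` or all-zero gives a flat slab
#'   identical to [make_homogeneous_medium()].
#' @return A `flot_medium`; `$exterior` is a logical array when curved.
#' @export
brain_like_medium <- function(grid, mua, mus, g, n, surface_height = NULL) {
  med <- make_homogeneous_medium(grid, mua, mus, g, n)
  if (is.null(surface_height)) return(med)
  if (!is.matrix(surface_height) ||
      nrow(surface_height) != grid$nx || ncol(surface_height) != grid$ny)
    stop("surface_height must be an nx x ny matrix", call. = FALSE)
  if (all(surface_height == 0)) return(med)
  zc <- voxel_centers(grid, "z")
  ext <- array(FALSE, grid_dims(grid))
  for (iz in seq_len(grid$nz)) ext[, , iz] <- zc[iz] < surface_height
  med$exterior <- ext
  med
}

#' Expand a medium to per-voxel property arrays
#'
#' @param medium a `flot_medium`.
#' @return List of arrays `mua`, `mus`, `g`, `n` of the grid's dimensions
#'   (or length-1 vectors for a fully homogeneous medium, which the
#'   transport engine treats as uniform).
#' @export
as_medium_arrays <- function(medium) {
  if (is.null(medium$exterior))
    return(list(mua = medium$mua, mus = medium$mus,
                g = medium$g, n = medium$n))
  d <- grid_dims(medium$grid)
  mk <- function(v, outside) { a <- array(v, d); a[medium$exterior] <- outside; a }
  list(mua = mk(medium$mua, 0), mus = mk(medium$mus, 0),
       g = mk(medium$g, 0), n = mk(medium$n, 1))
}

#' Reduced scattering coefficient mus' = mus (1 - g)
#' @param medium a `flot_medium`.
#' @return mus' in mm^-1.
#' @export
reduced_scattering <- function(medium) medium$mus * (1 - medium$g)

#' @exportS3Method print flot_medium
print.flot_medium <- function(x, ...) {
  cat(sprintf(
    "<flot_medium> mua=%g mus=%g g=%g n=%g (mus'=%g mm^-1)%s%s\n",
    x$mua, x$mus, x$g, x$n, reduced_scattering(x),
    if (x$disabled_scatter) " [disabled-scatter test mode]" else "",
    if (!is.null(x$exterior)) " [curved surface]" else ""))
  print(x$grid)
  invisible(x)
}

#' Empty fluorophore map on a grid
#'
#' Per-voxel fluorescence yield in concentration-proportional arbitrary
#' units; the discretized object function of the Born forward model.
#'
#' @param grid a [voxel_grid()].
#' @return A `flot_fluoro` with an all-zero `yield` array.
#' @export
fluorophore_map <- function(grid) {
  stopifnot(inherits(grid, "flot_grid"))
  structure(list(grid = grid, yield = array(0, grid_dims(grid))),
            class = "flot_fluoro")
}

#' Embed a tilted capillary of fluorophore
#'
#' Sets every voxel whose centre lies within `inner_diameter / 2` of a
#' straight capillary axis to `value`, leaving all other voxels unchanged.
#' The axis lies in the x-z plane (the scan-direction vertical plane): it
#' enters the surface at `entry_x` and descends at `tilt_deg` toward +x.
#' The glass wall is not modeled; only the fluorophore core carries yield.
#'
#' @param map a [fluorophore_map()].
#' @param inner_diameter capillary inner diameter, mm.
#' @param tilt_deg tilt from the surface plane, degrees, in (0, 90).
#' @param entry_x surface x-coordinate (mm) where the axis crosses z = 0.
#' @param y_center y-coordinate (mm) of the axis plane; defaults to the
#'   grid mid-plane.
#' @param value fluorescence yield assigned to capillary voxels.
#' @return The updated `flot_fluoro`.
#' @export
embed_capillary <- function(map, inner_diameter, tilt_deg, entry_x,
                            y_center = NULL, value = 1) {
  stopifnot(inherits(map, "flot_fluoro"))
  if (!is.finite(inner_diameter) || inner_diameter <= 0)
    stop("inner_diameter must be > 0", call. = FALSE)
  if (!is.finite(tilt_deg) || tilt_deg <= 0 || tilt_deg >= 90)
    stop("tilt_deg must be in (0, 90)", call. = FALSE)
  if (value < 0) stop("value must be >= 0", call. = FALSE)
  g <- map$grid
  ex <- grid_extent(g)
  if (entry_x < 0 || entry_x >= ex["x"])
    stop("entry_x outside the grid footprint", call. = FALSE)
  if (is.null(y_center)) y_center <- ex["y"] / 2

  xc <- voxel_centers(g, "x"); yc <- voxel_centers(g, "y")
  zc <- voxel_centers(g, "z")
  th <- tilt_deg * pi / 180
  # axis direction (cos th, 0, sin th); distance of point p to the line
  # through (entry_x, y_center, 0)
  ax <- cos(th); az <- sin(th)
  r <- inner_diameter / 2

  # quick feasibility: does the axis intersect the grid volume at all?
  zx <- (xc - entry_x) * tan(th)
  if (all(zx < 0 | zx >= ex["z"]) && entry_x < 0)
    stop("capillary axis entirely outside the grid", call. = FALSE)

  dy2 <- (yc - y_center)^2
  touched <- FALSE
  for (iz in seq_len(g$nz)) {
    dz <- zc[iz]
    # projection of (dx, dz) onto the axis, then squared distance in-plane
    px <- xc - entry_x
    tproj <- px * ax + dz * az
    d2 <- (px - tproj * ax)^2 + (dz - tproj * az)^2
    ok_x <- which(d2 <= r^2)
    if (!length(ok_x)) next
    for (ixi in ok_x) {
      sel <- d2[ixi] + dy2 <= r^2
      if (any(sel)) {
        map$yield[ixi, sel, iz] <- value
        touched <- TRUE
      }
    }
  }
  if (!touched && value > 0)
    stop("capillary axis entirely outside the grid", call. = FALSE)
  map
}

#' Ground-truth capillary axis depth as a function of x
#'
#' @param entry_x surface entry x, mm.
#' @param tilt_deg tilt from the surface, degrees.
#' @param x numeric vector of x positions, mm.
#' @return Depth z(x) in mm (negative before the entry point).
#' @export
capillary_axis_depth <- function(entry_x, tilt_deg, x) {
  (x - entry_x) * tan(tilt_deg * pi / 180)
}
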