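#' Illumination source specification
#'
#' A pencil beam or a Gaussian-profile line beam incident on the surface.
#' The incidence angle is measured between the beam and the surface plane
#' on the +x side (135 deg, the instrument geometry, means 45 deg from the
#' surface normal with the refracted beam tilted toward +x).
#'
#' @param kind `"pencil"` or `"line"`.
#' @param position `(x, y)` surface position in mm (for a line, `x` of the
#'   line; `y` is ignored and the line spans `y_range`).
#' @param incidence_deg angle between beam and surface plane, in (90, 180).
#'   90 + 90 = 180 would be grazing; normal incidence is 90... measured as
#'   on the instrument: 135 deg means the beam arrives 45 deg off normal.
#' @param fwhm_mm Gaussian full width at half maximum of the line profile
#'   across the line (x direction), mm. Default 0.02 (20 um).
#' @param y_range along-line extent `(y0, y1)` in mm for a line source;
#'   `NULL` spans the full grid when used.
#' @param wavelength_nm metadata only.
#' @return An object of class `flot_source`.
#' @export
source_spec <- function(kind = c("pencil", "line"), position = c(0, 0),
                        incidence_deg = 135, fwhm_mm = 0.02,
                        y_range = NULL, wavelength_nm = 690) {
  kind <- match.arg(kind)
  if (!is.finite(incidence_deg) || incidence_deg < 90 || incidence_deg >= 180)
    stop("incidence_deg must be in [90, 180): 90 is normal incidence",
         call. = FALSE)
  if (!is.finite(fwhm_mm) || fwhm_mm <= 0)
    stop("fwhm_mm must be > 0", call. = FALSE)
  structure(list(kind = kind, position = position,
                 incidence_deg = incidence_deg, fwhm_mm = fwhm_mm,
                 y_range = y_range, wavelength_nm = wavelength_nm),
            class = "flot_source")
}

# Refracted in-medium launch direction and Fresnel transmit weight for a
# beam hitting the surface at `incidence_deg` to the surface plane,
# ambient n = 1 into medium index n_med. Returns list(dir, weight).
launch_refraction <- function(incidence_deg, n_med) {
  theta_i <- (incidence_deg - 90) * pi / 180  # from the surface normal
  si <- sin(theta_i)
  st <- si / n_med
  theta_t <- asin(st)
  ci <- cos(theta_i); ct <- cos(theta_t)
  rs <- (ci - n_med * ct) / (ci + n_med * ct)
  rp <- (ct - n_med * ci) / (ct + n_med * ci)
  R <- 0.5 * (rs^2 + rp^2)
  list(dir = c(sin(theta_t), 0, cos(theta_t)), weight = 1 - R)
}

mc_run <- function(medium, launch_kind, pos, dir, sigma, y_range, weight,
                   n_photons, seed, periodic_y = FALSE, cone_sin2 = 1) {
  if (n_photons < 1) stop("n_photons must be >= 1", call. = FALSE)
  arr <- as_medium_arrays(medium)
  if (anyNA(arr$mua) || anyNA(arr$mus))
    stop("NaN in medium optical properties", call. = FALSE)
  if (all(arr$mua + arr$mus == 0))
    stop("zero mu_t everywhere: photons never interact", call. = FALSE)
  g <- medium$grid
  mc_transport(grid_dims(g), g$voxel_size,
               as.numeric(arr$mua), as.numeric(arr$mus),
               as.numeric(arr$g), as.numeric(arr$n),
               launch_kind, as.numeric(pos), as.numeric(dir),
               sigma, as.numeric(y_range), weight,
               n_photons, seed, periodic_y, cone_sin2)
}

new_field <- function(res, grid, class2, meta) {
  structure(list(grid = grid, values = res$fluence,
                 absorbed = res$absorbed, escaped = res$escaped,
                 launched = res$launched, audit = res$audit, meta = meta),
            class = c(class2, "flot_field"))
}

#' @exportS3Method print flot_field
print.flot_field <- function(x, ...) {
  cat(sprintf("<%s> max=%.4g mm^-2, audit=%.6f (n=%g photons, seed=%g)\n",
              class(x)[1], max(x$values), x$audit,
              x$meta$n_photons, x$meta$seed))
  invisible(x)
}

#' Excitation fluence by voxel Monte Carlo
#'
#' Transports `n_photons` through the medium with exponential step sampling
#' at mu_t = mu_a + mu_s, Henyey-Greenstein scattering, continuous
#' absorption weighting, Russian roulette (threshold 1e-4, survival 0.1),
#' Fresnel reflection/refraction at the z = 0 surface against ambient
#' n = 1, and termination at the lateral/bottom faces. Fluence is the
#' track-length estimate per voxel, mm^-2 per launched photon.
#'
#' @param medium a `flot_medium`.
#' @param source a [source_spec()]. A pencil source launches at
#'   `source$position`; incidence is refracted at the surface and the
#'   specular loss is booked as escaped weight.
#' @param n_photons photon budget (>= 1).
#' @param seed integer seed for the transport RNG (bit-reproducible).
#' @return A `flot_fluence` with `$values` (grid-shaped array), the energy
#'   audit `(absorbed + escaped) / launched`, and provenance metadata.
#' @examples
#' \donttest{
#' g <- voxel_grid(21, 21, 30, 0.05)
#' m <- make_homogeneous_medium(g, 0.01, 15, 0.9, 1.33)
#' src <- source_spec("pencil", position = c(0.525, 0.525),
#'                    incidence_deg = 135)
#' f <- simulate_fluence(m, src, n_photons = 1e4, seed = 1)
#' }
#' @export
simulate_fluence <- function(medium, source, n_photons, seed) {
  stopifnot(inherits(source, "flot_source"))
  lr <- launch_refraction(source$incidence_deg, medium$n)
  pos <- c(source$position[1], source$position[2], 0)
  yr <- source$y_range
  if (is.null(yr)) yr <- c(0, grid_extent(medium$grid)["y"])
  kind <- if (source$kind == "line") 1L else 0L
  sigma <- source$fwhm_mm / (2 * sqrt(2 * log(2)))
  res <- mc_run(medium, kind, pos, lr$dir, sigma, yr, lr$weight,
                n_photons, seed)
  new_field(res, medium$grid, "flot_fluence",
            list(source = source, n_photons = n_photons, seed = seed,
                 disabled_scatter = medium$disabled_scatter))
}

#' Line-source excitation fluence
#'
#' Superposition of oblique launches distributed uniformly along y with the
#' Gaussian cross-line profile; in a homogeneous slab the resulting field
#' is y-invariant away from the y-edges.
#'
#' @inheritParams simulate_fluence
#' @param source a line [source_spec()]; `y_range = NULL` spans the grid.
#' @return A `flot_fluence`.
#' @export
line_source_fluence <- function(medium, source, n_photons, seed) {
  if (source$kind != "line") source$kind <- "line"
  simulate_fluence(medium, source, n_photons, seed)
}

#' Emission Green's function by adjoint Monte Carlo
#'
#' Reciprocity: adjoint photons are launched from the detector pixel into
#' the medium and the per-voxel visitation fluence is recorded, giving a
#' field proportional to the probability that emission from each voxel is
#' detected at that pixel. The launch distribution over the inward
#' hemisphere is cosine-weighted by default (camera normal to the surface,
#' collection NA unspecified); `acceptance = "normal"` launches a normal
#' pencil instead, which makes the field identical (within MC error) to
#' the fluence of a normally incident pencil source — the reciprocity
#' cross-check. Normalization matches [simulate_fluence()] so that Born
#' products are comparable across pixels.
#'
#' @param medium a `flot_medium`.
#' @param detector list with `position = c(x, y)` (mm, on the surface).
#' @param n_photons photon budget.
#' @param seed transport seed.
#' @param acceptance `"cosine"` (default) or `"normal"`.
#' @param na numerical aperture of the collection optics; the acceptance
#'   cone in the medium has half-angle `asin(na / n)`. `NULL` (or `>= n`)
#'   collects over the full inward hemisphere — a surface-contact
#'   detector. An imaging system (camera behind an objective) is
#'   NA-limited and cannot see the grazing near-field flux a contact
#'   detector would.
#' @return A `flot_green`.
#' @export
emission_green <- function(medium, detector, n_photons, seed,
                           acceptance = c("cosine", "normal"),
                           na = NULL) {
  acceptance <- match.arg(acceptance)
  pos <- c(detector$position[1], detector$position[2], 0)
  cone_sin2 <- if (is.null(na) || na >= medium$n) 1 else (na / medium$n)^2
  if (acceptance == "cosine") {
    kind <- 2L; dir <- c(0, 0, 1); w <- 1
  } else {
    kind <- 0L; dir <- c(0, 0, 1)
    w <- 1 - ((medium$n - 1) / (medium$n + 1))^2  # normal-incidence Fresnel
  }
  res <- mc_run(medium, kind, pos, dir, 0, c(0, 0), w, n_photons, seed,
                cone_sin2 = cone_sin2)
  new_field(res, medium$grid, "flot_green",
            list(detector = detector, acceptance = acceptance,
                 n_photons = n_photons, seed = seed))
}
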