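#' Line-scan acquisition specification
#'
#' Geometry and camera model of the stage-scanned acquisition: the line
#' beam is fixed, the sample moves in x through `n_positions` stage steps,
#' and at each step the camera (normal to the surface) records a frame of
#' `n_offset` source-detector offset bins by `n_along` along-line bins.
#' The physical CCD pitch is 2.9 um; `detector_pitch_mm` is the effective
#' binned pitch on the sample (the full-resolution chip is binned to keep
#' the measurement count tractable; the bin factor is recorded).
#'
#' @param n_positions stage positions (default 300).
#' @param stage_step mm moved per position.
#' @param detector_pitch_mm effective detector bin pitch on the sample, mm.
#' @param pixel_pitch_mm physical camera pixel pitch, mm (metadata).
#' @param n_offset number of offset bins (bin 1 is the source line itself,
#'   rendered as the leakage column).
#' @param n_along number of along-line bins.
#' @param bit_depth camera bit depth, one of 8, 12, 16.
#' @param noise list: `photon_scale` (Poisson scaling: counts are
#'   `rpois(photon_scale * counts) / photon_scale`; `Inf` disables shot
#'   noise), `read_sigma` (Gaussian read noise sd, counts), `background`
#'   (dark level N0, counts).
#' @param stage_x0 x of the source line over the sample at the first
#'   position, mm.
#' @return An object of class `flot_acq`.
#' @export
acquisition_spec <- function(n_positions = 300, stage_step = 0.01,
                             detector_pitch_mm = 0.0029,
                             pixel_pitch_mm = 0.0029,
                             n_offset = 128, n_along = 64,
                             bit_depth = 12,
                             noise = list(photon_scale = 1,
                                          read_sigma = 5,
                                          background = 100),
                             stage_x0 = 0) {
  if (n_positions < 1) stop("n_positions must be >= 1", call. = FALSE)
  if (stage_step <= 0) stop("stage_step must be > 0", call. = FALSE)
  if (!bit_depth %in% c(8, 12, 16))
    stop("bit_depth must be 8, 12 or 16", call. = FALSE)
  noise <- modifyList(list(photon_scale = 1, read_sigma = 5,
                           background = 100), noise)
  if (noise$read_sigma < 0 || noise$background < 0 ||
      (is.finite(noise$photon_scale) && noise$photon_scale <= 0))
    stop("noise parameters must be nonnegative (photon_scale > 0)",
         call. = FALSE)
  structure(list(n_positions = as.integer(n_positions),
                 stage_step = stage_step,
                 detector_pitch_mm = detector_pitch_mm,
                 pixel_pitch_mm = pixel_pitch_mm,
                 n_offset = as.integer(n_offset),
                 n_along = as.integer(n_along),
                 bit_depth = as.integer(bit_depth),
                 noise = noise, stage_x0 = stage_x0),
            class = "flot_acq")
}

#' @exportS3Method print flot_acq
print.flot_acq <- function(x, ...) {
  cat(sprintf(
    "<flot_acq> %d positions @ %g mm, frames %d x %d @ %g mm, %d-bit\n",
    x$n_positions, x$stage_step, x$n_offset, x$n_along,
    x$detector_pitch_mm, x$bit_depth))
  invisible(x)
}

stage_positions <- function(acq) {
  acq$stage_x0 + (seq_len(acq$n_positions) - 1) * acq$stage_step
}

new_stack <- function(frames, acq, source_col = 1L, noiseless = FALSE,
                      meta = list()) {
  structure(list(frames = frames, acq = acq, source_col = source_col,
                 noiseless = noiseless, meta = meta),
            class = "flot_stack")
}

#' @exportS3Method print flot_stack
print.flot_stack <- function(x, ...) {
  cat(sprintf("<flot_stack> %d frames of %d x %d (%s), max=%g\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              if (x$noiseless) "noiseless" else "counts", max(x$frames)))
  invisible(x)
}

#' Mask of usable detector pixels in a stack
#'
#' TRUE everywhere except the registered source-line (leakage) column.
#' @param stack a `flot_stack`.
#' @return Logical array of the stack's dimensions.
#' @export
leakage_mask <- function(stack) {
  m <- array(TRUE, dim(stack$frames))
  m[, stack$source_col, ] <- FALSE
  m
}

#' Simulate a line-scan FLOT acquisition
#'
#' Forward-simulates the oblique measurement stack: for each stage
#' position the noiseless frame is the discretized Born integral
#' `sum_v G(r_d - r') O(r') Phi(r' - r_s)` evaluated with
#' translation-invariant Monte Carlo kernels (one kernel pair reused
#' across positions, valid in the homogeneous slab). The noiseless signal
#' is scaled to camera counts (brightest pixel at ~50% full scale unless
#' `counts_scale` is given), the source-line leakage is rendered as a
#' saturating bright column at offset 0, and CCD noise is applied via
#' [add_noise()] unless disabled.
#'
#' @param medium homogeneous `flot_medium`.
#' @param fluoro `flot_fluoro` on the same grid.
#' @param acq an [acquisition_spec()].
#' @param mc_budget photons per Monte Carlo kernel.
#' @param seed integer seed driving both the transport RNG and the noise.
#' @param kernels optional precomputed [mc_kernels()] (must contain
#'   `phi2d` and `g3d`); when `NULL` they are computed at `mc_budget`.
#' @param counts_scale counts per unit noiseless signal; `NULL` scales the
#'   brightest noiseless pixel to half full scale (auto-exposure). Pass the
#'   scale of a companion stack to make blanks comparable.
#' @param noise apply the CCD noise model.
#' @param y_center_mm y of the capillary plane (defaults to grid centre);
#'   detector along-line bins are centred there.
#' @return A `flot_stack` of dimension
#'   `(n_positions, n_offset, n_along)`.
#' @export
simulate_scan <- function(medium, fluoro, acq, mc_budget = 1e6, seed = 1,
                          kernels = NULL, counts_scale = NULL,
                          noise = TRUE, y_center_mm = NULL) {
  stopifnot(inherits(medium, "flot_medium"), inherits(fluoro, "flot_fluoro"))
  if (!grids_equal(medium$grid, fluoro$grid))
    stop("medium and fluorophore map must share a grid", call. = FALSE)
  g <- medium$grid
  h <- g$voxel_size
  ex <- grid_extent(g)
  if (is.null(y_center_mm)) y_center_mm <- ex["y"] / 2
  ydet <- y_center_mm + (seq_len(acq$n_along) - (acq$n_along + 1) / 2) *
    acq$detector_pitch_mm
  if (min(ydet) < 0 || max(ydet) > ex["y"])
    stop("acquisition along-line footprint exceeds the grid", call. = FALSE)
  offs <- (seq_len(acq$n_offset) - 1) * acq$detector_pitch_mm
  sx <- stage_positions(acq)
  if (max(sx) > ex["x"] + 1e-9)
    stop("stage scan footprint exceeds the grid", call. = FALSE)

  if (is.null(kernels)) {
    src <- source_spec("line", incidence_deg = 135)
    kernels <- mc_kernels(medium, src, n_photons = mc_budget, seed = seed,
                          what = c("phi", "g3"))
  }
  if (is.null(kernels$phi2d) || is.null(kernels$g3d))
    stop("kernels must provide phi2d and g3d", call. = FALSE)

  idx <- which(fluoro$yield > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    ovox <- cbind((idx[, 1] - 0.5) * h, (idx[, 2] - 0.5) * h,
                  (idx[, 3] - 0.5) * h, fluoro$yield[idx])
    frames <- born_forward_stack(kernels$phi2d, kernels$cx,
                                 as.numeric(kernels$g3d), dim(kernels$g3d),
                                 kernels$cgx, kernels$cgy, h,
                                 ovox, sx, offs, ydet)
  } else {
    frames <- array(0, c(acq$n_positions, acq$n_offset, acq$n_along))
  }

  full <- 2^acq$bit_depth - 1
  if (is.null(counts_scale)) {
    peak <- if (acq$n_offset > 1) max(frames[, -1, , drop = FALSE]) else max(frames)
    counts_scale <- if (peak > 0) 0.5 * full / peak else 1
  }
  frames <- frames * counts_scale
  # source-line light leakage: bright saturating column at offset 0
  frames[, 1, ] <- 10 * max(frames, full)

  st <- new_stack(frames, acq, source_col = 1L, noiseless = TRUE,
                  meta = list(seed = seed, mc_budget = mc_budget,
                              counts_scale = counts_scale,
                              kernel_seed = kernels$meta$seed,
                              y_center_mm = y_center_mm,
                              ydet = ydet, offsets_mm = offs))
  if (noise) st <- add_noise(st, acq, seed = derive_seed(seed, 9))
  st
}

#' Apply the CCD noise model to a noiseless stack
#'
#' counts -> Poisson(photon_scale x counts) / photon_scale
#'           + Gaussian(0, read_sigma) + background, then quantized and
#' clipped to the bit depth. `photon_scale = Inf` disables shot noise.
#'
#' @param stack a noiseless `flot_stack`.
#' @param acq acquisition spec carrying the noise parameters (defaults to
#'   the stack's own).
#' @param seed RNG seed (R RNG, restored on exit).
#' @return The quantized noisy `flot_stack`.
#' @export
add_noise <- function(stack, acq = stack$acq, seed = 1) {
  nz <- acq$noise
  v <- stack$frames
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% 2147483647)
  if (is.finite(nz$photon_scale)) {
    lam <- pmax(v * nz$photon_scale, 0)
    v <- array(rpois(length(lam), lam), dim(lam)) / nz$photon_scale
  }
  if (nz$read_sigma > 0)
    v <- v + array(rnorm(length(v), 0, nz$read_sigma), dim(v))
  v <- v + nz$background
  full <- 2^acq$bit_depth - 1
  stack$frames <- pmin(pmax(round(v), 0), full)
  stack$noiseless <- FALSE
  stack$meta$noise_seed <- seed
  stack
}

#' Digital phantom recipes
#'
#' `"paper_phantom"`: a homogeneous intralipid-like slab (mua = 0.01,
#' mus = 15, g = 0.9, n = 1.33 at 690 nm; mus' = 1.5 mm^-1) containing a
#' 100-um-ID capillary of fluorophore (yield 2.5, concentration units)
#' tilted 23.5 deg from the surface, scanned over 300 stage positions.
#' `"paper_exvivo_analog"`: a synthetic uniform brain-like slab (the real
#' tissue's optical properties are not published; defaults are typical
#' cortex-like values) with a 150-um-ID capillary.
#'
#' @param name recipe name.
#' @param voxel_size_mm grid resolution (desk-scale default 0.025).
#' @param nx,ny,nz grid size; the default x extent (5.6 mm) covers the
#'   3.2-mm capillary descent plus the detector offset span.
#' @param scan_extent_mm stage travel covered by the 300 positions.
#' @param max_offset_mm largest detector offset recorded in the frames
#'   (source-detector separations up to ~2x the target depth are what
#'   carry deep sensitivity).
#' @param mus override the scattering coefficient (ex vivo analog).
#' @param inner_diameter_mm capillary inner diameter override.
#' @param noise CCD noise parameters (see [acquisition_spec()]).
#' @return List with `medium`, `fluoro`, `acq`, and `geometry` (capillary
#'   entry x, tilt, diameter, yield, y centre).
#' @export
phantom_recipe <- function(name = c("paper_phantom", "paper_exvivo_analog"),
                           voxel_size_mm = 0.025, nx = 224, ny = 52, nz = 56,
                           scan_extent_mm = 3.2, max_offset_mm = 2.4,
                           mus = NULL, inner_diameter_mm = NULL,
                           noise = list(photon_scale = 1, read_sigma = 5,
                                        background = 100)) {
  if (!name[1] %in% c("paper_phantom", "paper_exvivo_analog"))
    stop("unknown recipe '", name[1],
         "'; known recipes: paper_phantom, paper_exvivo_analog",
         call. = FALSE)
  name <- match.arg(name)
  grid <- voxel_grid(nx, ny, nz, voxel_size_mm)
  if (name == "paper_phantom") {
    medium <- make_homogeneous_medium(grid, mua = 0.01,
                                      mus = if (is.null(mus)) 15 else mus,
                                      g = 0.9, n = 1.33)
    id <- if (is.null(inner_diameter_mm)) 0.10 else inner_diameter_mm
  } else {
    medium <- make_homogeneous_medium(grid, mua = 0.02,
                                      mus = if (is.null(mus)) 20 else mus,
                                      g = 0.9, n = 1.37)
    id <- if (is.null(inner_diameter_mm)) 0.15 else inner_diameter_mm
  }
  ex <- grid_extent(grid)
  entry_x <- 0.2
  ycen <- unname(ex["y"] / 2)
  fl <- embed_capillary(fluorophore_map(grid), inner_diameter = id,
                        tilt_deg = 23.5, entry_x = entry_x,
                        y_center = ycen, value = 2.5)
  acq <- acquisition_spec(
    n_positions = 300,
    stage_step = (scan_extent_mm - voxel_size_mm) / 300,
    detector_pitch_mm = voxel_size_mm,
    pixel_pitch_mm = 0.0029,
    n_offset = as.integer(round(max_offset_mm / voxel_size_mm)) + 1L,
    n_along = ny, bit_depth = 12, noise = noise,
    stage_x0 = voxel_size_mm / 2)
  list(medium = medium, fluoro = fl, acq = acq,
       geometry = list(name = name, entry_x = entry_x, tilt_deg = 23.5,
                       inner_diameter_mm = id, yield = 2.5,
                       y_center = ycen, outer_diameter_mm = 0.17))
}
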