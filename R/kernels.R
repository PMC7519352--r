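# Translation-invariant Monte Carlo kernels for the homogeneous-slab
# fast path: one excitation/emission kernel pair serves every stage
# position and detector offset (block-convolutional forward model).

derive_seed <- function(seed, k) as.numeric((seed * 7 + k * 1000003) %% 2147483647)

#' Monte Carlo kernel pair for the line-scan forward model
#'
#' Computes, on a relative-coordinate grid centred on the source line /
#' detector pixel, the excitation fluence of the oblique Gaussian line beam
#' (`phi2d`, y-invariant), the emission Green's function of an along-line
#' detector column (`g2d`, y-invariant, cosine acceptance) and optionally
#' the point-pixel Green's function resolved in dy (`g3d`). The y-invariant
#' kernels are run with a periodic y boundary, which is exact for a line
#' unbounded in y over a homogeneous slab.
#'
#' @param medium a homogeneous `flot_medium` (its grid sets the depth and
#'   the voxel size of the kernels).
#' @param source a [source_spec()] giving incidence angle and line FWHM.
#' @param x_half_mm lateral half-extent of the kernel in x, mm.
#' @param y_half_mm half-extent in dy for the point kernel, mm.
#' @param n_photons photon budget per kernel.
#' @param seed base transport seed; sub-kernels use derived seeds.
#' @param what which kernels to compute.
#' @param collection_na numerical aperture of the imaging objective for
#'   the emission kernels (acceptance cone half-angle `asin(na / n)` in
#'   the medium). The default 0.12 is a low-magnification imaging
#'   objective; `NULL` means a surface-contact cosine detector.
#' @return A `flot_kernels` list: `phi2d` (nkx x nz), `g2d`, `g3d`
#'   (ngx x ngy x nz), centre indices `cx`, `cgx`, `cgy` (1-based),
#'   voxel size `h`, and provenance.
#' @export
mc_kernels <- function(medium, source, x_half_mm = 2.8, y_half_mm = 0.64,
                       n_photons = 1e6, seed = 1,
                       what = c("phi", "g2", "g3"),
                       collection_na = 0.12) {
  stopifnot(inherits(medium, "flot_medium"), is.null(medium$exterior))
  h <- medium$grid$voxel_size
  nz <- medium$grid$nz
  nkx <- 2L * as.integer(round(x_half_mm / h)) + 1L
  cx <- (nkx + 1L) %/% 2L
  cone_sin2 <- if (is.null(collection_na) || collection_na >= medium$n) 1
               else (collection_na / medium$n)^2
  ker <- list(h = h, nz = nz, cx = cx,
              meta = list(mua = medium$mua, mus = medium$mus,
                          g = medium$g, n = medium$n,
                          source = source, n_photons = n_photons,
                          seed = seed, collection_na = collection_na))
  x0 <- (cx - 0.5) * h
  lr <- launch_refraction(source$incidence_deg, medium$n)
  sigma <- source$fwhm_mm / (2 * sqrt(2 * log(2)))

  lin_grid <- voxel_grid(nkx, 1L, nz, h)
  lin_med <- make_homogeneous_medium(lin_grid, medium$mua, medium$mus,
                                     medium$g, medium$n,
                                     allow_zero_scatter = TRUE)

  if ("phi" %in% what) {
    res <- mc_run(lin_med, 1L, c(x0, 0, 0), lr$dir, sigma, c(0, h),
                  lr$weight, n_photons, derive_seed(seed, 1),
                  periodic_y = TRUE)
    ker$phi2d <- matrix(res$fluence, nkx, nz)
    ker$phi_audit <- res$audit
  }
  if ("g2" %in% what) {
    res <- mc_run(lin_med, 3L, c(x0, 0, 0), c(0, 0, 1), 0, c(0, h),
                  1, n_photons, derive_seed(seed, 2), periodic_y = TRUE,
                  cone_sin2 = cone_sin2)
    ker$g2d <- matrix(res$fluence, nkx, nz)
    ker$cxg <- cx
    ker$g2_audit <- res$audit
  }
  if ("g3" %in% what) {
    ngy <- 2L * as.integer(round(y_half_mm / h)) + 1L
    cgy <- (ngy + 1L) %/% 2L
    pt_grid <- voxel_grid(nkx, ngy, nz, h)
    pt_med <- make_homogeneous_medium(pt_grid, medium$mua, medium$mus,
                                      medium$g, medium$n,
                                      allow_zero_scatter = TRUE)
    y0 <- (cgy - 0.5) * h
    res <- mc_run(pt_med, 2L, c(x0, y0, 0), c(0, 0, 1), 0, c(0, 0),
                  1, n_photons, derive_seed(seed, 3),
                  cone_sin2 = cone_sin2)
    ker$g3d <- array(res$fluence, c(nkx, ngy, nz))
    ker$cgx <- cx
    ker$cgy <- cgy
    ker$g3_audit <- res$audit
  }
  structure(ker, class = "flot_kernels")
}

#' @exportS3Method print flot_kernels
print.flot_kernels <- function(x, ...) {
  cat(sprintf("<flot_kernels> h=%g mm, nz=%d, seed=%g, photons=%g [%s]\n",
              x$h, x$nz, x$meta$seed, x$meta$n_photons,
              paste(intersect(c("phi2d", "g2d", "g3d"), names(x)),
                    collapse = ", ")))
  invisible(x)
}
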