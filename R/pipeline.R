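#' Validated pipeline configuration
#'
#' All randomness in a pipeline run flows from the two named seeds; the
#' measurement-simulation seed and the sensitivity-matrix seed must
#' differ (inverse-crime guard: the reconstruction must never be tested
#' against the identical Monte Carlo realization that generated its
#' forward model). Unknown parameter names are rejected.
#'
#' @param recipe phantom recipe name (see [phantom_recipe()]).
#' @param data_seed seed for the measurement simulation (kernels + noise).
#' @param w_seed seed for the sensitivity-matrix kernels.
#' @param mc_photons_data,mc_photons_w photon budgets.
#' @param gamma depth-compensation exponent (see [depth_compensate()]).
#'   The default 1 is the smallest strength that keeps the reconstructed
#'   capillary-axis depth tracking the ground truth monotonically over
#'   the full descent; without compensation deep segments are attributed
#'   to shallow voxels, and stronger exponents push shallow segments
#'   into deep artifacts.
#' @param lambda fixed regularization strength (`NULL` = L-curve).
#' @param stage_by use every k-th stage position as W rows.
#' @param y_halfwidth number of along-line columns on each side of the
#'   capillary plane to reconstruct (`NULL` = all).
#' @param ... recipe overrides forwarded to [phantom_recipe()]
#'   (e.g. `voxel_size_mm`, `nx`, `nz`, `noise`).
#' @return A validated `flot_config` list.
#' @export
pipeline_config <- function(recipe = "paper_phantom", data_seed = 1,
                            w_seed = 2, mc_photons_data = 1e6,
                            mc_photons_w = 1e6, gamma = 1,
                            lambda = NULL, stage_by = 5,
                            y_halfwidth = 12, ...) {
  if (identical(data_seed, w_seed))
    stop("inverse-crime guard: data_seed must differ from w_seed",
         call. = FALSE)
  extra <- list(...)
  allowed <- setdiff(names(formals(phantom_recipe)), "name")
  bad <- setdiff(names(extra), allowed)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(recipe = recipe, data_seed = data_seed, w_seed = w_seed,
                 mc_photons_data = mc_photons_data,
                 mc_photons_w = mc_photons_w, gamma = gamma,
                 lambda = lambda, stage_by = stage_by,
                 y_halfwidth = y_halfwidth, recipe_args = extra),
            class = "flot_config")
}

#' Run the full simulate / build-W / reconstruct / MIP / metrics pipeline
#'
#' Executes the complete in-silico experiment on a phantom recipe:
#' simulate the 300-position line scan with CCD noise, assemble the
#' sensitivity matrix from an independent Monte Carlo realization,
#' reconstruct the volume (Tikhonov + L-curve), build the raw-stack MIP
#' comparator, extract both depth-decay curves along the ground-truth
#' capillary track, measure resolution profiles, and compute the blank
#' N + 3 sigma limit of detection in reconstruction units. Deterministic
#' given the configuration seeds.
#'
#' @param config a [pipeline_config()].
#' @param blank also simulate and reconstruct a blank (no-capillary)
#'   stack for the limit of detection.
#' @return A `flot_run` list: `stack`, `W`, `recon`, `stack_volume`,
#'   `mips`, `flot_curve`, `mip_curve`, `resolution`, `lod`,
#'   `max_depth_mm`, `comparison`, `report` (plain-list summary with the
#'   config echo).
#' @export
run_pipeline <- function(config, blank = TRUE) {
  stopifnot(inherits(config, "flot_config"))
  ph <- do.call(phantom_recipe, c(list(name = config$recipe),
                                  config$recipe_args))
  medium <- ph$medium; acq <- ph$acq; geom <- ph$geometry
  src <- source_spec("line", incidence_deg = 135)

  data_kernels <- mc_kernels(medium, src,
                             n_photons = config$mc_photons_data,
                             seed = config$data_seed,
                             what = c("phi", "g3"))
  stack <- simulate_scan(medium, ph$fluoro, acq, seed = config$data_seed,
                         kernels = data_kernels)

  w_kernels <- mc_kernels(medium, src, n_photons = config$mc_photons_w,
                          seed = config$w_seed, what = c("phi", "g2"))
  W <- build_weight_matrix_conv(w_kernels, medium$grid, acq,
                                stage_sel = seq(1, acq$n_positions,
                                                by = config$stage_by))

  ny <- dim(stack$frames)[3]
  y_sel <- if (is.null(config$y_halfwidth)) seq_len(ny) else {
    mid <- (ny + 1) %/% 2
    max(1, mid - config$y_halfwidth):min(ny, mid + config$y_halfwidth)
  }
  recon <- reconstruct_volume(stack, W, lambda = config$lambda,
                              y_sel = y_sel, gamma = config$gamma)

  sv <- orthogonal_stack(stack, shear_correct = FALSE)
  mips <- mip(sv)

  track_r <- capillary_track(geom, grid = medium$grid, domain = "recon")
  track_s <- capillary_track(geom, acq = acq, domain = "stack")
  flot_curve <- depth_profile(recon, track_r)
  mip_curve <- depth_profile(mips$y, track_s)

  res_xy <- resolution_profile(recon, track_r, "xy", depth_um = 0)
  res_xz0 <- resolution_profile(recon, track_r, "xz", depth_um = 0)
  res_xz600 <- resolution_profile(recon, track_r, "xz", depth_um = 600)
  resolution <- rbind(cbind(res_xy, at = "surface"),
                      cbind(res_xz0, at = "surface"),
                      cbind(res_xz600, at = "600um"))

  lod <- NULL; max_depth_mm <- NA_real_
  if (blank) {
    blank_stack <- simulate_scan(medium, fluorophore_map(medium$grid),
                                 acq, seed = derive_seed(config$data_seed, 17),
                                 kernels = data_kernels,
                                 counts_scale = stack$meta$counts_scale)
    # only the along-line-summed (x-z) view enters the threshold, so a
    # single representative column keeps the blank solve cheap
    blank_recon <- reconstruct_volume(blank_stack, W,
                                      lambda = recon$lambda,
                                      background = recon$background,
                                      y_sel = (ny + 1) %/% 2,
                                      gamma = config$gamma)
    lod <- limit_of_detection(blank_recon$xz)
    raw_curve <- depth_profile(recon, track_r, normalize = FALSE)
    max_depth_mm <- max_detectable_depth(raw_curve, lod$threshold) / 1000
  }

  comparison <- compare_flot_mip(flot_curve, mip_curve)

  report <- list(
    config = unclass(config),
    lambda = recon$lambda,
    flot_1e_um = comparison$replicates$flot_1e_um,
    mip_1e_um = comparison$replicates$mip_1e_um,
    flot_at_500um_pct = 100 * intensity_at_depth(flot_curve, 500),
    fwhm_xy_um = res_xy$fwhm_um,
    fwhm_xz_surface_um = res_xz0$fwhm_um,
    fwhm_xz_600um_um = res_xz600$fwhm_um,
    max_detectable_depth_mm = max_depth_mm,
    lod = if (!is.null(lod)) unclass(lod))

  structure(list(stack = stack, W = W, recon = recon, stack_volume = sv,
                 mips = mips, flot_curve = flot_curve,
                 mip_curve = mip_curve, resolution = resolution,
                 lod = lod, max_depth_mm = max_depth_mm,
                 comparison = comparison, report = report,
                 geometry = geom, medium = medium, acq = acq),
            class = "flot_run")
}

#' @exportS3Method print flot_run
print.flot_run <- function(x, ...) {
  cat("<flot_run>\n")
  cat(sprintf("  lambda* = %.4g\n", x$recon$lambda))
  cat(sprintf("  1/e depth: FLOT %.0f um, MIP %.0f um\n",
              x$report$flot_1e_um, x$report$mip_1e_um))
  cat(sprintf("  FWHM: XY %.0f um, XZ(0) %.0f um, XZ(600) %.0f um\n",
              x$report$fwhm_xy_um, x$report$fwhm_xz_surface_um,
              x$report$fwhm_xz_600um_um))
  if (!is.na(x$max_depth_mm))
    cat(sprintf("  max detectable depth: %.2f mm\n", x$max_depth_mm))
  invisible(x)
}
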