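# Reduced-scale phantom runs shared across tests. Memoized so the
# acceptance blocks and the pipeline tests reuse the same computations.

.flot_test_cache <- new.env(parent = emptyenv())

test_recipe <- function() {
  phantom_recipe("paper_phantom", voxel_size_mm = 0.04, nx = 90, ny = 26,
                 nz = 32, scan_extent_mm = 2.0, max_offset_mm = 1.6)
}

# one reduced-scale end-to-end experiment (simulate -> W -> reconstruct
# -> curves), with independent data / W seeds
small_phantom_run <- function(seed, photons = 2e5) {
  key <- paste0("run_", seed, "_", photons)
  if (!is.null(.flot_test_cache[[key]])) return(.flot_test_cache[[key]])
  ph <- test_recipe()
  src <- source_spec("line", incidence_deg = 135)
  dk <- mc_kernels(ph$medium, src, x_half_mm = 2.0, y_half_mm = 0.5,
                   n_photons = photons, seed = seed, what = c("phi", "g3"))
  st <- simulate_scan(ph$medium, ph$fluoro, ph$acq, seed = seed,
                      kernels = dk)
  wk <- mc_kernels(ph$medium, src, x_half_mm = 2.0, n_photons = photons,
                   seed = seed + 5000, what = c("phi", "g2"))
  W <- build_weight_matrix_conv(wk, ph$medium$grid, ph$acq)
  rec <- reconstruct_volume(st, W, y_sel = 8:19, maxit = 120, gamma = 1)
  tr <- capillary_track(ph$geometry, grid = ph$medium$grid,
                        domain = "recon")
  ts <- capillary_track(ph$geometry, acq = ph$acq, domain = "stack")
  fc <- depth_profile(rec, tr)
  mcv <- depth_profile(mip(orthogonal_stack(st))$y, ts)
  out <- list(ph = ph, kernels = dk, stack = st, W = W, rec = rec,
              track = tr, track_stack = ts, flot_curve = fc,
              mip_curve = mcv)
  .flot_test_cache[[key]] <- out
  out
}

# shared phantom-medium kernels for sensitivity-ordering tests
phantom_kernels <- function(photons = 5e5, seed = 77) {
  key <- paste0("ker_", photons, "_", seed)
  if (!is.null(.flot_test_cache[[key]])) return(.flot_test_cache[[key]])
  med <- make_homogeneous_medium(voxel_grid(120, 1, 40, 0.04),
                                 0.01, 15, 0.9, 1.33)
  src <- source_spec("line", incidence_deg = 135)
  k <- mc_kernels(med, src, x_half_mm = 2.2, n_photons = photons,
                  seed = seed, what = c("phi", "g2"))
  out <- list(medium = med, kernels = k)
  .flot_test_cache[[key]] <- out
  out
}
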