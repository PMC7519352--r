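acq_small <- function(n_positions = 40, n_offset = 21, n_along = 10,
                      noise = list(photon_scale = 1, read_sigma = 5,
                                   background = 100)) {
  acquisition_spec(n_positions = n_positions, stage_step = 0.038,
                   detector_pitch_mm = 0.04, n_offset = n_offset,
                   n_along = n_along, bit_depth = 12, noise = noise,
                   stage_x0 = 0.02)
}

small_scene <- function(with_capillary = TRUE) {
  g <- voxel_grid(60, 12, 20, 0.04)
  med <- make_homogeneous_medium(g, 0.01, 15, 0.9, 1.33)
  fl <- fluorophore_map(g)
  if (with_capillary)
    fl <- embed_capillary(fl, 0.1, 23.5, 0.2, value = 2.5)
  list(medium = med, fluoro = fl)
}

scene_kernels <- function(seed = 31) {
  sc <- small_scene()
  mc_kernels(sc$medium, source_spec("line"), x_half_mm = 1.2,
             y_half_mm = 0.3, n_photons = 1e5, seed = seed,
             what = c("phi", "g3"))
}

test_that("simulated stacks have the acquisition geometry and a leakage
           column", {
  sc <- small_scene()
  st <- simulate_scan(sc$medium, sc$fluoro, acq_small(), seed = 1,
                      kernels = scene_kernels())
  expect_equal(dim(st$frames), c(40, 21, 10))
  expect_equal(st$source_col, 1L)
  expect_true(all(st$frames[, 1, ] == 4095))  # saturated leakage
  expect_true(all(st$frames >= 0 & st$frames <= 4095))
})

test_that("a blank scene produces background-level frames", {
  sc <- small_scene(with_capillary = FALSE)
  st <- simulate_scan(sc$medium, sc$fluoro, acq_small(), seed = 2,
                      kernels = scene_kernels())
  vals <- st$frames[leakage_mask(st)]
  expect_lt(abs(mean(vals) - 100), 2)
})

test_that("a single fluorophore voxel lights up the frame at its stage
           position and small offset", {
  sc <- small_scene(with_capillary = FALSE)
  fl <- sc$fluoro
  fl$yield[30, 6, 2] <- 5  # x = 1.18 mm, depth 60 um
  st <- simulate_scan(sc$medium, fl, acq_small(), seed = 3,
                      kernels = scene_kernels(), noise = FALSE)
  v <- st$frames
  v[, 1, ] <- 0  # exclude leakage
  pk <- which(v == max(v), arr.ind = TRUE)[1, ]
  sx <- stage_positions(acq_small())
  expect_lt(abs(sx[pk[1]] - 1.18), 0.12)  # frame near the voxel
  expect_lt(pk[2], 8)                     # small source-detector offset
})

test_that("noiseless stacks are linear in fluorophore yield", {
  sc <- small_scene()
  ker <- scene_kernels()
  st1 <- simulate_scan(sc$medium, sc$fluoro, acq_small(), seed = 4,
                       kernels = ker, noise = FALSE, counts_scale = 1)
  fl2 <- sc$fluoro; fl2$yield <- fl2$yield * 2
  st2 <- simulate_scan(sc$medium, fl2, acq_small(), seed = 4,
                       kernels = ker, noise = FALSE, counts_scale = 1)
  m <- leakage_mask(st1)
  expect_equal(st2$frames[m], 2 * st1$frames[m], tolerance = 1e-12)
})

test_that("deeper capillary segments return less signal near the line", {
  sc <- small_scene()
  st <- simulate_scan(sc$medium, sc$fluoro, acq_small(), seed = 5,
                      kernels = scene_kernels(), noise = FALSE,
                      counts_scale = 1)
  sx <- stage_positions(acq_small())
  depth <- capillary_axis_depth(0.2, 23.5, sx)
  sel <- which(depth > 0.1 & depth < 0.7)
  sig <- vapply(sel, function(i) max(st$frames[i, 2:4, ]), numeric(1))
  shallow <- mean(head(sig, 5)); deep <- mean(tail(sig, 5))
  expect_gt(shallow, deep)
})

test_that("the CCD noise model matches its moments and is deterministic", {
  acq <- acq_small(n_positions = 12, n_offset = 40, n_along = 40)
  blank <- structure(list(frames = array(500, c(12, 40, 40)), acq = acq,
                          source_col = 1L, noiseless = TRUE,
                          meta = list()), class = "flot_stack")
  noisy <- add_noise(blank, acq, seed = 11)
  vals <- noisy$frames[, -1, ] - 100 - 500
  expect_lt(abs(mean(vals)), 2)            # unbiased around the signal
  sd_expect <- sqrt(500 + 25)              # shot + read
  expect_lt(abs(sd(vals) - sd_expect) / sd_expect, 0.02)

  again <- add_noise(blank, acq, seed = 11)
  expect_identical(noisy$frames, again$frames)

  # noise-free limit: quantization only
  acq0 <- acq_small(noise = list(photon_scale = Inf, read_sigma = 0,
                                 background = 0))
  clean <- add_noise(blank, acq0, seed = 1)
  expect_equal(clean$frames, round(blank$frames))
  expect_error(acq_small(noise = list(read_sigma = -1)), "nonneg")
})

test_that("phantom recipes encode the study conditions", {
  ph <- phantom_recipe("paper_phantom")
  expect_equal(reduced_scattering(ph$medium), 1.5)
  expect_equal(ph$medium$n, 1.33)
  expect_equal(ph$geometry$tilt_deg, 23.5)
  expect_equal(ph$geometry$inner_diameter_mm, 0.10)
  expect_equal(ph$acq$n_positions, 300L)
  expect_equal(max(ph$fluoro$yield), 2.5)

  ex <- phantom_recipe("paper_exvivo_analog")
  expect_equal(ex$geometry$inner_diameter_mm, 0.15)

  expect_error(phantom_recipe("nope"), "paper_phantom")
})

test_that("the simulation seed is independent of the W seed by contract", {
  expect_error(pipeline_config(data_seed = 7, w_seed = 7),
               "inverse-crime")
  cfg <- pipeline_config(data_seed = 7, w_seed = 8)
  expect_s3_class(cfg, "flot_config")
  expect_error(pipeline_config(data_seed = 1, w_seed = 2, nope = 3),
               "unknown configuration")
})
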