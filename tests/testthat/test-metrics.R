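test_that("one_over_e_depth interpolates the crossing", {
  z <- seq(0, 2000, by = 10)
  c1 <- decay_curve(z, exp(-z / 500))
  expect_equal(as.numeric(one_over_e_depth(c1)), 500, tolerance = 1e-3)

  # hand-computed bracketing case: 0.40 at 480, 0.35 at 520
  c2 <- new_curve <- decay_curve(c(0, 480, 520), c(1, 0.40, 0.35),
                                 normalize = FALSE)
  expect_equal(as.numeric(one_over_e_depth(c2)),
               480 + (0.40 - exp(-1)) / 0.05 * 40, tolerance = 1e-9)

  c3 <- decay_curve(c(0, 100, 200), c(1, 0.9, 0.8), normalize = FALSE)
  v <- one_over_e_depth(c3)
  expect_true(is.na(v))
  expect_false(attr(v, "reached"))
  expect_equal(attr(v, "deepest"), 200)

  expect_error(one_over_e_depth(decay_curve(c(0, 1), c(2, 1),
                                            normalize = FALSE)),
               "not normalized")
})

test_that("1/e depth is invariant to uniform pre-normalization scaling
           and respects pointwise dominance", {
  z <- seq(0, 1500, by = 10)
  i1 <- exp(-z / 400)
  expect_equal(as.numeric(one_over_e_depth(decay_curve(z, i1))),
               as.numeric(one_over_e_depth(decay_curve(z, 7.3 * i1))))
  dom <- pmin(1, i1 + 0.1); dom[1] <- 1
  e_dom <- one_over_e_depth(decay_curve(z, dom, normalize = FALSE))
  expect_gte(as.numeric(e_dom), as.numeric(one_over_e_depth(decay_curve(z, i1))))
})

test_that("exponential decay fits recover their parameters", {
  z <- seq(0, 1200, by = 20)
  exact <- fit_exponential(decay_curve(z, exp(-z / 1000 * 2)))
  expect_equal(exact$mu_eff, 2, tolerance = 1e-9)
  expect_equal(exact$I0, 1, tolerance = 1e-9)

  flat <- fit_exponential(decay_curve(z, rep(1, length(z)),
                                      normalize = FALSE))
  expect_equal(flat$mu_eff, 0, tolerance = 1e-12)

  set.seed(55)
  recov <- replicate(100, {
    noisy <- exp(-z / 1000 * 2) * exp(rnorm(length(z), 0, 0.05))
    fit_exponential(decay_curve(z, noisy, normalize = FALSE))$mu_eff
  })
  expect_lt(abs(median(recov) - 2) / 2, 0.10)

  td <- tidy(exact)
  expect_equal(td$estimate[td$term == "mu_eff"], 2, tolerance = 1e-9)
  expect_true(glance(exact)$r.squared > 0.999)
  expect_error(fit_exponential(decay_curve(c(0, 1, 2), c(1, 0, 0),
                                           normalize = FALSE)),
               ">= 3 positive")
})

test_that("fwhm matches closed forms and is offset/scale invariant", {
  x <- seq(-300, 300, by = 2)
  gauss <- exp(-x^2 / (2 * 50^2))
  expect_equal(fwhm(x + 300, gauss), 2 * sqrt(2 * log(2)) * 50,
               tolerance = 0.01)
  expect_equal(fwhm(x + 300, 40 + 7 * gauss),
               fwhm(x + 300, gauss), tolerance = 1e-6)

  # top-hat convolved with a 30-um-FWHM Gaussian, numeric oracle
  xs <- seq(-400, 400, by = 1)
  th <- as.numeric(abs(xs) <= 50)
  sig <- 30 / (2 * sqrt(2 * log(2)))
  kern <- dnorm(seq(-150, 150, by = 1), 0, sig)
  conv <- stats::filter(c(rep(0, 150), th, rep(0, 150)),
                        kern / sum(kern), sides = 2)
  conv <- conv[151:(150 + length(xs))]
  keep <- !is.na(conv)
  w <- fwhm(xs[keep], conv[keep])
  # oracle: width where the convolved profile crosses half max
  half <- max(conv, na.rm = TRUE) / 2
  above <- range(which(conv[keep] >= half))
  w_oracle <- xs[keep][above[2]] - xs[keep][above[1]]
  expect_lt(abs(w - w_oracle), 2)

  expect_error(fwhm(1:10, 1:10), "truncated")
})

test_that("the detection limit is N + 3 sigma", {
  arr <- array(100, c(4, 5, 6))
  lod0 <- limit_of_detection(arr)
  expect_equal(lod0$threshold, 100)

  acq <- acquisition_spec(n_positions = 20, stage_step = 0.01,
                          n_offset = 30, n_along = 30,
                          noise = list(photon_scale = Inf,
                                       read_sigma = 5, background = 100))
  blank <- structure(list(frames = array(0, c(20, 30, 30)), acq = acq,
                          source_col = 1L, noiseless = TRUE,
                          meta = list()), class = "flot_stack")
  blank <- add_noise(blank, acq, seed = 77)
  lod <- limit_of_detection(blank)
  expect_lt(abs(lod$N - 100), 1)
  expect_lt(abs(lod$threshold - 115), 2)

  curve <- decay_curve(c(0, 100, 200, 300), c(50, 30, 10, 2),
                       normalize = FALSE)
  expect_equal(max_detectable_depth(curve, 9), 200)
  expect_true(is.na(max_detectable_depth(curve, 60)))
})

test_that("depth profiles reproduce constructed fields", {
  # synthetic reconstruction whose x-z image is exp(-z / tau) along an
  # inclined rod
  g <- voxel_grid(50, 5, 40, 0.02)
  xz <- matrix(0, 50, 40)
  tau_um <- 300
  geom <- list(entry_x = 0.1, tilt_deg = 23.5, inner_diameter_mm = 0.06,
               yield = 1)
  track <- capillary_track(geom, grid = g, domain = "recon")
  for (k in seq_len(nrow(track))) {
    iz <- round(track$depth_um[k] / 20 + 0.5)
    if (iz >= 1 && iz <= 40)
      xz[track$index[k], iz] <- exp(-track$depth_um[k] / tau_um)
  }
  rec <- structure(list(xz = xz, volume = array(xz, c(50, 1, 40)),
                        grid = g), class = "flot_recon")
  cv <- depth_profile(rec, track, smooth_x = 1)
  fit <- fit_exponential(cv)
  expect_equal(fit$mu_eff, 1000 / tau_um, tolerance = 0.05)

  # constant rod: flat curve at 1
  recf <- rec
  recf$xz[recf$xz > 0] <- 3
  cvf <- depth_profile(recf, track, smooth_x = 1)
  expect_true(all(abs(cvf$intensity - 1) < 1e-9))

  bad <- track; bad$index <- bad$index + 100
  expect_error(depth_profile(rec, bad), "exits")
})

test_that("FLOT-vs-MIP comparison reports the expected analytic
           quantities", {
  z <- seq(0, 2000, by = 10)
  a <- decay_curve(z, exp(-z / 500))
  b <- decay_curve(z, exp(-z / 1000))
  cmp <- compare_flot_mip(b, a)
  expect_equal(cmp$replicates$ratio, 2, tolerance = 1e-3)
  expect_true(cmp$replicates$dominates_beyond_300)

  same <- compare_flot_mip(a, a)
  expect_equal(same$replicates$ratio, 1, tolerance = 1e-12)
  expect_true(same$replicates$dominates_beyond_300)

  far <- decay_curve(z + 5000, exp(-z / 500), normalize = FALSE)
  expect_error(compare_flot_mip(a, far), "disjoint")

  reps <- compare_flot_mip(list(a, a, a), list(b, b, b))
  expect_equal(nrow(reps$replicates), 3)
  expect_equal(reps$summary$sd[1], 0)
})

test_that("curve constructors enforce their invariants", {
  expect_error(decay_curve(c(0, 0, 10), c(1, 1, 1)), "increasing")
  expect_error(decay_curve(c(0, 10), c(-1, 1)), ">= 0")
  expect_error(decay_curve(c(0, 10), c(0, 1)), "nonpositive")
})
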