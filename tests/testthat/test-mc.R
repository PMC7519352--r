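test_that("absorbing-only transport reproduces Beer-Lambert decay", {
  g <- voxel_grid(5, 5, 30, 0.05)
  m <- make_homogeneous_medium(g, mua = 1, mus = 0, g = 0, n = 1,
                               allow_zero_scatter = TRUE)
  src <- source_spec("pencil", position = c(0.125, 0.125),
                     incidence_deg = 90)
  f <- simulate_fluence(m, src, n_photons = 1e5, seed = 42)
  zc <- voxel_centers(g, "z")
  onax <- f$values[3, 3, ]
  i0 <- which.min(abs(zc - 0.025))
  i1 <- which.min(abs(zc - 1.025))
  expect_lt(abs(onax[i1] / onax[i0] - exp(-1)), 0.02 * exp(-1))
  expect_lt(abs(f$audit - 1), 1e-3)
})

test_that("energy is conserved in a scattering medium", {
  m <- small_phantom_medium()
  src <- source_spec("pencil", position = c(1, 0.5), incidence_deg = 135)
  f <- simulate_fluence(m, src, n_photons = 5e4, seed = 3)
  expect_lt(abs(f$audit - 1), 1e-3)
  expect_true(all(f$values >= 0))
  expect_true(all(is.finite(f$values)))
})

test_that("source-swap reciprocity holds for normal incidence", {
  m <- small_phantom_medium(nx = 30, ny = 30, nz = 20, h = 0.05)
  pa <- c(0.625, 0.725); pb <- c(0.925, 0.725)
  fa <- simulate_fluence(m, source_spec("pencil", pa, 90), 4e5, seed = 5)
  fb <- simulate_fluence(m, source_spec("pencil", pb, 90), 4e5, seed = 6)
  # fluence of A's source near B vs B's source near A, small neighborhood
  nb <- function(f, p, iz) {
    ix <- round(p[1] / 0.05 + 0.5); iy <- round(p[2] / 0.05 + 0.5)
    mean(f$values[(ix - 1):(ix + 1), (iy - 1):(iy + 1), iz])
  }
  va <- nb(fa, pb, 4); vb <- nb(fb, pa, 4)
  expect_lt(abs(va - vb) / ((va + vb) / 2), 0.15)
})

test_that("adjoint Green field with normal acceptance matches the pencil
           fluence from the detector position", {
  m <- small_phantom_medium(nx = 24, ny = 24, nz = 16, h = 0.05)
  p <- c(0.625, 0.625)
  gr <- emission_green(m, list(position = p), 3e5, seed = 9,
                       acceptance = "normal")
  fl <- simulate_fluence(m, source_spec("pencil", p, 90), 3e5, seed = 10)
  sel <- fl$values > 0.05 * max(fl$values)
  rel <- abs(gr$values[sel] - fl$values[sel]) / fl$values[sel]
  expect_lt(median(rel), 0.10)
})

test_that("two detectors mirror-symmetric about a source give mirror
           Green fields", {
  m <- small_phantom_medium(nx = 31, ny = 15, nz = 12, h = 0.05)
  g1 <- emission_green(m, list(position = c(0.475, 0.375)), 3e5, seed = 21)
  g2 <- emission_green(m, list(position = c(1.075, 0.375)), 3e5, seed = 22)
  # mirror g2 in x about the midpoint x = 0.775 (voxel index 16)
  mirrored <- g2$values[31:1, , ]
  sel <- g1$values > 0.02 * max(g1$values)
  rel <- abs(g1$values[sel] - mirrored[sel]) /
    pmax(g1$values[sel], 1e-12)
  expect_lt(median(rel), 0.20)
})

test_that("absorbing-only Green field decays as Beer-Lambert along the
           normal", {
  g <- voxel_grid(5, 5, 30, 0.05)
  m <- make_homogeneous_medium(g, 1, 0, 0, 1, allow_zero_scatter = TRUE)
  gr <- emission_green(m, list(position = c(0.125, 0.125)), 1e5,
                       seed = 2, acceptance = "normal")
  zc <- voxel_centers(g, "z")
  onax <- gr$values[3, 3, ]
  i0 <- which.min(abs(zc - 0.025)); i1 <- which.min(abs(zc - 1.025))
  expect_lt(abs(onax[i1] / onax[i0] - exp(-1)), 0.03 * exp(-1))
})

test_that("line-source fluence is y-invariant away from the edges", {
  g <- voxel_grid(30, 40, 16, 0.05)
  m <- make_homogeneous_medium(g, 0.01, 15, 0.9, 1.33)
  src <- source_spec("line", position = c(0.5, 0), incidence_deg = 135)
  f <- line_source_fluence(m, src, n_photons = 1.2e6, seed = 8)
  mid <- f$values[, 20, ]; quarter <- f$values[, 10, ]
  sel <- mid > 0.05 * max(mid)
  rel_rms <- sqrt(mean((mid[sel] - quarter[sel])^2)) /
    sqrt(mean(mid[sel]^2))
  expect_lt(rel_rms, 0.05)
})

test_that("oblique 135-degree incidence displaces fluence toward +x", {
  m <- small_phantom_medium(nx = 40, ny = 10, nz = 20, h = 0.05)
  src <- source_spec("pencil", position = c(0.5, 0.25),
                     incidence_deg = 135)
  f <- simulate_fluence(m, src, n_photons = 1e5, seed = 12)
  xc <- voxel_centers(m$grid, "x")
  for (iz in c(4, 8, 12)) {
    sl <- apply(f$values[, , iz], 1, sum)
    centroid <- sum(xc * sl) / sum(sl)
    expect_gt(centroid, 0.5)
  }
})

test_that("MC error shrinks like one over root photon count", {
  m <- small_phantom_medium(nx = 20, ny = 20, nz = 12, h = 0.05)
  src <- source_spec("pencil", position = c(0.5, 0.5), incidence_deg = 90)
  probe <- function(n, seeds) vapply(seeds, function(s)
    simulate_fluence(m, src, n, seed = s)$values[10, 10, 6], numeric(1))
  s1 <- sd(probe(4e3, 1:8))
  s2 <- sd(probe(1.6e4, 11:18))
  expect_gt(s1 / s2, 1.0)   # centered on 2 for a 4x budget
  expect_lt(s1 / s2, 4.0)
})

test_that("transport is bit-reproducible for a fixed seed", {
  m <- small_phantom_medium(nx = 16, ny = 16, nz = 10, h = 0.05)
  src <- source_spec("pencil", position = c(0.4, 0.4), incidence_deg = 135)
  f1 <- simulate_fluence(m, src, 2e4, seed = 123)
  f2 <- simulate_fluence(m, src, 2e4, seed = 123)
  expect_identical(f1$values, f2$values)
  f3 <- simulate_fluence(m, src, 2e4, seed = 124)
  expect_false(identical(f1$values, f3$values))
})

test_that("degenerate media are rejected", {
  g <- voxel_grid(4, 4, 4, 0.1)
  m <- make_homogeneous_medium(g, 0, 0.001, 0, 1, allow_zero_scatter = TRUE)
  m$mua <- 0; m$mus <- 0
  src <- source_spec("pencil", position = c(0.2, 0.2), incidence_deg = 90)
  expect_error(simulate_fluence(m, src, 10, 1), "zero mu_t")
  m2 <- make_homogeneous_medium(g, 0.01, 15, 0.9, 1.33)
  m2$mua <- NaN
  expect_error(simulate_fluence(m2, src, 10, 1), "NaN")
  expect_error(simulate_fluence(m2, src, 0, 1), "n_photons")
})
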