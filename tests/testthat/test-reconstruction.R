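test_that("tikhonov_solve matches direct solutions", {
  # identity system, no damping
  b <- c(3, -1, 2)
  x <- tikhonov_solve(diag(3), b, lam = 0)
  expect_equal(as.numeric(x), b, tolerance = 1e-10)

  # random overdetermined system vs the normal-equations oracle
  set.seed(7)
  for (rep in 1:3) {
    A <- matrix(rnorm(120), 12, 10)
    b <- rnorm(12)
    lam <- 0.1
    xo <- solve(crossprod(A) + lam^2 * diag(10), crossprod(A, b))
    xs <- tikhonov_solve(A, b, lam)
    expect_lt(sqrt(sum((as.numeric(xs) - xo)^2)) / sqrt(sum(xo^2)), 1e-8)
  }
})

test_that("solution norm is nonincreasing along the lambda path", {
  set.seed(8)
  A <- matrix(rnorm(200), 20, 10)
  b <- rnorm(20)
  lams <- 10^seq(3, -3, length.out = 13)
  norms <- vapply(lams, function(l)
    attr(tikhonov_solve(A, b, l), "solution_norm"), numeric(1))
  expect_true(all(diff(norms) >= -1e-10))  # decreasing lambda grows x
})

test_that("rank-deficient unregularized solves return the minimum-norm
           solution with a flag", {
  A <- cbind(c(1, 0), c(1, 0))  # rank 1
  b <- c(2, 0)
  x <- tikhonov_solve(A, b, 0)
  expect_equal(as.numeric(x), c(1, 1), tolerance = 1e-8)  # min-norm
  expect_true(attr(x, "min_norm_warning"))
  expect_error(tikhonov_solve(A, c(1, 2, 3), 0.1), "does not match")
  expect_error(tikhonov_solve(A, b, -1), "lam")
})

test_that("L-curve selection handles degenerate sweeps", {
  A <- diag(4)
  b <- c(1, 2, 3, 4)
  one <- l_curve_select(A, b, lambda_grid = 0.5)
  expect_equal(one$lambda, 0.5)
  expect_false(one$curvature_defined)
  expect_error(l_curve_select(A, b, lambda_grid = c(-1, 1)), "lambda_grid")
})

test_that("the L-curve corner is near-optimal on an ill-posed toy", {
  toy <- phillips_toy()
  grid <- 10^seq(-6, 1, length.out = 25)
  sel <- l_curve_select(toy$A, toy$b, grid)
  errs <- vapply(grid, function(l)
    sqrt(sum((as.numeric(tikhonov_solve(toy$A, toy$b, l)) -
                toy$x_true)^2)), numeric(1))
  err_star <- errs[sel$index]
  expect_lte(err_star, 2 * min(errs))
})

test_that("a noiseless consistent system sends lambda to the small end", {
  toy <- phillips_toy(noise = 0)
  grid <- 10^seq(-6, 1, length.out = 25)
  sel <- l_curve_select(toy$A, toy$b, grid)
  expect_lte(sel$index, 6)
})

test_that("reconstruction is linear in the measurements before
           clipping", {
  r <- small_phantom_run(301)
  st2 <- r$stack
  bg <- r$rec$background
  st2$frames <- (st2$frames - bg) * 2 + bg  # alpha = 2 on the signal
  rec1 <- reconstruct_volume(r$stack, r$W, lambda = 1, y_sel = 13,
                             nonneg = FALSE, background = bg, maxit = 80)
  rec2 <- reconstruct_volume(st2, r$W, lambda = 1, y_sel = 13,
                             nonneg = FALSE, background = bg, maxit = 80)
  expect_equal(rec2$xz, 2 * rec1$xz, tolerance = 1e-6)

  rec05 <- reconstruct_volume(
    {
      s <- r$stack; s$frames <- (s$frames - bg) * 0.5 + bg; s
    }, r$W, lambda = 1, y_sel = 13, nonneg = FALSE, background = bg,
    maxit = 80)
  expect_equal(rec05$xz, 0.5 * rec1$xz, tolerance = 1e-6)
})

test_that("a background-only stack reconstructs to less than a capillary
           stack", {
  r <- small_phantom_run(301)
  blank <- r$stack
  set.seed(1)
  blank$frames[] <- 100 + rnorm(length(blank$frames), 0, 5)
  blank$frames[, 1, ] <- 4095
  rb <- reconstruct_volume(blank, r$W, lambda = r$rec$lambda,
                           background = 100, y_sel = 13, maxit = 80)
  expect_lt(sqrt(sum(rb$xz^2)), sqrt(sum(r$rec$xz^2)))
})

test_that("mismatched stack and W index maps are rejected by axis", {
  r <- small_phantom_run(301)
  short <- r$stack
  short$frames <- short$frames[1:100, , , drop = FALSE]
  expect_error(reconstruct_volume(short, r$W), "stage axis")
  W2 <- r$W
  W2$offset_bins <- c(1L, W2$offset_bins)
  expect_error(reconstruct_volume(r$stack, W2), "leakage")
})

test_that("a single fluorophore voxel is localized within one voxel", {
  ph <- test_recipe()
  src <- source_spec("line", incidence_deg = 135)
  dk <- mc_kernels(ph$medium, src, x_half_mm = 2.0, y_half_mm = 0.5,
                   n_photons = 2e5, seed = 61, what = c("phi", "g3"))
  fl <- fluorophore_map(ph$medium$grid)
  fl$yield[25, 13, 5] <- 5  # x = 0.98 mm, depth 180 um
  st <- simulate_scan(ph$medium, fl, ph$acq, seed = 61, kernels = dk)
  wk <- mc_kernels(ph$medium, src, x_half_mm = 2.0, n_photons = 2e5,
                   seed = 62, what = c("phi", "g2"))
  W <- build_weight_matrix_conv(wk, ph$medium$grid, ph$acq)
  rec <- reconstruct_volume(st, W, y_sel = 13, maxit = 120)
  pk <- which(rec$xz == max(rec$xz), arr.ind = TRUE)[1, ]
  expect_lte(abs(pk[1] - 25), 1)
  expect_lte(abs(pk[2] - 5), 1)
})
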