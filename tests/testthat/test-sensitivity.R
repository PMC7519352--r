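test_that("generic Born assembly reproduces the brute-force triple sum", {
  set.seed(41)
  g <- voxel_grid(4, 4, 4, 0.1)
  phis <- lapply(1:3, function(i) array(runif(64), c(4, 4, 4)))
  greens <- lapply(1:2, function(i) array(runif(64), c(4, 4, 4)))
  yield <- array(rexp(64), c(4, 4, 4))

  W <- build_weight_matrix(phis, greens, g)
  expect_equal(dim(W$W), c(6L, 64L))
  pred <- as.numeric(W$W %*% as.numeric(yield))
  k <- 0
  for (s in 1:3) for (d in 1:2) {
    k <- k + 1
    expect_equal(pred[k],
                 born_triple_sum(phis[[s]], greens[[d]], yield, 0.1),
                 tolerance = 1e-12)
  }
})

test_that("a single-voxel grid gives the single Born product", {
  g <- voxel_grid(1, 1, 1, 0.2)
  W <- build_weight_matrix(list(array(3, c(1, 1, 1))),
                           list(array(5, c(1, 1, 1))), g)
  expect_equal(as.numeric(W$W), 3 * 5 * 0.2^3)
})

test_that("convolutional rows are exact x-translates across stage
           positions", {
  pk <- phantom_kernels(photons = 2e5)
  acq <- acquisition_spec(n_positions = 12, stage_step = 0.04,
                          detector_pitch_mm = 0.04, n_offset = 11,
                          n_along = 1, stage_x0 = 0.02)
  W <- build_weight_matrix_conv(pk$kernels, pk$medium$grid, acq,
                                stage_sel = c(3, 6), offset_bins = 2:5,
                                floor_rel = 0)
  nd <- 4; nx <- pk$medium$grid$nx; nz <- pk$medium$grid$nz
  shift <- W$stage_ix[2] - W$stage_ix[1]
  for (d in seq_len(nd)) {
    r1 <- matrix(W$W[d, ], nx, nz)
    r2 <- matrix(W$W[nd + d, ], nx, nz)
    lo <- (1 + shift):nx
    expect_equal(r2[lo, ], r1[lo - shift, ], tolerance = 1e-12)
  }
})

test_that("mean sensitivity depth grows with source-detector offset", {
  pk <- phantom_kernels()
  acq <- acquisition_spec(n_positions = 30, stage_step = 0.08,
                          detector_pitch_mm = 0.04, n_offset = 41,
                          n_along = 1, stage_x0 = 1.0)
  W <- build_weight_matrix_conv(pk$kernels, pk$medium$grid, acq,
                                stage_sel = 10:20,
                                offset_bins = seq(2, 38, by = 4))
  md <- sensitivity_mean_depth(W)
  expect_true(all(diff(md$mean_depth_mm) > 0))
})

test_that("the sparsity floor drops small entries", {
  pk <- phantom_kernels(photons = 2e5)
  acq <- acquisition_spec(n_positions = 8, stage_step = 0.04,
                          detector_pitch_mm = 0.04, n_offset = 11,
                          n_along = 1, stage_x0 = 0.02)
  W0 <- build_weight_matrix_conv(pk$kernels, pk$medium$grid, acq,
                                 stage_sel = 1:4, offset_bins = 2:6,
                                 floor_rel = 0)
  W1 <- build_weight_matrix_conv(pk$kernels, pk$medium$grid, acq,
                                 stage_sel = 1:4, offset_bins = 2:6,
                                 floor_rel = 1e-2)
  expect_lt(length(W1$W@x), length(W0$W@x))
  expect_gt(min(W1$W@x), 1e-2 * max(W1$W@x) * 0.999)
})

test_that("depth compensation weights match an SVD oracle on a toy
           matrix", {
  # 2 layers x 2 voxels each, known entries
  A <- rbind(c(4, 2, 0.4, 0.1),
             c(1, 3, 0.2, 0.3),
             c(2, 2, 0.1, 0.2))
  W <- structure(list(W = Matrix::Matrix(A, sparse = TRUE),
                      mode = "xz_conv", col_layer = c(1, 1, 2, 2),
                      h = 0.1, nx = 2, nz = 2), class = "flot_w")
  M1 <- max(svd(A[, 1:2])$d)
  M2 <- max(svd(A[, 3:4])$d)
  Wc <- depth_compensate(W, gamma = 1)
  expect_equal(Wc$depth_weights$M, c(M1, M2), tolerance = 1e-6)
  # reversed assignment: surface layer scaled by M2, deep by M1
  wts <- c(M2, M1) / max(M1, M2)
  hand <- A %*% diag(c(wts[1], wts[1], wts[2], wts[2]))
  expect_equal(as.matrix(Wc$W), hand, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("gamma = 0 leaves W unchanged and gamma raises the deep-to-
           shallow column-norm ratio monotonically", {
  A <- rbind(c(4, 2, 0.4, 0.1),
             c(1, 3, 0.2, 0.3),
             c(2, 2, 0.1, 0.2))
  W <- structure(list(W = Matrix::Matrix(A, sparse = TRUE),
                      mode = "xz_conv", col_layer = c(1, 1, 2, 2),
                      h = 0.1, nx = 2, nz = 2), class = "flot_w")
  expect_identical(depth_compensate(W, 0)$W, W$W)
  ratio <- function(Wc) {
    cn <- sqrt(Matrix::colSums(Wc$W^2))
    mean(cn[3:4]) / mean(cn[1:2])
  }
  r0 <- ratio(W)
  r1 <- ratio(depth_compensate(W, 1))
  r2 <- ratio(depth_compensate(W, 2))
  expect_gt(r1, r0)
  expect_gt(r2, r1)
  expect_error(depth_compensate(W, 5), "gamma")

  # an all-zero depth layer has no defined weight
  A2 <- A; A2[, 3:4] <- 0
  W2 <- W; W2$W <- Matrix::Matrix(A2, sparse = TRUE)
  expect_error(depth_compensate(W2, 1), "layer 2")
})
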