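# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

# Semi-infinite CW diffusion solution for a pencil beam approximated as
# an isotropic point source at one transport length, with extrapolated
# boundary from the Fresnel moments (Haskell/Contini internal-reflection
# coefficient, computed by numeric quadrature).
diffusion_oracle <- function(mua, musp, n_rel) {
  D <- 1 / (3 * (mua + musp))
  z0 <- 1 / (mua + musp)
  mueff <- sqrt(mua / D)
  fres <- function(th) {
    ci <- cos(th)
    st2 <- n_rel^2 * sin(th)^2
    ifelse(st2 >= 1, 1, {
      ct <- sqrt(pmax(0, 1 - st2))
      rs <- (n_rel * ci - ct) / (n_rel * ci + ct)
      rp <- (n_rel * ct - ci) / (n_rel * ct + ci)
      0.5 * (rs^2 + rp^2)
    })
  }
  rphi <- integrate(function(th) 2 * sin(th) * cos(th) * fres(th),
                    0, pi / 2)$value
  rj <- integrate(function(th) 3 * sin(th) * cos(th)^2 * fres(th),
                  0, pi / 2)$value
  A <- (1 + rj) / (1 - rphi)
  zb <- 2 * A * D
  function(r, z) {
    r1 <- sqrt(r^2 + (z - z0)^2)
    r2 <- sqrt(r^2 + (z + z0 + 2 * zb)^2)
    (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
  }
}

# Brute-force discretized Born sum: frame value for one (source,
# detector) pair by an explicit triple loop over voxels.
born_triple_sum <- function(phi, green, yield, voxel_size) {
  stopifnot(all(dim(phi) == dim(yield)), all(dim(green) == dim(yield)))
  total <- 0
  d <- dim(yield)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    total <- total + green[i, j, k] * yield[i, j, k] * phi[i, j, k]
  total * voxel_size^3
}

# element-wise max projection by explicit loops
mip_loop_oracle <- function(v, along) {
  d <- dim(v)
  if (along == 2) {  # project along the y axis of an (x, y, z) array
    out <- matrix(-Inf, d[1], d[3])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      out[i, k] <- max(out[i, k], v[i, j, k])
  } else {
    out <- matrix(-Inf, d[2], d[3])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      out[j, k] <- max(out[j, k], v[i, j, k])
  }
  out
}

# The Phillips test problem: convolution with a cosine-bump kernel on
# [-6, 6], the standard smooth ill-posed benchmark, with additive
# Gaussian noise.
phillips_toy <- function(n = 32, noise = 0.01, seed = 99) {
  h <- 12 / n
  t <- -6 + (seq_len(n) - 0.5) * h
  K <- outer(t, t, function(s, x)
    ifelse(abs(s - x) < 3, 1 + cos(pi * (s - x) / 3), 0)) * h
  x_true <- ifelse(abs(t) < 3, 1 + cos(pi * t / 3), 0)
  b0 <- K %*% x_true
  set.seed(seed)
  list(A = K, b = as.numeric(b0 + rnorm(n, 0, noise * max(abs(b0)))),
       x_true = x_true)
}

# a small homogeneous medium used in several MC tests
small_phantom_medium <- function(nx = 40, ny = 20, nz = 24, h = 0.05) {
  make_homogeneous_medium(voxel_grid(nx, ny, nz, h),
                          mua = 0.01, mus = 15, g = 0.9, n = 1.33)
}
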