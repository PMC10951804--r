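# Shared fixtures, built once per test run and memoised. Default geometry
# mirrors the package defaults: N = 32, 2 A voxels, L = 8, P = 2, radial
# band to half Nyquist.

.fix <- new.env()

memo <- function(key, fn) {
  if (is.null(.fix[[key]])) .fix[[key]] <- fn()
  .fix[[key]]
}

test_grid <- function() memo("grid", function() default_polar_grid(32L, 2, L = 8L))
test_cfg <- function() memo("cfg", function() metric_config(test_grid(), L = 8L, P = 2L))

test_phantom <- function() memo("phantom", function()
  make_phantom(phantom_spec("blobs", n = 32L, voxel_size = 2, seed = 21L)))

test_phantom2 <- function() memo("phantom2", function()
  make_phantom(phantom_spec("blobs", n = 32L, voxel_size = 2, seed = 22L)))

test_expansion <- function() memo("expansion", function()
  expand_volume(test_phantom(), 8L, test_grid()$k))

test_expansion2 <- function() memo("expansion2", function()
  expand_volume(test_phantom2(), 8L, test_grid()$k))

test_slice_expansion <- function() memo("slice_expansion", function()
  expand_for_slices(test_phantom(), 8L))

test_uniform_moments <- function() memo("uniform_moments", function()
  analytic_moments_uniform(test_expansion(), test_grid()))

test_design <- function() memo("design", function()
  moment_design(test_expansion(), test_grid(), 2L))

# Random unit vectors
runit <- function(n) {
  u <- matrix(stats::rnorm(3L * n), n, 3L)
  u / sqrt(rowSums(u^2))
}

# Test-side Monte-Carlo moment oracle: plain averaging of central-slice
# values and their in-plane product averages over explicit rotations,
# written as a direct loop independent of the package's quadrature path.
mc_moments_oracle <- function(e, grid, rotations, with_se = FALSE) {
  n <- dim(rotations)[3L]
  cp <- cbind(cos(grid$phi), sin(grid$phi), 0)
  np <- grid$n_phi; nk <- grid$n_k
  s1 <- 0; s2 <- 0; s1sq <- 0; s2sq <- 0
  for (i in seq_len(n)) {
    S <- eval_expansion(e, cp %*% t(rotations[, , i]))   # u_t = R c_t (rows)
    m1 <- colMeans(S)
    Fh <- stats::mvfft(S)
    m2 <- array(0i, c(np, nk, nk))
    for (j2 in seq_len(nk))
      m2[, , j2] <- stats::mvfft(Fh * Conj(Fh[, j2]), inverse = TRUE) / np^2
    s1 <- s1 + m1; s2 <- s2 + m2
    if (with_se) { s1sq <- s1sq + abs(m1)^2; s2sq <- s2sq + abs(m2)^2 }
  }
  out <- list(m1 = s1 / n, m2 = s2 / n)
  if (with_se) {
    out$se1 <- sqrt(pmax(0, s1sq / n - abs(out$m1)^2) / n)
    out$se2 <- sqrt(pmax(0, s2sq / n - abs(out$m2)^2) / n)
  }
  out
}

# Trilinear rotation of a volume about the grid centre (test oracle for
# rotate_expansion; edges fill with zero).
rotate_volume_trilinear <- function(v, R) {
  n <- v$n
  ax <- (seq_len(n) - 1 - n %/% 2)
  X <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  Xs <- X %*% R                       # source coords: v'(x) = v(R^{-1} x)
  lo <- floor(Xs); fr <- Xs - lo
  out <- numeric(nrow(X))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- lo[, 1L] + dx + n %/% 2 + 1L
    iy <- lo[, 2L] + dy + n %/% 2 + 1L
    iz <- lo[, 3L] + dz + n %/% 2 + 1L
    ok <- ix >= 1L & ix <= n & iy >= 1L & iy <= n & iz >= 1L & iz <= n
    w <- (if (dx) fr[, 1L] else 1 - fr[, 1L]) *
         (if (dy) fr[, 2L] else 1 - fr[, 2L]) *
         (if (dz) fr[, 3L] else 1 - fr[, 3L])
    idx <- cbind(ix[ok], iy[ok], iz[ok])
    out[ok] <- out[ok] + w[ok] * v$values[idx]
  }
  volume_grid(array(out, c(n, n, n)), v$voxel_size)
}
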