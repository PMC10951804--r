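test_that("MRC round trip preserves data and header geometry", {
  set.seed(5)
  v <- volume_grid(array(rnorm(16^3), c(16, 16, 16)), 1.5)
  p <- tempfile(fileext = ".mrc")
  save_volume(v, p)
  v2 <- load_volume(p)
  expect_equal(v2$voxel_size, 1.5, tolerance = 1e-6)
  expect_equal(v2$side_length, 16 * 1.5, tolerance = 1e-6)
  expect_lt(max(abs(v2$values - v$values)), 1e-6 * max(abs(v$values)))
  # float32 storage is idempotent: a second round trip is bit-identical
  p2 <- tempfile(fileext = ".mrc")
  save_volume(v2, p2)
  expect_identical(load_volume(p2)$values, v2$values)
})

test_that("malformed and non-cubic MRC inputs are rejected", {
  p <- tempfile(fileext = ".mrc")
  writeBin(raw(100L), p)                         # truncated header
  expect_error(load_volume(p), "truncated|malformed")
  write_mrc(array(0, c(8, 8, 4)), p, 1.0)        # non-cubic
  expect_error(load_volume(p), "non-cubic")
  expect_error(load_volume(tempfile()), "not found")
})

test_that("atomic models voxelise to centred Gaussian densities", {
  m <- atomic_model("C", c(0, 0, 0))
  v <- atomic_model_to_volume(m, 32L, 1)
  expect_equal(which(v$values == max(v$values)),
               ((16 * 32) + 16) * 32 + 17)       # centre voxel (17,17,17)
  # two atoms related by point reflection -> field symmetric under it
  m2 <- atomic_model(c("C", "C"), rbind(c(3.2, -1.5, 2.1), c(-3.2, 1.5, -2.1)))
  v2 <- atomic_model_to_volume(m2, 32L, 1)$values
  # point reflection through the centre of a grid centred at voxel N/2+1
  # maps index i to N+2-i; compare on the common interior
  expect_lt(max(abs(v2[2:32, 2:32, 2:32] - v2[32:2, 32:2, 32:2])), 1e-12)
  # total integral matches the closed-form sum of Gaussian masses
  ff <- kammetrics:::default_form_factors()
  w <- ff$weight[ff$element == "C"]; s <- ff$sigma[ff$element == "C"]
  expect_equal(sum(v2) * 1^3, 2 * w * (2 * pi * s^2)^1.5, tolerance = 1e-6)
  # atom outside the grid after centering
  m3 <- atomic_model(c("C", "C"), rbind(c(0, 0, 0), c(40, 0, 0)))
  expect_error(atomic_model_to_volume(m3, 32L, 1), "outside grid")
})

test_that("expansion of a centred Gaussian blob is pure l = 0 and matches the closed form", {
  v0 <- make_phantom(phantom_spec("blobs", n = 32L, voxel_size = 2, seed = 1L,
                                  n_blobs = 1L, max_offset = 0))
  g <- test_grid()
  e0 <- expand_volume(v0, 8L, g$k)
  se <- shell_energy(e0)
  expect_lt(sum(se[-1L, ]) / sum(se[1L, ]), 1e-10)
  p <- attr(v0, "params")
  a00 <- sqrt(4 * pi) * p$amp[1L] * (2 * pi * p$sigma[1L]^2)^1.5 *
    exp(-2 * pi^2 * p$sigma[1L]^2 * g$k^2)
  expect_lt(max(abs(e0$coeffs[[1L]][1L, ] - a00)) / max(abs(a00)), 1e-6)
})

test_that("expansion evaluates the analytic Fourier transform of blob phantoms", {
  set.seed(6)
  v <- test_phantom()
  g <- test_grid()
  e <- test_expansion()
  u <- runit(20L)
  Fhat <- eval_expansion(e, u)
  Ftrue <- sapply(seq_along(g$k), function(j) phantom_fourier(v, g$k[j] * u))
  expect_lt(max(abs(Fhat - Ftrue)) / max(abs(Ftrue)), 5e-4)   # L-truncation
  expect_lt(kammetrics:::conjugate_symmetry_error(e), 1e-10)
  # zero volume -> all-zero coefficients
  ez <- expand_volume(volume_grid(array(0, c(16, 16, 16)), 2), 4L, g$k)
  expect_true(all(abs(kammetrics:::expansion_matrix(ez)) == 0))
  # angular aliasing guard
  expect_error(expand_volume(v, 60L, g$k), "bandlimit")
})

test_that("harmonic phantoms recover their seeded coefficients (radial Hankel oracle)", {
  sp <- phantom_spec("harmonic", n = 32L, voxel_size = 2, seed = 9L, degree = 4L)
  v <- make_phantom(sp)
  p <- attr(v, "params")
  g <- test_grid()
  e <- expand_volume(v, 6L, g$k)
  # oracle: A_lm(k) (package phase convention, i^l folded in) equals
  # 4 pi c_lm sigma^{-l} * integral_0^inf r^{l+2} e^{-r^2/2s^2} j_l(2 pi k r) dr
  for (l in 0:4) for (m in c(0L, min(l, 2L))) {
    cf <- p$coeffs[lm_index(l, m)]
    if (abs(cf) < 1e-12) next
    for (j in c(2L, 5L)) {
      k <- g$k[j]
      int <- stats::integrate(function(r)
        r^(l + 2) * exp(-r^2 / (2 * p$sigma^2)) *
          kammetrics:::sph_bessel(l, 2 * pi * k * r),
        0, Inf, rel.tol = 1e-10)$value
      oracle <- 4 * pi * cf * p$sigma^(-l) * int
      got <- e$coeffs[[l + 1L]][m + l + 1L, j]
      expect_lt(abs(got - oracle), 1e-4 * max(abs(e$coeffs[[1L]])))
    }
  }
})

test_that("rotating an expansion matches rotating the underlying field", {
  set.seed(7)
  v <- test_phantom(); g <- test_grid(); e <- test_expansion()
  R <- random_rotations(1L)[, , 1L]
  # identity rotation leaves coefficients unchanged
  eid <- rotate_expansion(e, diag(3))
  expect_lt(max(abs(kammetrics:::expansion_matrix(eid) -
                    kammetrics:::expansion_matrix(e))), 1e-12)
  # group property
  R2 <- random_rotations(1L)[, , 1L]
  e12 <- rotate_expansion(rotate_expansion(e, R), R2)
  e21 <- rotate_expansion(e, R2 %*% R)
  expect_lt(max(abs(kammetrics:::expansion_matrix(e12) -
                    kammetrics:::expansion_matrix(e21))), 1e-10)
  # rotated expansion evaluates F(R^{-1} u): compare to the closed form
  er <- rotate_expansion(e, R)
  u <- runit(10L)
  Fr <- eval_expansion(er, u)
  Ftrue <- sapply(seq_along(g$k), function(j)
    phantom_fourier(v, g$k[j] * u %*% R))        # rows R^{-1} u
  expect_lt(max(abs(Fr - Ftrue)) / max(abs(Ftrue)), 5e-4)
  # per-shell energy is exactly invariant
  expect_lt(max(abs(shell_energy(er) - shell_energy(e))) / max(shell_energy(e)),
            1e-12)
  # trilinear-rotation oracle: expansion of the numerically rotated volume
  vr <- rotate_volume_trilinear(v, R)
  evr <- expand_volume(vr, 8L, g$k)
  ref <- max(abs(kammetrics:::expansion_matrix(e)))
  expect_lt(max(abs(kammetrics:::expansion_matrix(evr) -
                    kammetrics:::expansion_matrix(er))) / ref, 0.02)
})
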