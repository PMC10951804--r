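random_moment_pair <- function(g) {
  moment_pair(complex(real = rnorm(g$n_k), imaginary = rnorm(g$n_k)),
              array(complex(real = rnorm(g$n_phi * g$n_k^2),
                            imaginary = rnorm(g$n_phi * g$n_k^2)),
                    c(g$n_phi, g$n_k, g$n_k)), g)
}

test_that("d_volume is a pseudometric: identity, symmetry, triangle inequality", {
  set.seed(40)
  g <- test_grid(); cfg <- test_cfg()
  ma <- test_uniform_moments()
  expect_equal(d_volume(ma, ma, cfg), 0)
  for (i in 1:5) {
    a <- random_moment_pair(g); b <- random_moment_pair(g); c <- random_moment_pair(g)
    expect_equal(d_volume(a, b, cfg), d_volume(b, a, cfg))
    expect_gte(d_volume(a, b, cfg), 0)
    expect_lte(d_volume(a, c, cfg),
               d_volume(a, b, cfg) + d_volume(b, c, cfg) + 1e-12)
  }
  # grid mismatch is refused
  g2 <- polar_grid(4L, 36L, g$k_max)
  expect_error(d_volume(ma, random_moment_pair(g2), cfg), "grid")
})

test_that("d_volume is rotation-invariant and discriminates distinct phantoms", {
  set.seed(41)
  cfg <- test_cfg(); g <- test_grid()
  ma <- test_uniform_moments()
  mb <- analytic_moments_uniform(test_expansion2(), g)
  inter <- d_volume(ma, mb, cfg)
  expect_gt(inter, 0)
  worst <- 0
  for (i in 1:5) {
    R <- random_rotations(1L)[, , 1L]
    mr <- analytic_moments_uniform(rotate_expansion(test_expansion(), R), g)
    worst <- max(worst, d_volume(ma, mr, cfg))
  }
  expect_lt(worst, 1e-8 * inter)
  # volume-rotation oracle: moments of a trilinearly rotated volume agree
  # with the rotate_expansion route far better than structures differ
  R <- random_rotations(1L)[, , 1L]
  vr <- rotate_volume_trilinear(test_phantom(), R)
  m_vol <- analytic_moments_uniform(expand_volume(vr, 8L, g$k), g)
  expect_lt(d_volume(m_vol, ma, cfg), 0.05 * inter)
})

test_that("metric norms are homogeneous and approximate the continuous norms", {
  cfg <- test_cfg(); g <- test_grid()
  ma <- test_uniform_moments()
  zero <- moment_pair(ma$m1 * 0, ma$m2 * 0, g)
  expect_equal(unname(metric_norms(zero, cfg)), c(0, 0))
  sc <- metric_norms(moment_pair(ma$m1 * -2.5, ma$m2 * -2.5, g), cfg)
  expect_equal(unname(sc), unname(2.5 * metric_norms(ma, cfg)), tolerance = 1e-12)
  # continuous-norm oracle on a spherically symmetric Gaussian: slices are
  # the radial profile F(k), so ||m1||^2 = int k F^2 dk and
  # ||m2||^2 = 2 pi (int k F^2 dk)^2; compare on a finer radial grid
  sig <- 6; amp <- 1.3
  Fk <- function(k) amp * (2 * pi * sig^2)^1.5 * exp(-2 * pi^2 * sig^2 * k^2)
  n <- 32L; vox <- 2
  ax <- (seq_len(n) - 1 - n %/% 2) * vox
  blob <- amp * exp(-outer(outer(ax^2, ax^2, "+"), ax^2, "+") / (2 * sig^2))
  v <- volume_grid(array(blob, c(n, n, n)), vox)
  gf <- polar_grid(16L, 36L, 0.125, radial = "gauss")
  cfgf <- metric_config(gf, L = 8L, P = 2L)
  mf <- analytic_moments_uniform(expand_volume(v, 8L, gf$k), gf)
  nn <- metric_norms(mf, cfgf)
  i1 <- stats::integrate(function(k) k * Fk(k)^2, 0, 0.125, rel.tol = 1e-12)$value
  expect_lt(abs(nn[["m1"]] - sqrt(i1)) / sqrt(i1), 0.01)
  expect_lt(abs(nn[["m2"]] - sqrt(2 * pi) * i1) / (sqrt(2 * pi) * i1), 0.01)
})

test_that("d_image solves the density-elimination least squares exactly", {
  set.seed(42)
  cfg <- test_cfg(); g <- test_grid()
  des <- test_design()
  b <- c(0.02, 0.01, -0.015, 0.012, -0.008)
  emp <- design_moments(des, b)
  fit <- d_image(emp, des, cfg)
  expect_lt(fit$distance, 1e-8)
  expect_lt(max(abs(coef(fit) - b)), 1e-8)
  expect_equal(fit$fitted_density$bandlimit, 2L)
  # uniform moments of the same structure: distance 0, uniform density back
  fit0 <- d_image(test_uniform_moments(), des, cfg)
  expect_lt(fit0$distance, 1e-8)
  expect_lt(max(abs(coef(fit0))), 1e-8)
  # minimisation never exceeds the pinned-uniform residual
  mb <- analytic_moments_uniform(test_expansion2(), g)
  fitx <- d_image(mb, des, cfg)
  expect_lte(fitx$distance, fitx$uniform_distance + 1e-9)
  expect_gt(fitx$distance, 0)
})

test_that("d_image is invariant to the reference structure's orientation", {
  set.seed(43)
  cfg <- test_cfg(); g <- test_grid()
  des <- test_design()
  b <- c(0.01, -0.02, 0.005, 0.015, 0.01)
  emp <- design_moments(des, b)
  R <- random_rotations(1L)[, , 1L]
  desr <- moment_design(rotate_expansion(test_expansion(), R), g, 2L)
  fitr <- d_image(emp, desr, cfg)
  expect_lt(fitr$distance, 1e-7 * fitr$uniform_distance)
  # and the fitted density is the rotated one, up to the design null space
  fit <- d_image(emp, des, cfg)
  br <- density_to_vector(rotate_density(vector_to_density(coef(fit), 2L), R))
  expect_lt(max(abs(br - coef(fitr))), 1e-6)
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  cfg <- test_cfg()
  des <- test_design()
  des$L1[, 5L] <- des$L1[, 4L]
  des$L2[, 5L] <- des$L2[, 4L]
  emp <- design_moments(des, c(0.01, 0, 0, 0.005, 0.005))
  expect_message(fit <- d_image(emp, des, cfg), "minimum-norm|rank")
  expect_true(is.finite(fit$distance))
  expect_lt(fit$distance, 1e-8 * fit$uniform_distance + 1e-8)
})
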