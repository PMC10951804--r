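test_that("projection reduces to an axis sum and respects the Fourier-slice theorem", {
  v <- test_phantom()
  P <- project(v, diag(3), L = 14L)
  vsum <- apply(v$values, c(1L, 2L), sum) * v$voxel_size
  expect_lt(max(abs(P - vsum)) / max(abs(vsum)), 1e-3)
  # spherically symmetric volume: projections identical for all rotations
  set.seed(30)
  v0 <- make_phantom(phantom_spec("blobs", n = 32L, voxel_size = 2, seed = 1L,
                                  n_blobs = 1L, max_offset = 0))
  e0 <- expand_for_slices(v0, 8L)
  P1 <- project(e0, random_rotations(1L)[, , 1L])
  P2 <- project(e0, random_rotations(1L)[, , 1L])
  expect_lt(max(abs(P1 - P2)) / max(abs(P1)), 1e-6)
  # 2D transform of the projection equals the direct central slice of the
  # volume's nonuniform Fourier transform at low frequencies
  R <- random_rotations(1L)[, , 1L]
  Pr <- project(expand_for_slices(v, 14L), R)
  Fc <- kammetrics:::image_to_freq_grid(Pr, v$voxel_size)
  g3 <- kammetrics:::voxel_geometry(32L)
  X <- g3$X * v$voxel_size
  for (q in list(c(2L, 3L), c(-4L, 1L), c(3L, -2L))) {
    k3 <- drop(R %*% c(q / (32 * 2), 0))
    direct <- 2^3 * sum(as.numeric(v$values) * exp(-2i * pi * drop(X %*% k3)))
    expect_lt(abs(Fc[q[1L] + 17L, q[2L] + 17L] - direct) / abs(direct), 1e-4)
  }
})

test_that("the CTF behaves multiplicatively and flips sign at its analytic first zero", {
  set.seed(31)
  img <- project(test_slice_expansion(), random_rotations(1L)[, , 1L])
  ct <- ctf_params(2e4, pixel_size = 2)
  # twice the CTF equals its pointwise square once
  twice <- apply_ctf(apply_ctf(img, ct), ct)
  n <- 32L
  qd <- ifelse(0:(n - 1L) >= n / 2, 0:(n - 1L) - n, 0:(n - 1L))
  kr <- sqrt(outer(qd^2, qd^2, "+")) / (n * 2)
  H2 <- matrix(eval_ctf(ct, as.numeric(kr))^2, n, n)
  sq <- Re(stats::fft(stats::fft(img) * H2, inverse = TRUE)) / n^2
  expect_lt(max(abs(twice - sq)) / max(abs(sq)), 1e-10)
  # closed-form first zero: chi(k) + asin(alpha) = pi with
  # chi = pi lam z k^2 - (pi/2) Cs lam^3 k^4
  lam <- 12.2643 / sqrt(3e5 * (1 + 3e5 * 0.978466e-6))
  A <- -(pi / 2) * 2e7 * lam^3; B <- pi * lam * 2e4; C <- -(pi - asin(0.07))
  roots <- sqrt(Filter(function(x) x > 0,
                       c((-B + sqrt(B^2 - 4 * A * C)) / (2 * A),
                         (-B - sqrt(B^2 - 4 * A * C)) / (2 * A))))
  k0 <- min(roots)
  expect_gt(eval_ctf(ct, k0 - 1e-4), 0)
  expect_lt(eval_ctf(ct, k0 + 1e-4), 0)
  expect_equal(eval_ctf(ct, 0), 0.07, tolerance = 1e-12)
})

test_that("noise addition follows the SNR convention and the law of large numbers", {
  # mean squared clean intensity 2.0 at snr 0.1 -> variance 20
  clean <- array(sqrt(2), c(16, 16, 40))
  st <- add_noise(image_stack(clean, 1), snr = 0.1, seed = 32L)
  expect_equal(attr(st, "noise_variance"), 20)
  # empirical variance over ~10^6 pixels within 1%
  big <- add_noise(image_stack(array(1, c(64, 64, 256)), 1), snr = 0.5,
                   seed = 33L)
  expect_lt(abs(stats::var(as.numeric(big$images - 1)) / 2 - 1), 0.01)
})

test_that("simulate_dataset is reproducible and keeps its books", {
  v <- test_phantom()
  rec <- simulation_recipe(n_images = 60L, poses = random_vmf_mixture(seed = 5L),
                           n_ctf = 7L, snr = 0.5, seed = 34L, L = 6L)
  a <- simulate_dataset(v, rec)
  b <- simulate_dataset(v, rec)
  expect_identical(a$stack$images, b$stack$images)
  expect_identical(a$rotations, b$rotations)
  expect_equal(length(a$ctf_bank), 7L)
  expect_true(all(a$stack$ctf_assignment %in% 1:7))
  expect_equal(a$noise_variance, a$clean_power / 0.5)
  # defocus values fall in the recipe's window
  z <- vapply(a$ctf_bank, function(ct) ct$defocus, numeric(1L))
  expect_true(all(z >= 1e4 & z <= 3e4))
})

test_that("the expected noisy image at fixed pose is the CTF-filtered projection", {
  set.seed(35)
  esl <- test_slice_expansion()
  R <- random_rotations(1L)[, , 1L]
  clean <- project(esl, R)
  ct <- ctf_params(1.5e4, pixel_size = 2)
  filtered <- apply_ctf(clean, ct)
  reps <- 400L
  noisy <- array(rep(filtered, reps), c(32, 32, reps))
  stn <- add_noise(image_stack(noisy, 2), snr = 0.2, seed = 36L)
  avg <- apply(stn$images, c(1L, 2L), mean)
  sd_mean <- sqrt(attr(stn, "noise_variance") / reps)
  expect_lt(max(abs(avg - filtered)), 5 * sd_mean)
})
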