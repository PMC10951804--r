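test_that("a single clean image reproduces its own polar transform", {
  set.seed(20)
  g <- test_grid()
  esl <- test_slice_expansion()
  R <- random_rotations(1L)[, , 1L]
  img <- project(esl, R)
  st <- image_stack(array(img, c(32, 32, 1)), 2)
  m <- empirical_moments(st, NULL, 0, g)
  P <- matrix(kammetrics:::polar_samples(array(img, c(32, 32, 1)), g, 2),
              g$n_phi, g$n_k)
  expect_lt(max(abs(m$m1 - colMeans(P))), 1e-9 * max(abs(P)))
  # and that transform agrees with the exact central slice (the pixel image
  # is an honest discretisation of the model's projection)
  S <- kammetrics:::slice_polar(test_expansion(), R, g)
  expect_lt(max(abs(P - S)) / max(abs(S)), 1e-3)
  expect_error(empirical_moments(image_stack(array(0, c(32, 32, 0)) , 2),
                                 NULL, 0, g), "empty|positive")
})

test_that("empirical moments are streaming-consistent and chunk-invariant", {
  g <- test_grid()
  esl <- test_slice_expansion()
  sim <- simulate_dataset(esl, simulation_recipe(n_images = 120L, n_ctf = 0L,
                                                 snr = Inf, seed = 23L, L = 8L))
  full <- empirical_moments(sim$stack, NULL, 0, g)
  rechunk <- empirical_moments(sim$stack, NULL, 0, g, chunk_size = 17L)
  expect_lt(max(abs(full$m2 - rechunk$m2)), 1e-10 * max(abs(full$m2)))
  # weighted recombination of a partition equals the full-stack result
  s1 <- image_stack(sim$stack$images[, , 1:50], 2)
  s2 <- image_stack(sim$stack$images[, , 51:120], 2)
  m1p <- empirical_moments(s1, NULL, 0, g)
  m2p <- empirical_moments(s2, NULL, 0, g)
  comb_m2 <- (50 * m1p$m2 + 70 * m2p$m2) / 120
  expect_lt(max(abs(comb_m2 - full$m2)), 1e-10 * max(abs(full$m2)))
  expect_lt(kammetrics:::hermitian_error(full), 1e-10)
})

test_that("clean uniform-pose empirical moments converge to the analytic ones", {
  g <- test_grid(); cfg <- test_cfg()
  esl <- test_slice_expansion()
  ma <- test_uniform_moments()
  nn <- metric_norms(ma, cfg)
  den <- sqrt(nn[["m1"]]^2 + nn[["m2"]]^2)
  sim <- simulate_dataset(esl, simulation_recipe(n_images = 1500L, n_ctf = 0L,
                                                 snr = Inf, seed = 24L, L = 8L))
  memp <- empirical_moments(sim$stack, NULL, 0, g)
  expect_lt(d_volume(memp, ma, cfg) / den, 0.02)
})

test_that("noise variance is estimated from corners and debiasing cancels noise", {
  set.seed(25)
  # pure sigma^2 = 1 noise
  st <- image_stack(array(rnorm(24 * 24 * 1000), c(24, 24, 1000)), 2)
  vhat <- estimate_noise_variance(st)
  expect_gt(vhat, 0.95); expect_lt(vhat, 1.05)
  expect_equal(estimate_noise_variance(image_stack(array(0, c(24, 24, 0)), 2)), 0)
  # signal confined to the central disk does not contaminate the corners
  ax <- seq_len(24) - 13
  disk <- sqrt(outer(ax^2, ax^2, "+")) <= 6
  sig <- array(rnorm(24 * 24 * 500, sd = sqrt(0.5)), c(24, 24, 500))
  for (i in 1:500) sig[, , i] <- sig[, , i] + disk * 3
  expect_lt(abs(estimate_noise_variance(image_stack(sig, 2)) - 0.5), 0.05)
  # debiased second moment of pure noise is centred on zero
  g <- test_grid()
  stn <- image_stack(array(rnorm(32 * 32 * 800), c(32, 32, 800)), 2)
  mdeb <- empirical_moments(stn, NULL, noise_variance = 1, grid = g)
  mraw <- empirical_moments(stn, NULL, noise_variance = 0, grid = g)
  # debiasing removes nearly all of the diagonal noise floor
  expect_lt(max(abs(mdeb$m2)), 0.05 * max(abs(mraw$m2)))
})

test_that("CTF-grouped estimation recovers moments across a CTF bank", {
  g <- test_grid(); cfg <- test_cfg()
  esl <- test_slice_expansion()
  ma <- test_uniform_moments()
  nn <- metric_norms(ma, cfg)
  den <- sqrt(nn[["m1"]]^2 + nn[["m2"]]^2)
  sim <- simulate_dataset(esl, simulation_recipe(n_images = 1500L, n_ctf = 8L,
                                                 snr = Inf, seed = 26L, L = 8L))
  memp <- empirical_moments(sim$stack, sim$ctf_bank, 0, g)
  expect_lt(d_volume(memp, ma, cfg) / den, 0.05)
  expect_error(empirical_moments(sim$stack, sim$ctf_bank[1:2], 0, g), "bank")
})

test_that("preprocessing: identity mask, Fourier-crop downsampling, shift centering", {
  set.seed(27)
  esl <- test_slice_expansion()
  img <- project(esl, random_rotations(1L)[, , 1L])
  st <- image_stack(array(img, c(32, 32, 1)), 2)
  # full-size, full-radius mask: only corner pixels outside the inscribed
  # circle change
  same <- preprocess_stack(st, 32L, 1)
  ax <- seq_len(32) - 1 - 16
  inside <- sqrt(outer(ax^2, ax^2, "+")) <= 16
  expect_lt(max(abs((same$images[, , 1] - img)[inside])), 1e-9 * max(abs(img)))
  expect_true(all(same$images[, , 1][!inside] == 0))
  # a sinusoid below the new Nyquist survives Fourier cropping exactly
  x <- (seq_len(32) - 1 - 16) * 2
  wave <- outer(cos(2 * pi * 3 / 64 * x), sin(2 * pi * 2 / 64 * x))
  stw <- image_stack(array(wave, c(32, 32, 1)), 2)
  dsw <- preprocess_stack(stw, 16L, 1)
  expect_equal(dsw$pixel_size, 4)
  xs <- (seq_len(16) - 1 - 8) * 4
  expect_lt(max(abs(dsw$images[, , 1] -
                    outer(cos(2 * pi * 3 / 64 * xs), sin(2 * pi * 2 / 64 * xs)) *
                      (sqrt(outer(xs^2, xs^2, "+")) / 4 <= 8))), 1e-10)
  # shifting then centering with the recorded shift restores the image
  sh <- c(6, -4)                                  # angstrom, 3 and -2 pixels
  Fc <- kammetrics:::image_to_freq_grid(img, 2)
  q <- (seq_len(32) - 1 - 16) / 64
  ramp <- exp(-2i * pi * (outer(q * sh[1L], rep(1, 32)) +
                          outer(rep(1, 32), q * sh[2L])))
  shifted <- kammetrics:::freq_grid_to_image(Fc * ramp, 2)
  stsh <- image_stack(array(shifted, c(32, 32, 1)), 2,
                      shifts = matrix(sh, 1L))
  back <- preprocess_stack(stsh, 32L, 1)
  expect_lt(max(abs((back$images[, , 1] - img)[inside])), 1e-8 * max(abs(img)))
  expect_error(preprocess_stack(st, 64L), "upsample")
})

test_that("diagonal scale fitting matches a brute-force scan and its conventions", {
  g <- test_grid()
  ma <- test_uniform_moments()
  expect_equal(fit_moment_scale(ma, ma), 1)
  expect_equal(fit_moment_scale(ma, scale_moments(ma, 4)), 0.25)
  # random perturbed pair: closed form beats/matches a fine grid scan
  set.seed(28)
  q <- moment_pair(ma$m1 * 1.3, ma$m2 * 1.7 +
                     0.01 * max(abs(ma$m2)) * array(rnorm(length(ma$m2)),
                                                    dim(ma$m2)), g)
  chat <- fit_moment_scale(ma, q)
  jj <- cbind(1L, seq_len(g$n_k), seq_len(g$n_k))
  w <- (g$k * g$w_k)^2
  loss <- function(c2) sum(w * abs(c2 * q$m2[jj] - ma$m2[jj])^2)
  cgrid <- seq(chat * 0.5, chat * 1.5, length.out = 4001L)
  expect_lt(abs(cgrid[which.min(sapply(cgrid, loss))] - chat), 1e-3 * chat)
  # degenerate query
  zero <- moment_pair(ma$m1 * 0, ma$m2 * 0, g)
  expect_error(fit_moment_scale(ma, zero), "degenerate")
})
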