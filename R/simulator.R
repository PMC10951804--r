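## Synthetic cryo-EM image formation: central-slice projection from the
## harmonic expansion, radial CTF, white noise at a target SNR.

## ---- CTF ---------------------------------------------------------------

#' Contrast transfer function parameters
#'
#' Radial (astigmatism-free) CTF
#' `H(k) = sin(chi(k) + asin(alpha))`, with phase
#' `chi(k) = pi lambda z k^2 - (pi/2) Cs lambda^3 k^4`
#' (underfocus `z > 0`), `lambda` the relativistic electron wavelength and
#' `alpha` the amplitude contrast fraction, so `H(0) = alpha`.
#'
#' @param defocus defocus in angstrom (> 0 underfocus).
#' @param cs spherical aberration in mm.
#' @param voltage acceleration voltage in kV.
#' @param amp_contrast amplitude contrast fraction in `[0, 1]`.
#' @param pixel_size pixel size in angstrom.
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(defocus, cs = 2.0, voltage = 300, amp_contrast = 0.07,
                       pixel_size = 1) {
  stopifnot(defocus > 0, cs >= 0, voltage > 0,
            amp_contrast >= 0, amp_contrast <= 1, pixel_size > 0)
  structure(list(defocus = defocus, cs = cs, voltage = voltage,
                 amp_contrast = amp_contrast, pixel_size = pixel_size),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf("<ctf_params> defocus %.0f A, Cs %.2g mm, %g kV, amp contrast %.3g\n",
              x$defocus, x$cs, x$voltage, x$amp_contrast))
  invisible(x)
}

electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2643 / sqrt(v * (1 + v * 0.978466e-6))     # angstrom
}

#' Evaluate a CTF at radial frequencies
#' @param ctf a [ctf_params()].
#' @param k radial frequencies (1/angstrom).
#' @return numeric vector `H(k)`.
#' @export
eval_ctf <- function(ctf, k) {
  lam <- electron_wavelength(ctf$voltage)
  cs_a <- ctf$cs * 1e7                          # mm -> angstrom
  chi <- pi * lam * ctf$defocus * k^2 - (pi / 2) * cs_a * lam^3 * k^4
  sin(chi + asin(ctf$amp_contrast))
}

#' Random bank of radial CTFs
#'
#' Defocus values drawn uniformly from `defocus_range` (the field-typical
#' 1-3 micrometre window by default); other parameters shared.
#'
#' @param n number of CTFs.
#' @param defocus_range in angstrom.
#' @param seed optional seed.
#' @param ... passed to [ctf_params()].
#' @return list of [ctf_params()].
#' @export
ctf_bank <- function(n, defocus_range = c(1e4, 3e4), seed = NULL, ...) {
  with_seed(seed, function() {
    z <- stats::runif(n, defocus_range[1L], defocus_range[2L])
    lapply(z, ctf_params, ...)
  })
}

## ---- Fourier grid geometry for N x N images ---------------------------

## Centred integer frequencies -N/2..N/2-1, their radius bins and unit
## directions (z = 0 plane); cached per N.
image_freq_geometry <- function(n) {
  cache_get(sprintf("freq2d:%d", n), function() {
    q <- seq_len(n) - 1L - n %/% 2L
    Q <- as.matrix(expand.grid(q1 = q, q2 = q))
    r2 <- rowSums(Q^2)
    ru2 <- sort(unique(r2))
    bin <- match(r2, ru2)
    r <- sqrt(r2)
    u <- cbind(Q[, 1L] / pmax(r, 1e-300), Q[, 2L] / pmax(r, 1e-300), 0)
    u[r == 0, ] <- c(1, 0, 0)                   # arbitrary; only l = 0 survives at k = 0
    list(Q = Q, r_int = r, r_unique_int = sqrt(ru2), bin = bin, u = u)
  })
}

image_freq_harmonics <- function(n, L) {
  cache_get(sprintf("Y2d:%d:%d", n, L), function() {
    sph_harmonics_xyz(L, image_freq_geometry(n)$u)
  })
}

## Radial nodes (1/angstrom) at which a volume expansion must be known to
## evaluate central slices on the full N x N frequency grid.
slice_radial_nodes <- function(n, voxel_size) {
  image_freq_geometry(n)$r_unique_int / (n * voxel_size)
}

#' Expansion tailored for slice evaluation on the image frequency grid
#'
#' Convenience wrapper: expands `v` at every distinct radial frequency of
#' the `N x N` image grid so [project()] and [simulate_dataset()] can
#' evaluate exact central slices.
#'
#' @param v a [volume_grid()].
#' @param L harmonic bandlimit.
#' @return a [volume_expansion()].
#' @export
expand_for_slices <- function(v, L = 8L) {
  expand_volume(v, L, slice_radial_nodes(v$n, v$voxel_size))
}

## Inverse 2D DFT from the centred frequency grid to centred pixels:
## I(x_a, x_b) = (1/(N dx)^2) sum_q Fc[q] exp(+2 pi i q . (a - 1 - N/2)/N).
freq_grid_to_image <- function(Fc, voxel_size) {
  n <- nrow(Fc)
  sh <- c((n %/% 2L + 1L):n, 1L:(n %/% 2L))     # ifftshift for even n
  Fhat <- Fc[sh, sh]
  alt <- outer((-1)^(0:(n - 1L)), (-1)^(0:(n - 1L)))
  img <- stats::fft(Fhat * alt, inverse = TRUE)
  Re(img) / (n * voxel_size)^2
}

## Forward: centred-frequency DFT values of a pixel image (inverse of the
## above up to the h^2 factor matching the continuous transform).
image_to_freq_grid <- function(img, voxel_size) {
  n <- nrow(img)
  alt <- outer((-1)^(0:(n - 1L)), (-1)^(0:(n - 1L)))
  Fhat <- stats::fft(img) * alt * voxel_size^2
  sh <- c((n %/% 2L + 1L):n, 1L:(n %/% 2L))     # fftshift to centred order
  Fhat[sh, sh]
}

## Evaluate the central slice F(R kappa) of an expansion on the image
## frequency grid (centred N x N complex matrix).
slice_freq_grid <- function(e, R, n, voxel_size) {
  g <- image_freq_geometry(n)
  Y <- image_freq_harmonics(n, e$bandlimit)
  ## rotating the expansion by R^T evaluates F(R kappa) at fixed grid
  ## directions, i.e. the central slice of the R-posed particle
  er <- rotate_expansion(e, t(R))
  Am <- expansion_matrix(er, apply_phase = TRUE)  # (L+1)^2 x n_r
  B <- t(Am)[g$bin, , drop = FALSE]               # N^2 x (L+1)^2
  Fv <- rowSums(Y * B)
  matrix(Fv, n, n)
}

#' Tomographic projection of a volume
#'
#' Projects along the rotated viewing axis via the Fourier-slice route: the
#' central slice of the volume's Fourier transform (evaluated exactly from
#' its harmonic expansion) is placed on the image frequency grid and
#' inverse-transformed. The projection of `v` under rotation `R` views the
#' volume down the axis `R e_z`.
#'
#' @param v a [volume_grid()] or an expansion from [expand_for_slices()].
#' @param R 3x3 rotation matrix.
#' @param L harmonic bandlimit when `v` is a volume (default 12 for a
#'   faithful single projection; the simulator uses the metric's own `L`).
#' @return `N x N` numeric image (pixel size = voxel size).
#' @export
project <- function(v, R = diag(3), L = 12L) {
  if (inherits(v, "volume_grid")) {
    e <- expand_for_slices(v, L)
    n <- v$n; vox <- v$voxel_size
  } else if (inherits(v, "volume_expansion")) {
    e <- v; n <- v$n; vox <- v$voxel_size
  } else stop("v must be a volume_grid or volume_expansion")
  Fc <- slice_freq_grid(e, R, n, vox)
  freq_grid_to_image(Fc, vox)
}

#' Apply a radial CTF to an image
#'
#' Multiplication by `H(|kappa|)` in Fourier space; real input gives real
#' output.
#'
#' @param img `N x N` numeric image.
#' @param ctf a [ctf_params()] (its `pixel_size` must match the image's).
#' @param pixel_size pixel size of `img` in angstrom.
#' @return filtered image.
#' @export
apply_ctf <- function(img, ctf, pixel_size = ctf$pixel_size) {
  n <- nrow(img)
  stopifnot(ncol(img) == n)
  if (abs(pixel_size - ctf$pixel_size) > 1e-9 * pixel_size)
    stop("CTF and image pixel sizes disagree")
  q <- seq_len(n) - 1L
  q <- ifelse(q >= n / 2, q - n, q)             # DFT-order frequencies
  kr <- sqrt(outer(q^2, q^2, "+")) / (n * pixel_size)
  H <- matrix(eval_ctf(ctf, as.numeric(kr)), n, n)
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / n^2
}

## ---- image stacks ------------------------------------------------------

#' Construct a particle image stack
#'
#' @param images numeric `N x N x n` array.
#' @param pixel_size angstrom per pixel.
#' @param ctf_assignment optional per-image index into a CTF bank.
#' @param shifts optional `n x 2` matrix of translations (angstrom).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(images, pixel_size, ctf_assignment = NULL, shifts = NULL) {
  d <- dim(images)
  stopifnot(length(d) == 3L, d[1L] == d[2L], pixel_size > 0)
  if (!is.null(ctf_assignment)) stopifnot(length(ctf_assignment) == d[3L])
  if (!is.null(shifts)) stopifnot(nrow(shifts) == d[3L], ncol(shifts) == 2L)
  structure(list(images = images, pixel_size = pixel_size,
                 n_images = d[3L], n = d[1L],
                 ctf_assignment = ctf_assignment, shifts = shifts),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d images, %d x %d px at %.3g A/px%s\n",
              x$n_images, x$n, x$n, x$pixel_size,
              if (is.null(x$ctf_assignment)) "" else
                sprintf(", %d CTF groups", length(unique(x$ctf_assignment)))))
  invisible(x)
}

#' Add white Gaussian noise at a target SNR
#'
#' The SNR convention takes the signal as the average squared pixel
#' intensity over all clean images and sets the per-pixel noise variance to
#' `signal / snr`.
#'
#' @param stack an [image_stack()] of clean images.
#' @param snr signal-to-noise ratio (> 0).
#' @param seed integer seed.
#' @return the stack with noise added; the applied per-pixel variance is
#'   attached as attribute `noise_variance`.
#' @export
add_noise <- function(stack, snr, seed = NULL) {
  stopifnot(inherits(stack, "image_stack"), snr > 0)
  with_seed(seed, function() {
  sig <- mean(stack$images^2)
  var <- sig / snr
  stack$images <- stack$images +
    array(stats::rnorm(length(stack$images), sd = sqrt(var)), dim(stack$images))
  attr(stack, "noise_variance") <- var
  stack
  })
}

#' Simulation recipe
#'
#' Bundles the study conditions of a synthetic dataset: pose distribution,
#' CTF bank, SNR and reproducibility seed. Defaults follow the synthetic
#' protocol emulated by the package: nonuniform poses from a three-component
#' von Mises-Fisher mixture, a bank of 100 unique radial CTFs, white noise
#' at SNR 0.1, 25000 images.
#'
#' @param n_images number of images.
#' @param poses a [vmf_mixture()] (or [viewing_density()]); `NULL` means
#'   uniform poses.
#' @param n_ctf CTF bank size; 0 disables the CTF (H = 1).
#' @param defocus_range defocus window (angstrom).
#' @param snr signal-to-noise ratio; `Inf` disables noise.
#' @param seed integer seed driving poses, CTF bank, assignment and noise.
#' @param L harmonic bandlimit of the projector.
#' @return object of class `simulation_recipe`.
#' @export
simulation_recipe <- function(n_images = 25000L, poses = NULL, n_ctf = 100L,
                              defocus_range = c(1e4, 3e4), snr = 0.1,
                              seed = 1L, L = 8L) {
  stopifnot(n_images >= 1L, snr > 0)
  structure(list(n_images = as.integer(n_images), poses = poses,
                 n_ctf = as.integer(n_ctf), defocus_range = defocus_range,
                 snr = snr, seed = as.integer(seed), L = as.integer(L)),
            class = "simulation_recipe")
}

#' Simulate a cryo-EM particle dataset from a volume
#'
#' Composes pose sampling, Fourier-slice projection, per-image radial CTF
#' (random assignment over the bank) and white noise at the recipe's SNR.
#' Ground-truth rotations are returned for evaluation only.
#'
#' @param v a [volume_grid()] (or an expansion from [expand_for_slices()],
#'   in which case its bandlimit is used).
#' @param recipe a [simulation_recipe()].
#' @return list with `stack` (an [image_stack()] with CTF assignment),
#'   `rotations` (`3 x 3 x n`), `ctf_bank` (list of [ctf_params()]; empty if
#'   disabled), `noise_variance` (per-pixel, 0 if `snr = Inf`),
#'   `clean_power` (mean squared clean-pixel intensity).
#' @export
simulate_dataset <- function(v, recipe) {
  stopifnot(inherits(recipe, "simulation_recipe"))
  if (inherits(v, "volume_grid")) {
    e <- expand_for_slices(v, recipe$L)
  } else {
    e <- v
  }
  n <- e$n; vox <- e$voxel_size
  nim <- recipe$n_images
  with_seed(recipe$seed, function() {
  rots <- if (is.null(recipe$poses)) {
    random_rotations(nim)
  } else {
    sample_rotations(recipe$poses, nim)
  }
  bank <- list()
  assign <- NULL
  Hgrid <- NULL
  if (recipe$n_ctf > 0L) {
    z <- stats::runif(recipe$n_ctf, recipe$defocus_range[1L], recipe$defocus_range[2L])
    bank <- lapply(z, ctf_params, pixel_size = vox)
    assign <- sample.int(recipe$n_ctf, nim, replace = TRUE)
    g <- image_freq_geometry(n)
    kr <- g$r_int / (n * vox)
    Hgrid <- vapply(bank, function(ct) eval_ctf(ct, kr), numeric(n * n))
  }
  imgs <- array(0, c(n, n, nim))
  for (i in seq_len(nim)) {
    Fc <- slice_freq_grid(e, rots[, , i], n, vox)
    if (!is.null(Hgrid)) Fc <- Fc * matrix(Hgrid[, assign[i]], n, n)
    imgs[, , i] <- freq_grid_to_image(Fc, vox)
  }
  clean_power <- mean(imgs^2)
  stack <- image_stack(imgs, vox, ctf_assignment = assign)
  noise_var <- 0
  if (is.finite(recipe$snr)) {
    stack <- add_noise(stack, recipe$snr)       # RNG continues from recipe seed
    noise_var <- attr(stack, "noise_variance")
  }
  list(stack = stack, rotations = rots, ctf_bank = bank,
       noise_variance = noise_var, clean_power = clean_power)
  })
}
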