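## Deterministic phantom volumes. Gaussian-blob mixtures (and anisotropic
## ellipsoids) have closed-form Fourier transforms, so every phantom carries
## an analytic oracle; the "harmonic" kind has an exactly known spherical
## harmonic expansion. Frequency content is kept compact so a bandlimit of
## L = 8 at N = 32 captures the phantoms essentially exactly.

#' Specify a phantom volume
#'
#' @param kind `"blobs"` (isotropic Gaussian mixture), `"ellipsoid"`
#'   (single anisotropic Gaussian), or `"harmonic"` (Gaussian envelope times
#'   a random low-degree solid-harmonic polynomial).
#' @param n grid size (default 32).
#' @param voxel_size angstrom per voxel (default 2).
#' @param seed integer seed making the phantom reproducible.
#' @param n_blobs blob count for `kind = "blobs"`.
#' @param max_offset largest blob-centre distance from the grid centre, as a
#'   fraction of the side length (default 0.14; keeps angular content within
#'   small harmonic bandlimits at the default frequency band).
#' @param sigma_range range of blob widths in angstrom.
#' @param degree top harmonic degree for `kind = "harmonic"`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("blobs", "ellipsoid", "harmonic"),
                         n = 32L, voxel_size = 2, seed = 1L,
                         n_blobs = 4L, max_offset = 0.14,
                         sigma_range = c(4, 7), degree = 4L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, n = as.integer(n), voxel_size = voxel_size,
                 seed = as.integer(seed), n_blobs = as.integer(n_blobs),
                 max_offset = max_offset, sigma_range = sigma_range,
                 degree = as.integer(degree)),
            class = "phantom_spec")
}

## Draw the blob parameters for a spec (deterministic given the seed).
phantom_params <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- spec$n * spec$voxel_size
  with_seed(spec$seed, function() {
  if (spec$kind == "blobs") {
    nb <- spec$n_blobs
    ctr <- matrix(stats::rnorm(3L * nb), nb, 3L)
    ctr <- ctr / sqrt(rowSums(ctr^2)) *
      (stats::runif(nb)^(1 / 3) * spec$max_offset * side)
    list(centers = ctr,
         sigma = stats::runif(nb, spec$sigma_range[1L], spec$sigma_range[2L]),
         amp = stats::runif(nb, 0.5, 1.5))
  } else if (spec$kind == "ellipsoid") {
    ax <- stats::runif(3L, spec$sigma_range[1L], spec$sigma_range[2L] * 1.5)
    q <- random_rotations(1L)[, , 1L]
    list(axes = ax, rotation = q, amp = 1)
  } else {
    L <- spec$degree
    cf <- complex(real = stats::rnorm((L + 1L)^2), imaginary = stats::rnorm((L + 1L)^2))
    ## realness: c_{l,-m} = (-1)^m conj(c_{lm}); m = 0 real
    pairs <- lm_pairs(L)
    for (i in seq_len(nrow(pairs))) {
      l <- pairs$l[i]; m <- pairs$m[i]
      if (m == 0) cf[i] <- Re(cf[i])
      if (m < 0) cf[i] <- (-1)^m * Conj(cf[lm_index(l, -m)])
    }
    cf <- cf / (1 + pairs$l)^1.5
    list(coeffs = cf, sigma = mean(spec$sigma_range), degree = L)
  }
  })
}

#' Build a phantom volume from a spec
#'
#' @param spec a [phantom_spec()].
#' @return a [volume_grid()]; the [phantom_spec()] and its drawn parameters
#'   are attached as attributes `spec` and `params` so tests can evaluate
#'   closed-form Fourier oracles.
#' @export
make_phantom <- function(spec) {
  p <- phantom_params(spec)
  ax <- grid_axis(spec$n, spec$voxel_size)
  n <- spec$n
  vol <- array(0, c(n, n, n))
  if (spec$kind == "blobs") {
    for (b in seq_len(nrow(p$centers))) {
      gx <- exp(-(ax - p$centers[b, 1L])^2 / (2 * p$sigma[b]^2))
      gy <- exp(-(ax - p$centers[b, 2L])^2 / (2 * p$sigma[b]^2))
      gz <- exp(-(ax - p$centers[b, 3L])^2 / (2 * p$sigma[b]^2))
      vol <- vol + p$amp[b] * (gx %o% gy %o% gz)
    }
  } else if (spec$kind == "ellipsoid") {
    X <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    Y <- X %*% p$rotation                       # rotate into principal frame
    q <- sweep(Y^2, 2L, 2 * p$axes^2, "/")
    vol <- array(p$amp * exp(-rowSums(q)), c(n, n, n))
  } else {
    X <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    r <- sqrt(rowSums(X^2))
    u <- X / pmax(r, 1e-12)
    Y <- sph_harmonics_xyz(p$degree, u)
    pairs <- lm_pairs(p$degree)
    ## solid harmonics r^l Y_lm times a Gaussian envelope
    f <- rep(0, nrow(X))
    for (l in 0:p$degree) {
      cols <- lm_index(l, -l:l)
      f <- f + (r / p$sigma)^l * Re(Y[, cols, drop = FALSE] %*% p$coeffs[cols])
    }
    vol <- array(f * exp(-r^2 / (2 * p$sigma^2)), c(n, n, n))
  }
  v <- volume_grid(vol, spec$voxel_size)
  attr(v, "spec") <- spec
  attr(v, "params") <- p
  v
}

#' Closed-form Fourier transform of a phantom at arbitrary frequencies
#'
#' For `"blobs"` and `"ellipsoid"` phantoms the continuous Fourier transform
#' (convention `F(k) = integral phi(x) exp(-2 pi i k.x) dx`) is an explicit
#' sum of Gaussians; this evaluates it exactly and independently of any
#' voxelisation, for use as an oracle.
#'
#' @param v a phantom built by [make_phantom()].
#' @param kpts numeric `m x 3` matrix of frequencies (1/angstrom).
#' @return complex vector of length `m`.
#' @export
phantom_fourier <- function(v, kpts) {
  spec <- attr(v, "spec"); p <- attr(v, "params")
  stopifnot(!is.null(spec))
  kpts <- rbind(kpts)
  if (spec$kind == "blobs") {
    out <- complex(nrow(kpts))
    k2 <- rowSums(kpts^2)
    for (b in seq_len(nrow(p$centers))) {
      s <- p$sigma[b]
      out <- out + p$amp[b] * (2 * pi * s * s)^1.5 *
        exp(-2 * pi^2 * s * s * k2) *
        exp(-2i * pi * drop(kpts %*% p$centers[b, ]))
    }
    out
  } else if (spec$kind == "ellipsoid") {
    kp <- kpts %*% p$rotation
    s <- p$axes
    p$amp * (2 * pi)^1.5 * prod(s) *
      exp(-2 * pi^2 * drop(kp^2 %*% (s^2)))
  } else {
    stop("no closed-form transform for kind = 'harmonic'")
  }
}

#' Library of mutually distinct phantoms
#'
#' Stands in for a structure database: `n` Gaussian-blob phantoms with
#' varied blob counts and geometry, deterministic in `seed`. Candidates too
#' close to an already-accepted member under the Kam volume metric are
#' rejected, so pairwise distances stay above `min_separation` times the
#' median pairwise distance.
#'
#' @param n number of phantoms.
#' @param seed integer seed.
#' @param grid_n,voxel_size grid geometry passed to [phantom_spec()].
#' @param min_separation rejection floor as a fraction of the running
#'   median pairwise distance.
#' @return named list of [volume_grid()]s (`ph01`, `ph02`, ...).
#' @export
make_phantom_library <- function(n, seed = 1L, grid_n = 32L, voxel_size = 2,
                                 min_separation = 0.15) {
  stopifnot(n >= 1L)
  grid <- default_polar_grid(grid_n, voxel_size, L = 8L)
  cfg <- metric_config(grid, L = 8L, P = 2L)
  out <- list()
  moms <- list()
  pairwise <- numeric(0)
  attempt <- 0L
  while (length(out) < n) {
    attempt <- attempt + 1L
    if (attempt > 20L * n) stop("phantom rejection sampling did not terminate")
    sp <- phantom_spec("blobs", n = grid_n, voxel_size = voxel_size,
                       seed = seed * 1000L + attempt,
                       n_blobs = 3L + (attempt %% 4L),
                       sigma_range = c(3.5, 7))
    v <- make_phantom(sp)
    m <- analytic_moments_uniform(expand_volume(v, 8L, grid$k), grid)
    if (length(out)) {
      dnew <- vapply(moms, function(mm) d_volume(m, mm, cfg), numeric(1L))
      if (min(dnew) < min_separation * stats::median(c(pairwise, dnew))) next
      pairwise <- c(pairwise, dnew)
    }
    out[[length(out) + 1L]] <- v
    moms[[length(moms) + 1L]] <- m
  }
  names(out) <- sprintf("ph%02d", seq_len(n))
  out
}
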