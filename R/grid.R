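## Polar Fourier grid on which moments are represented.

#' Construct a polar Fourier grid
#'
#' First and second moments are stored on a polar grid of radial frequencies
#' `k_j` (1/angstrom) and uniform angles `phi_t` on `[0, 2pi)`. The radial
#' nodes follow the volume grid's natural frequency spacing by default
#' (`k_j = j / side_length`, a uniform ladder), or Gauss-Legendre nodes on
#' `(0, k_max]`; each node carries a quadrature weight `w_j` used by the
#' discrete moment norms, which also weight entries by `k` (first moment)
#' and `k1 k2` (second moment) to approximate the continuous polar measures.
#'
#' @param n_k number of radial nodes.
#' @param n_phi number of angular nodes (uniform); must satisfy
#'   `n_phi >= 2 (2 L + 1)` for the volume bandlimit `L` in use — checked by
#'   [metric_config()].
#' @param k_max largest radial frequency (1/angstrom).
#' @param radial `"uniform"` for `k_j = j k_max / n_k` with Riemann weights,
#'   or `"gauss"` for Gauss-Legendre nodes/weights on `(0, k_max]`.
#' @return object of class `polar_grid` with fields `k`, `w_k`, `phi`,
#'   `n_k`, `n_phi`, `k_max`.
#' @export
polar_grid <- function(n_k, n_phi, k_max, radial = c("uniform", "gauss")) {
  radial <- match.arg(radial)
  stopifnot(n_k >= 1L, n_phi >= 2L, is.finite(k_max), k_max > 0)
  if (radial == "uniform") {
    k <- seq_len(n_k) * k_max / n_k
    w <- rep(k_max / n_k, n_k)
  } else {
    gl <- pracma::gaussLegendre(n_k, 0, k_max)
    k <- gl$x
    w <- gl$w
  }
  structure(list(k = k, w_k = w, phi = 2 * pi * (seq_len(n_phi) - 1L) / n_phi,
                 n_k = as.integer(n_k), n_phi = as.integer(n_phi),
                 k_max = k_max, radial = radial),
            class = "polar_grid")
}

#' Default polar grid for a volume grid
#'
#' Radial nodes at multiples of `1/side_length` up to roughly half the
#' Nyquist frequency (low-order moments are a low-resolution summary; the
#' default band keeps the harmonic bandlimit `L` commensurate with the
#' angular content at the band edge), and an FFT-friendly angular count of
#' at least `2 (2L + 1)`.
#'
#' @param n volume grid size (voxels per side).
#' @param voxel_size angstrom per voxel.
#' @param L volume harmonic bandlimit the grid must support.
#' @param n_k number of radial nodes; default `n %/% 4`.
#' @return a [polar_grid()].
#' @export
default_polar_grid <- function(n, voxel_size, L = 8L, n_k = n %/% 4L) {
  side <- n * voxel_size
  n_phi <- 4L * ceiling((2L * (2L * L + 1L) + 1L) / 4)
  polar_grid(n_k, n_phi, k_max = n_k / side, radial = "uniform")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("<polar_grid> %d radial x %d angular nodes (%s), k in (0, %.4g] 1/A\n",
              x$n_k, x$n_phi, x$radial, x$k_max))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-12) {
  a$n_k == b$n_k && a$n_phi == b$n_phi &&
    max(abs(a$k - b$k)) <= tol * max(a$k) && max(abs(a$w_k - b$w_k)) <= tol
}
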