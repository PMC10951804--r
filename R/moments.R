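## Analytic first and second moments of projection images.
##
## For a rotation R, the Fourier-slice theorem makes the image transform a
## central slice of F: Ihat(k, phi) = F(R c_phi) with c_phi =
## k (cos phi, sin phi, 0). The moments under a pose density rho (invariant
## to in-plane rotation) are
##   m1(k)              = E[Ihat(k, phi)]
##   m2(k1, k2, dphi)   = E[Ihat(k1, phi + dphi) conj(Ihat(k2, phi))],
## independent of phi. They are computed EXACTLY for a bandlimited
## expansion: the in-plane average is a discrete circular mean (exact for
## trigonometric polynomials of degree <= 2L on an n_phi > 2L grid), and
## the viewing-sphere integral uses Gauss-Legendre x uniform-azimuth nodes
## that integrate the degree <= 2L + P integrand exactly. Both moments are
## linear in the density coefficients B_pu, which yields the design
## operators eliminated by the image metric.

#' First and second moments on a polar grid
#'
#' @param m1 complex vector of length `n_k`.
#' @param m2 complex array `n_phi x n_k x n_k`; entry `[s, j1, j2]` holds
#'   `m2(k_j1, k_j2, dphi_s)` with `dphi_s = 2 pi (s-1) / n_phi`.
#' @param grid the [polar_grid()] the moments live on.
#' @return object of class `moment_pair`.
#' @export
moment_pair <- function(m1, m2, grid) {
  stopifnot(inherits(grid, "polar_grid"),
            length(m1) == grid$n_k,
            all(dim(m2) == c(grid$n_phi, grid$n_k, grid$n_k)),
            all(is.finite(Re(m1))), all(is.finite(Re(m2))))
  structure(list(m1 = as.complex(m1), m2 = m2, grid = grid),
            class = "moment_pair")
}

#' @export
print.moment_pair <- function(x, ...) {
  cat(sprintf("<moment_pair> n_k = %d, n_phi = %d; |m1| up to %.4g, |m2| up to %.4g\n",
              x$grid$n_k, x$grid$n_phi, max(abs(x$m1)), max(abs(x$m2))))
  invisible(x)
}

## Hermitian structure m2(k1,k2,dphi) = conj(m2(k2,k1,-dphi)); returns the
## max absolute violation relative to the largest entry.
hermitian_error <- function(m) {
  n <- m$grid$n_phi
  sm <- c(1L, n:2L)                              # index of -dphi
  err <- max(abs(m$m2 - Conj(aperm(m$m2, c(1L, 3L, 2L))[sm, , , drop = FALSE])))
  mx <- max(abs(m$m2))
  if (mx == 0) 0 else err / mx
}

## Central slice of the expansion at rotation R, on the polar grid:
## returns n_phi x n_k complex matrix S[t, j] = F(k_j R c_{phi_t}).
slice_polar <- function(e, R, grid) {
  cp <- cbind(cos(grid$phi), sin(grid$phi), 0)
  u <- cp %*% t(R)
  eval_expansion(e, u)
}

## In-plane-averaged moments of a single slice S (n_phi x n_k):
## m1[j] = mean_t S[t, j];
## m2[s, j1, j2] = (1/n_phi) sum_t S[t + s - 1, j1] conj(S[t, j2]).
## Exact circular means via FFT along the angle.
slice_moments <- function(S) {
  np <- nrow(S); nk <- ncol(S)
  m1 <- colMeans(S)
  Fh <- stats::mvfft(S)
  m2 <- array(0i, c(np, nk, nk))
  for (j2 in seq_len(nk)) {
    cross <- Fh * Conj(Fh[, j2])                 # n_phi x n_k, all j1 at once
    m2[, , j2] <- stats::mvfft(cross, inverse = TRUE) / np^2
  }
  list(m1 = m1, m2 = m2)
}

## Gauss-Legendre (polar) x uniform (azimuth) nodes on the sphere, exact
## for spherical polynomials of degree <= min(2 n_theta - 1, n_phi - 1).
sphere_quadrature <- function(n_theta, n_phi) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  z <- rep(gl$x, each = n_phi)
  th <- acos(z)
  ph <- rep(phi, times = n_theta)
  s <- sin(th)
  list(u = cbind(s * cos(ph), s * sin(ph), z),
       theta = th, phi = ph,
       w = rep(gl$w, each = n_phi) * (2 * pi / n_phi))
}

## Per-node slice moments over a viewing-sphere quadrature: the reusable
## core of analytic moments and of the design operators. The quadrature is
## sized so that rho (degree <= P) times the node moments (degree <= 2L)
## integrates exactly.
moment_node_table <- function(e, grid, P = 2L) {
  L <- e$bandlimit
  deg <- 2L * L + as.integer(P)
  nt <- ceiling((deg + 1L) / 2) + 1L
  np <- deg + 2L
  q <- sphere_quadrature(nt, np)
  nn <- nrow(q$u)
  nk <- grid$n_k
  M1 <- matrix(0i, nn, nk)
  M2 <- matrix(0i, nn, grid$n_phi * nk * nk)
  for (i in seq_len(nn)) {
    Rv <- rot_zyz(q$phi[i], q$theta[i], 0)
    sm <- slice_moments(slice_polar(e, Rv, grid))
    M1[i, ] <- sm$m1
    M2[i, ] <- sm$m2
  }
  list(quad = q, M1 = M1, M2 = M2, P = as.integer(P))
}

## Check that the grid radial nodes are covered by the expansion's nodes.
check_grid_nodes <- function(e, grid) {
  if (length(e$radial_nodes) < grid$n_k ||
      max(abs(e$radial_nodes[seq_len(grid$n_k)] - grid$k)) > 1e-9 * max(grid$k))
    stop("polar grid radial nodes do not match the expansion's radial nodes")
}

#' Analytic moments under the uniform viewing distribution
#'
#' @param e a [volume_expansion()] whose radial nodes start with the grid's.
#' @param grid a [polar_grid()]; requires `n_phi > 2 L`.
#' @return a [moment_pair()].
#' @export
analytic_moments_uniform <- function(e, grid) {
  analytic_moments(e, grid, uniform_density(0L))
}

#' Analytic moments under a general admissible viewing density
#'
#' @param e a [volume_expansion()].
#' @param grid a [polar_grid()].
#' @param density a [viewing_density()].
#' @return a [moment_pair()].
#' @export
analytic_moments <- function(e, grid, density) {
  stopifnot(inherits(density, "viewing_density"))
  check_grid_nodes(e, grid)
  if (grid$n_phi <= 2L * e$bandlimit)
    stop("grid n_phi must exceed 2 L for exact in-plane averages")
  tab <- moment_node_table(e, grid, density$bandlimit)
  rho <- eval_density(density, tab$quad$u)
  wr <- tab$quad$w * rho
  m1 <- drop(crossprod(tab$M1, wr))
  m2 <- array(drop(crossprod(tab$M2, wr)), c(grid$n_phi, grid$n_k, grid$n_k))
  moment_pair(m1, m2, grid)
}

#' Design operators mapping density coefficients to analytic moments
#'
#' Both moments are affine in the free density coefficient vector `b` (see
#' [density_to_vector()]): `m1(b) = m1_0 + L1 b`, `m2(b) = m2_0 + L2 b`,
#' where the constants are the uniform-density moments contributed by the
#' fixed `B_00`. The image metric eliminates the unknown density by linear
#' least squares on this system.
#'
#' @param e a [volume_expansion()].
#' @param grid a [polar_grid()].
#' @param P even density bandlimit.
#' @return object of class `moment_design`: `m1_0` (complex `n_k`), `m2_0`
#'   (complex `n_phi x n_k x n_k` array), `L1` (`n_k x n_b`), `L2`
#'   (`(n_phi n_k^2) x n_b`), `P`, `grid`, `n_b`.
#' @export
moment_design <- function(e, grid, P = 2L) {
  P <- as.integer(P)
  stopifnot(P %% 2L == 0L)
  check_grid_nodes(e, grid)
  if (grid$n_phi <= 2L * e$bandlimit)
    stop("grid n_phi must exceed 2 L for exact in-plane averages")
  tab <- moment_node_table(e, grid, P)
  q <- tab$quad
  w0 <- q$w / (4 * pi)                           # rho = B_00 Y_00 = 1/(4 pi)
  m1_0 <- drop(crossprod(tab$M1, w0))
  m2_0 <- array(drop(crossprod(tab$M2, w0)), c(grid$n_phi, grid$n_k, grid$n_k))
  dof <- density_dof_table(P)
  nb <- nrow(dof)
  L1 <- matrix(0i, grid$n_k, nb)
  L2 <- matrix(0i, grid$n_phi * grid$n_k^2, nb)
  if (nb > 0) {
    Y <- sph_harmonics_xyz(P, q$u)
    for (a in seq_len(nb)) {
      Ypu <- Y[, lm_index(dof$p[a], dof$u[a])]
      psi <- if (dof$u[a] == 0L) Re(Ypu)
             else if (dof$part[a] == "re") 2 * Re(Ypu)
             else -2 * Im(Ypu)
      L1[, a] <- drop(crossprod(tab$M1, q$w * psi))
      L2[, a] <- drop(crossprod(tab$M2, q$w * psi))
    }
  }
  structure(list(m1_0 = m1_0, m2_0 = m2_0, L1 = L1, L2 = L2,
                 P = P, grid = grid, n_b = nb,
                 bandlimit = e$bandlimit),
            class = "moment_design")
}

#' @export
print.moment_design <- function(x, ...) {
  cat(sprintf("<moment_design> P = %d (%d free coefficients), grid %d x %d\n",
              x$P, x$n_b, x$grid$n_k, x$grid$n_phi))
  invisible(x)
}

#' Apply a moment design to a density coefficient vector
#'
#' @param design a [moment_design()].
#' @param b free coefficient vector (length `design$n_b`), or a
#'   [viewing_density()] of the same bandlimit.
#' @return the predicted [moment_pair()].
#' @export
design_moments <- function(design, b) {
  if (inherits(b, "viewing_density")) {
    stopifnot(b$bandlimit == design$P)
    b <- density_to_vector(b)
  }
  stopifnot(length(b) == design$n_b)
  g <- design$grid
  m1 <- design$m1_0 + if (design$n_b) drop(design$L1 %*% b) else 0
  m2v <- as.vector(design$m2_0) + if (design$n_b) drop(design$L2 %*% b) else 0
  moment_pair(m1, array(m2v, c(g$n_phi, g$n_k, g$n_k)), g)
}
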