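## Complex orthonormal spherical harmonics (Condon-Shortley phase), Wigner
## rotation matrices and rotation utilities. All harmonic machinery in the
## package funnels through these few functions so conventions live in one
## place: Y_lm(theta, phi) = Nbar_lm P_lm(cos theta) e^{i m phi} with
## Nbar_lm = sqrt((2l+1)/(4pi) (l-m)!/(l+m)!) and the (-1)^m phase folded
## into P_lm, i.e. DLMF 14.30.1.

#' Flat column index of (l, m) in a packed harmonic matrix
#'
#' Coefficient tables and harmonic design matrices store all degrees up to a
#' bandlimit `L` in `(L+1)^2` columns ordered by degree then order,
#' `m = -l, ..., l`.
#'
#' @param l degree (vectorised).
#' @param m order (vectorised).
#' @return 1-based column index `l^2 + l + m + 1`.
#' @export
lm_index <- function(l, m) l * l + l + m + 1L

#' Degrees and orders for a packed harmonic matrix
#' @param L bandlimit.
#' @return data.frame with columns `l` and `m`, row `i` giving the (l, m)
#'   pair of packed column `i`.
#' @export
lm_pairs <- function(L) {
  l <- rep.int(0:L, 2L * (0:L) + 1L)
  m <- unlist(lapply(0:L, function(ll) seq(-ll, ll)), use.names = FALSE)
  data.frame(l = l, m = m)
}

## Normalised associated Legendre functions Pbar_lm(x) for m >= 0, with
## Condon-Shortley phase, such that Y_lm = Pbar_lm(cos theta) e^{i m phi} and
## the Y_lm are orthonormal on the sphere. Stable three-term recursions.
## Returns a length(x) x (L+1)(L+2)/2 matrix, columns ordered (l, m) with
## m <= l, index l(l+1)/2 + m + 1.
assoc_legendre_norm <- function(L, x) {
  n <- length(x)
  ncol <- (L + 1L) * (L + 2L) / 2L
  P <- matrix(0, n, ncol)
  idx <- function(l, m) l * (l + 1L) / 2L + m + 1L
  s <- sqrt(pmax(0, 1 - x * x))      # sin(theta)
  P[, 1L] <- 1 / sqrt(4 * pi)        # Pbar_00
  if (L == 0L) return(P)
  ## diagonal: Pbar_mm = -sqrt((2m+1)/(2m)) * s * Pbar_{m-1,m-1}
  for (m in 1:L)
    P[, idx(m, m)] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[, idx(m - 1L, m - 1L)]
  ## first off-diagonal: Pbar_{m+1,m} = sqrt(2m+3) * x * Pbar_mm
  for (m in 0:(L - 1L))
    P[, idx(m + 1L, m)] <- sqrt(2 * m + 3) * x * P[, idx(m, m)]
  if (L >= 2L) {
    for (l in 2:L) {
      mm <- 0:(l - 2L)
      for (m in mm) {
        a <- sqrt((4 * l * l - 1) / (l * l - m * m))
        b <- sqrt(((l - 1)^2 - m * m) * (2 * l + 1) / ((l * l - m * m) * (2 * l - 3)))
        P[, idx(l, m)] <- a * x * P[, idx(l - 1L, m)] - b * P[, idx(l - 2L, m)]
      }
    }
  }
  P
}

#' Evaluate complex spherical harmonics at points on the sphere
#'
#' @param L bandlimit; all degrees `0..L` are returned.
#' @param theta polar angles (radians, from +z).
#' @param phi azimuthal angles (radians).
#' @return complex matrix `length(theta) x (L+1)^2`, column `lm_index(l, m)`
#'   holding `Y_lm(theta, phi)`.
#' @export
sph_harmonics <- function(L, theta, phi) {
  stopifnot(length(theta) == length(phi), L >= 0L)
  n <- length(theta)
  P <- assoc_legendre_norm(L, cos(theta))
  pidx <- function(l, m) l * (l + 1L) / 2L + m + 1L
  Y <- matrix(0 + 0i, n, (L + 1L)^2)
  em <- vector("list", L + 1L)       # e^{i m phi}, m = 0..L
  for (m in 0:L) em[[m + 1L]] <- exp(1i * m * phi)
  for (l in 0:L) {
    for (m in 0:l) {
      v <- P[, pidx(l, m)] * em[[m + 1L]]
      Y[, lm_index(l, m)] <- v
      if (m > 0) Y[, lm_index(l, -m)] <- (-1)^m * Conj(v)
    }
  }
  Y
}

#' Evaluate spherical harmonics at unit direction vectors
#' @param L bandlimit.
#' @param u numeric matrix `n x 3` of unit vectors (rows).
#' @return complex matrix `n x (L+1)^2` as [sph_harmonics()].
#' @export
sph_harmonics_xyz <- function(L, u) {
  u <- rbind(u)
  theta <- acos(pmin(1, pmax(-1, u[, 3L])))
  phi <- atan2(u[, 2L], u[, 1L])
  sph_harmonics(L, theta, phi)
}

## ---- rotations --------------------------------------------------------

#' Rotation matrix from ZYZ Euler angles
#'
#' `rot_zyz(a, b, g) = Rz(a) %*% Ry(b) %*% Rz(g)`.
#' @param alpha,beta,gamma Euler angles in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_zyz <- function(alpha, beta, gamma) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(alpha) %*% ry(beta) %*% rz(gamma)
}

#' ZYZ Euler angles of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return numeric `c(alpha, beta, gamma)` with `beta` in `[0, pi]`.
#' @export
euler_zyz <- function(R) {
  beta <- acos(pmin(1, pmax(-1, R[3L, 3L])))
  if (abs(sin(beta)) < 1e-9) {
    ## gimbal: only alpha -/+ gamma is determined; fold it into alpha.
    ## beta = 0: R = Rz(a+g); beta = pi: R[1:2,1:2] = Rz(a-g) %*% diag(-1,1)
    alpha <- if (R[3L, 3L] > 0) atan2(R[2L, 1L], R[1L, 1L])
             else atan2(-R[2L, 1L], -R[1L, 1L])
    return(c(alpha, beta, 0))
  }
  alpha <- atan2(R[2L, 3L], R[1L, 3L])
  gamma <- atan2(R[3L, 2L], -R[3L, 1L])
  c(alpha, beta, gamma)
}

#' Haar-uniform random rotations
#' @param n number of rotations.
#' @return `3 x 3 x n` array of rotation matrices.
#' @export
random_rotations <- function(n) {
  ## unit quaternions from 4 i.i.d. normals are exactly Haar on SO(3)
  q <- matrix(stats::rnorm(4L * n), n, 4L)
  q <- q / sqrt(rowSums(q^2))
  a <- q[, 1L]; b <- q[, 2L]; c <- q[, 3L]; d <- q[, 4L]
  out <- array(0, c(3, 3, n))
  out[1, 1, ] <- a * a + b * b - c * c - d * d
  out[1, 2, ] <- 2 * (b * c - a * d)
  out[1, 3, ] <- 2 * (b * d + a * c)
  out[2, 1, ] <- 2 * (b * c + a * d)
  out[2, 2, ] <- a * a - b * b + c * c - d * d
  out[2, 3, ] <- 2 * (c * d - a * b)
  out[3, 1, ] <- 2 * (b * d - a * c)
  out[3, 2, ] <- 2 * (c * d + a * b)
  out[3, 3, ] <- a * a - b * b - c * c + d * d
  out
}

## Wigner small-d matrices d^l_{m' m}(beta) for l = 0..L, via the explicit
## factorial sum (stable in log space; fine for the small bandlimits used
## here, l <= ~30). Rows indexed by m' = -l..l, columns by m = -l..l.
## The beta-independent term table (signed coefficients and the powers of
## cos(beta/2), sin(beta/2) per term) is cached per degree, making repeated
## evaluation (one rotation per particle image) a few vector operations.
.wigner_env <- new.env(parent = emptyenv())

wigner_terms <- function(l) {
  key <- sprintf("l%d", l)
  if (!is.null(.wigner_env[[key]])) return(.wigner_env[[key]])
  lfac <- function(k) lgamma(k + 1)
  entry <- integer(0); coef <- numeric(0); pc <- integer(0); ps <- integer(0)
  idx <- 0L
  for (m in -l:l) for (mp in -l:l) {            # column-major over (mp, m)
    idx <- idx + 1L
    smin <- max(0L, m - mp)
    smax <- min(l + m, l - mp)
    if (smin > smax) next
    s <- smin:smax
    pref <- 0.5 * (lfac(l + m) + lfac(l - m) + lfac(l + mp) + lfac(l - mp))
    lt <- pref - (lfac(l + m - s) + lfac(s) + lfac(mp - m + s) + lfac(l - mp - s))
    entry <- c(entry, rep.int(idx, length(s)))
    coef <- c(coef, (-1)^(mp - m + s) * exp(lt))
    pc <- c(pc, 2L * l + m - mp - 2L * s)
    ps <- c(ps, mp - m + 2L * s)
  }
  val <- list(entry = entry, coef = coef, pc = pc, ps = ps,
              n_entry = (2L * l + 1L)^2)
  .wigner_env[[key]] <- val
  val
}

wigner_d <- function(L, beta) {
  cb <- cos(beta / 2); sb <- sin(beta / 2)
  out <- vector("list", L + 1L)
  for (l in 0:L) {
    tt <- wigner_terms(l)
    v <- tt$coef * cb^tt$pc * sb^tt$ps          # 0^0 == 1 in R, as needed
    d <- numeric(tt$n_entry)
    acc <- rowsum(v, tt$entry)
    d[as.integer(rownames(acc))] <- acc
    out[[l + 1L]] <- matrix(d, 2L * l + 1L, 2L * l + 1L)
  }
  out
}

#' Wigner D-matrices of a rotation
#'
#' Returns the unitary representation matrices `D^l(R)` for `l = 0..L` in the
#' convention where, for any unit vector `u`,
#' `Y_lm(R^{-1} u) = sum_{m'} D^l[m', m] Y_lm'(u)`,
#' so that a volume rotated by `R` has harmonic coefficients `D^l %*% A_l`.
#'
#' @param L bandlimit.
#' @param R 3x3 rotation matrix.
#' @return list of `L + 1` complex matrices, element `l + 1` of size
#'   `(2l+1) x (2l+1)` with rows/columns ordered `m = -l..l`.
#' @export
wigner_D <- function(L, R) {
  ang <- euler_zyz(R)
  dd <- wigner_d(L, ang[2L])
  out <- vector("list", L + 1L)
  for (l in 0:L) {
    m <- -l:l
    ea <- exp(-1i * m * ang[1L])     # over m' (rows)
    eg <- exp(-1i * m * ang[3L])     # over m (cols)
    out[[l + 1L]] <- (ea %o% eg) * dd[[l + 1L]]
  }
  out
}
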