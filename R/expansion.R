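## Fourier-space spherical harmonic expansion of a voxel volume.
##
## With the Fourier convention F(k) = integral phi(x) exp(-2 pi i k.x) dx,
## the volume's transform restricted to the sphere of radius k expands as
## F(k u) = sum_lm A_lm(k) Y_lm(u). Treating the voxel volume as a weighted
## point set (midpoint rule), the plane-wave expansion
##   exp(-2 pi i k.x) = 4 pi sum_lm (-i)^l j_l(2 pi k r) conj(Y_lm(xhat)) Y_lm(khat)
## gives the coefficients exactly, with no angular quadrature and no
## off-grid interpolation:
##   A_lm(k) = 4 pi (-i)^l h^3 sum_x v(x) j_l(2 pi k r_x) conj(Y_lm(xhat_x)).
## Voxels are binned by their (few hundred distinct) radii, which makes the
## computation a pair of small dense products per degree.

.kam_cache <- new.env(parent = emptyenv())

## Run fn under a fixed seed (when given) without disturbing the caller's
## RNG stream; seeded package functions are reproducible side-effect-free.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  fn()
}

cache_get <- function(key, fn) {
  if (!is.null(.kam_cache[[key]])) return(.kam_cache[[key]])
  val <- fn()
  .kam_cache[[key]] <- val
  val
}

#' Clear the internal geometry cache
#'
#' Precomputed voxel-geometry tables (harmonics on the voxel grid, spherical
#' Bessel tables) are cached per grid shape; call this to free them.
#' @return invisibly, `NULL`.
#' @export
clear_kam_cache <- function() {
  rm(list = ls(.kam_cache), envir = .kam_cache)
  invisible(NULL)
}

## Voxel geometry for an N^3 grid (voxel units; radii scale by voxel_size):
## unique radii, bin index per voxel, and conj(Y) per voxel binned later.
voxel_geometry <- function(n) {
  cache_get(sprintf("geom:%d", n), function() {
    ax <- seq_len(n) - 1 - n %/% 2
    X <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    r2 <- rowSums(X^2)
    ru2 <- sort(unique(r2))
    bin <- match(r2, ru2)
    list(X = X, r = sqrt(r2), r_unique = sqrt(ru2), bin = bin)
  })
}

## Per-degree tables T_l(rho, m) = sum_{x in bin rho} v(x) conj(Y_lm(xhat)),
## precomputed structure: conj(Y) on voxels (cached), binned per volume.
voxel_harmonics <- function(n, L) {
  cache_get(sprintf("vY:%d:%d", n, L), function() {
    g <- voxel_geometry(n)
    u <- g$X / pmax(g$r, 1e-300)
    u[g$r == 0, ] <- c(0, 0, 1)
    Conj(sph_harmonics_xyz(L, u))
  })
}

## j_l(2 pi k rho) for unique radii rho (angstrom) x radial nodes k, per l.
## x = 0 handled explicitly (j_0(0) = 1, j_l(0) = 0 for l >= 1).
sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  nz <- x > 1e-12
  if (any(nz))
    out[nz] <- besselJ(x[nz], l + 0.5) * sqrt(pi / (2 * x[nz]))
  if (l == 0L) out[!nz] <- 1
  out
}

bessel_tables <- function(n, voxel_size, k, L) {
  key <- sprintf("jl:%d:%.10g:%d:%s", n, voxel_size, L,
                 paste(c(signif(k, 10)), collapse = ","))
  cache_get(key, function() {
    g <- voxel_geometry(n)
    rho <- g$r_unique * voxel_size
    arg <- 2 * pi * outer(rho, k)               # n_unique x n_k
    lapply(0:L, function(l) {
      m <- sph_bessel(l, as.numeric(arg))
      matrix(m, nrow = length(rho))
    })
  })
}

#' Expand a volume in Fourier-space spherical harmonics
#'
#' Computes the coefficients `A_lm(k_j)` of the volume's Fourier transform
#' on spheres of radius `k_j`, for all degrees `l <= L`, by an exact
#' projection of the voxel volume's nonuniform Fourier transform (spherical
#' Bessel route; no interpolation). Coefficients follow the phase convention
#' `F(k u) = sum_lm (-i)^l A_lm(k) Y_lm(u)` (the `i^l` of the plane-wave
#' expansion is folded into the coefficient), under which a real volume
#' satisfies the conjugate symmetry `A_{l,-m}(k) = (-1)^m conj(A_lm(k))` to
#' machine precision; [eval_expansion()] restores the phase.
#'
#' @param v a [volume_grid()].
#' @param L harmonic bandlimit (`0 <= L`); degrees above
#'   `pi * n / 2` exceed what the voxel grid can resolve and are refused.
#' @param radial_nodes radial frequencies `k_j` (1/angstrom), strictly
#'   positive; defaults to the nodes of [default_polar_grid()].
#' @return object of class `volume_expansion`: `coeffs` (list over degrees,
#'   element `l + 1` a `(2l+1) x n_k` complex matrix with rows
#'   `m = -l..l`), `radial_nodes`, `bandlimit`, `n`, `voxel_size`.
#' @export
expand_volume <- function(v, L = 8L, radial_nodes = NULL) {
  stopifnot(inherits(v, "volume_grid"), L >= 0L)
  if (L > floor(pi * v$n / 2))
    stop("bandlimit L = ", L, " exceeds the angular resolution of an N = ",
         v$n, " grid")
  if (is.null(radial_nodes))
    radial_nodes <- default_polar_grid(v$n, v$voxel_size, L = max(L, 1L))$k
  stopifnot(all(radial_nodes >= 0), !is.unsorted(radial_nodes))
  n <- v$n
  g <- voxel_geometry(n)
  Yc <- voxel_harmonics(n, L)
  Jl <- bessel_tables(n, v$voxel_size, radial_nodes, L)
  vals <- as.numeric(v$values)
  ## bin v * conj(Y) by radius: T is n_unique x (L+1)^2 (complex via Re/Im)
  Tre <- rowsum(vals * Re(Yc), g$bin, reorder = TRUE)
  Tim <- rowsum(vals * Im(Yc), g$bin, reorder = TRUE)
  h3 <- v$voxel_size^3
  coeffs <- vector("list", L + 1L)
  for (l in 0:L) {
    cols <- lm_index(l, -l:l)
    Tl <- complex(real = Tre[, cols], imaginary = Tim[, cols])
    dim(Tl) <- c(nrow(Tre), 2L * l + 1L)
    Al <- crossprod(Tl, Jl[[l + 1L]])           # (2l+1) x n_k
    coeffs[[l + 1L]] <- 4 * pi * h3 * Al
  }
  structure(list(coeffs = coeffs, radial_nodes = radial_nodes,
                 bandlimit = as.integer(L), n = n, voxel_size = v$voxel_size),
            class = "volume_expansion")
}

#' @export
print.volume_expansion <- function(x, ...) {
  cat(sprintf("<volume_expansion> L = %d, %d radial nodes in [%.4g, %.4g] 1/A (N = %d)\n",
              x$bandlimit, length(x$radial_nodes), min(x$radial_nodes),
              max(x$radial_nodes), x$n))
  invisible(x)
}

## Stack coefficients into an (L+1)^2 x n_k matrix (packed lm order).
## apply_phase multiplies degree-l rows by (-i)^l, giving the matrix that
## contracts with Y_lm values to evaluate F.
expansion_matrix <- function(e, apply_phase = FALSE) {
  M <- do.call(rbind, e$coeffs)
  if (apply_phase) {
    ph <- (-1i)^lm_pairs(e$bandlimit)$l
    M <- M * ph
  }
  M
}

#' Evaluate the expanded Fourier transform at unit directions
#'
#' Returns `F(k_j u_i) = sum_lm A_lm(k_j) Y_lm(u_i)` for every direction row
#' `u_i` and every radial node.
#'
#' @param e a [volume_expansion()].
#' @param u numeric `m x 3` matrix of unit direction vectors.
#' @return complex `m x n_k` matrix.
#' @export
eval_expansion <- function(e, u) {
  Y <- sph_harmonics_xyz(e$bandlimit, u)
  Y %*% expansion_matrix(e, apply_phase = TRUE)
}

#' Rotate an expansion with Wigner-D matrices
#'
#' Returns the expansion of the volume rotated by `R` (i.e. of
#' `v'(x) = v(R^{-1} x)`), applying the degree-wise unitary Wigner-D blocks;
#' radial nodes are unchanged and no resampling occurs.
#'
#' @param e a [volume_expansion()].
#' @param R 3x3 rotation matrix.
#' @return a [volume_expansion()].
#' @export
rotate_expansion <- function(e, R) {
  D <- wigner_D(e$bandlimit, R)
  e$coeffs <- lapply(seq_along(e$coeffs),
                     function(i) D[[i]] %*% e$coeffs[[i]])
  e
}

#' Per-degree shell energy of an expansion
#'
#' `E_l(k) = sum_m |A_lm(k)|^2`, a rotation invariant.
#' @param e a [volume_expansion()].
#' @return numeric `(L+1) x n_k` matrix.
#' @export
shell_energy <- function(e) {
  t(vapply(e$coeffs, function(A) colSums(abs(A)^2),
           numeric(length(e$radial_nodes))))
}

## Max relative violation of the real-volume conjugate symmetry; used by
## tests and as a cheap sanity diagnostic.
conjugate_symmetry_error <- function(e) {
  mx <- max(abs(expansion_matrix(e)))
  if (mx == 0) return(0)
  err <- 0
  for (l in 0:e$bandlimit) {
    A <- e$coeffs[[l + 1L]]
    for (m in 0:l) {
      d <- A[l + 1L - m, ] - (-1)^m * Conj(A[l + 1L + m, ])
      err <- max(err, max(abs(d)))
    }
  }
  err / mx
}
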