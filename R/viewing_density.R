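## Viewing-direction densities on the projective sphere.
##
## Densities of particle orientations are modelled as invariant to in-plane
## rotation and to reflection, so they live on the sphere with antipodal
## points identified and admit an even-degree spherical harmonic expansion
## rho(v) = sum_{p even <= P} sum_u B_pu Y_pu(v). Normalisation fixes
## B_00 = 1/sqrt(4 pi); realness ties B_{p,-u} to conj(B_pu). The free real
## degrees of freedom (sum over even p >= 2 of 2p + 1) are the optimisation
## variables of the image metric.

b00_value <- function() 1 / sqrt(4 * pi)

even_degrees <- function(P) seq(0L, P, by = 2L)

#' Construct a viewing-direction density from packed coefficients
#'
#' @param coeffs complex vector of length `(P+1)^2` in packed [lm_index()]
#'   order; odd-degree entries must be zero, `B_00` must equal
#'   `1/sqrt(4 pi)`, and realness requires
#'   `B_{p,-u} = (-1)^u conj(B_pu)`.
#' @param P even bandlimit.
#' @return object of class `viewing_density`.
#' @export
viewing_density <- function(coeffs, P) {
  P <- as.integer(P)
  stopifnot(P >= 0L, P %% 2L == 0L, length(coeffs) == (P + 1L)^2)
  coeffs <- as.complex(coeffs)
  pairs <- lm_pairs(P)
  if (any(abs(coeffs[pairs$l %% 2L == 1L]) > 1e-10))
    stop("viewing density must contain only even degrees")
  if (abs(coeffs[1L] - b00_value()) > 1e-8)
    stop("B_00 must be fixed to 1/sqrt(4 pi) (unit total mass)")
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$l[i]; u <- pairs$m[i]
    if (u > 0 && abs(coeffs[lm_index(l, -u)] - (-1)^u * Conj(coeffs[i])) > 1e-8)
      stop("coefficients violate the realness constraint B_{p,-u} = (-1)^u conj(B_pu)")
  }
  structure(list(coeffs = coeffs, bandlimit = P), class = "viewing_density")
}

#' The uniform viewing-direction density
#' @param P even bandlimit of the representation.
#' @return a [viewing_density()] with only the normalisation coefficient.
#' @export
uniform_density <- function(P = 2L) {
  cf <- complex(real = numeric((as.integer(P) + 1L)^2))
  cf[1L] <- b00_value()
  viewing_density(cf, P)
}

#' @export
print.viewing_density <- function(x, ...) {
  free <- density_to_vector(x)
  cat(sprintf("<viewing_density> P = %d, %d free coefficients (|b| = %.4g)\n",
              x$bandlimit, length(free), sqrt(sum(free^2))))
  invisible(x)
}

#' Evaluate a viewing density pointwise
#' @param d a [viewing_density()].
#' @param u numeric `m x 3` matrix of unit directions.
#' @return numeric vector of density values (imaginary residue discarded
#'   after an internal check).
#' @export
eval_density <- function(d, u) {
  Y <- sph_harmonics_xyz(d$bandlimit, rbind(u))
  val <- Y %*% d$coeffs
  val <- drop(val)
  if (length(val) && max(abs(Im(val))) > 1e-8 * max(1, max(abs(val))))
    warning("viewing density evaluated with non-negligible imaginary part")
  Re(val)
}

#' Most negative pointwise value of a density (diagnostic)
#'
#' Positivity is not enforced on fitted densities; this reports the most
#' negative value on a quasi-uniform direction set so users can judge how
#' far a fit strays from a true probability density.
#'
#' @param d a [viewing_density()].
#' @param n number of probe directions (Fibonacci sphere).
#' @return smallest probed value of the density.
#' @export
density_min <- function(d, n = 2000L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- acos(z)
  ph <- pi * (1 + sqrt(5)) * i
  u <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), z)
  min(eval_density(d, u))
}

#' Project a pointwise density onto the admissible even-degree space
#'
#' Symmetrises `f` over the antipodal map and projects onto even-degree
#' spherical harmonics up to `P` by Gauss-Legendre x uniform-azimuth
#' quadrature. `f` must integrate to 1 on the sphere (checked to 1e-3).
#'
#' @param f function taking an `m x 3` matrix of unit directions and
#'   returning nonnegative density values.
#' @param P even bandlimit.
#' @param n_theta,n_phi quadrature resolution.
#' @return a [viewing_density()].
#' @export
project_density <- function(f, P = 2L, n_theta = 40L, n_phi = 80L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  th <- acos(gl$x)
  TH <- rep(th, each = n_phi)
  PH <- rep(phi, times = n_theta)
  W <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  u <- cbind(sin(TH) * cos(PH), sin(TH) * sin(PH), cos(TH))
  fv <- 0.5 * (f(u) + f(-u))                    # antipodal symmetrisation
  total <- sum(W * fv)
  if (abs(total - 1) > 1e-3)
    stop(sprintf("density integrates to %.5f, not 1", total))
  Y <- sph_harmonics(P, TH, PH)
  cf <- drop(crossprod(Conj(Y), W * fv))
  pairs <- lm_pairs(P)
  cf[pairs$l %% 2L == 1L] <- 0                  # odd degrees vanish exactly
  cf[1L] <- b00_value()                         # quadrature-exact up to tol
  ## enforce exact realness structure against quadrature noise
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$l[i]; m <- pairs$m[i]
    if (m == 0) cf[i] <- complex(real = Re(cf[i]))
    if (m < 0) cf[i] <- (-1)^m * Conj(cf[lm_index(l, -m)])
  }
  viewing_density(cf, P)
}

#' Rotate a viewing density
#'
#' Applies the even-degree Wigner-D blocks; the result is again an
#' admissible density (the normalisation coefficient is untouched by the
#' degree-0 block).
#'
#' @param d a [viewing_density()].
#' @param R 3x3 rotation matrix.
#' @return a [viewing_density()].
#' @export
rotate_density <- function(d, R) {
  P <- d$bandlimit
  D <- wigner_D(P, R)
  cf <- d$coeffs
  for (l in even_degrees(P)) {
    ix <- lm_index(l, -l:l)
    cf[ix] <- D[[l + 1L]] %*% cf[ix]
  }
  ## clean rotation round-off on the realness structure
  pairs <- lm_pairs(P)
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$l[i]; m <- pairs$m[i]
    if (m == 0) cf[i] <- complex(real = Re(cf[i]))
    if (m < 0) cf[i] <- (-1)^m * Conj(cf[lm_index(l, -m)])
  }
  viewing_density(cf, P)
}

## ---- free-coefficient vectorisation -----------------------------------

## Real parametrisation of the free coefficients: for each even p >= 2,
## b_{p,0} (real), then for u = 1..p the pair (Re B_pu, Im B_pu). Bijective
## with the admissible set; the zero vector is the uniform density.
density_dof_table <- function(P) {
  rows <- list()
  for (p in setdiff(even_degrees(P), 0L)) {
    rows[[length(rows) + 1L]] <- data.frame(p = p, u = 0L, part = "re")
    for (u in seq_len(p)) {
      rows[[length(rows) + 1L]] <- data.frame(p = p, u = u, part = "re")
      rows[[length(rows) + 1L]] <- data.frame(p = p, u = u, part = "im")
    }
  }
  if (!length(rows)) return(data.frame(p = integer(), u = integer(), part = character()))
  do.call(rbind, rows)
}

#' Flatten a viewing density to its free real coefficient vector
#'
#' The normalisation coefficient `B_00` is excluded and the realness
#' constraints are folded in, so the vector holds exactly the free degrees
#' of freedom of the admissible set (`sum_{p even >= 2} (2p + 1)` numbers;
#' 5 for `P = 2`). The zero vector corresponds to the uniform density.
#'
#' @param d a [viewing_density()].
#' @return numeric vector.
#' @export
density_to_vector <- function(d) {
  tab <- density_dof_table(d$bandlimit)
  if (!nrow(tab)) return(numeric(0))
  v <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    cf <- d$coeffs[lm_index(tab$p[i], tab$u[i])]
    v[i] <- if (tab$part[i] == "re") Re(cf) else Im(cf)
  }
  v
}

#' Rebuild a viewing density from its free coefficient vector
#' @param v numeric vector as produced by [density_to_vector()].
#' @param P even bandlimit.
#' @return a [viewing_density()].
#' @export
vector_to_density <- function(v, P) {
  tab <- density_dof_table(P)
  stopifnot(length(v) == nrow(tab))
  cf <- complex(real = numeric((as.integer(P) + 1L)^2))
  cf[1L] <- b00_value()
  for (i in seq_len(nrow(tab))) {
    ix <- lm_index(tab$p[i], tab$u[i])
    cf[ix] <- cf[ix] + if (tab$part[i] == "re") v[i] else 1i * v[i]
  }
  for (i in seq_len(nrow(tab))) {
    p <- tab$p[i]; u <- tab$u[i]
    if (u > 0) cf[lm_index(p, -u)] <- (-1)^u * Conj(cf[lm_index(p, u)])
  }
  viewing_density(cf, P)
}

#' Serialise a viewing density to JSON
#' @param d a [viewing_density()].
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
density_to_json <- function(d, path = NULL) {
  pairs <- lm_pairs(d$bandlimit)
  doc <- list(type = "viewing_density", bandlimit = d$bandlimit,
              coefficients = data.frame(p = pairs$l, u = pairs$m,
                                        re = Re(d$coeffs), im = Im(d$coeffs)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a viewing density from JSON
#' @param path file or JSON string produced by [density_to_json()].
#' @return a [viewing_density()].
#' @export
density_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  stopifnot(identical(doc$type, "viewing_density"))
  cf <- complex(real = doc$coefficients$re, imaginary = doc$coefficients$im)
  viewing_density(cf, doc$bandlimit)
}

## ---- von Mises-Fisher mixtures ----------------------------------------

#' Construct a von Mises-Fisher mixture on the sphere
#'
#' @param mu `k x 3` matrix of mean directions (rows normalised).
#' @param kappa concentrations (> 0; 0 is accepted and means uniform).
#' @param weights mixture weights (nonnegative, normalised to sum 1).
#' @return object of class `vmf_mixture`.
#' @export
vmf_mixture <- function(mu, kappa, weights = NULL) {
  mu <- rbind(mu)
  stopifnot(ncol(mu) == 3L, nrow(mu) == length(kappa), all(kappa >= 0))
  if (is.null(weights)) weights <- rep(1, nrow(mu))
  stopifnot(length(weights) == nrow(mu), all(weights >= 0), sum(weights) > 0)
  mu <- mu / sqrt(rowSums(mu^2))
  structure(list(mu = mu, kappa = kappa, weights = weights / sum(weights)),
            class = "vmf_mixture")
}

#' @export
print.vmf_mixture <- function(x, ...) {
  cat(sprintf("<vmf_mixture> %d components, kappa in [%.3g, %.3g]\n",
              nrow(x$mu), min(x$kappa), max(x$kappa)))
  invisible(x)
}

#' Random von Mises-Fisher mixture
#'
#' Defaults emulate a moderately nonuniform pose distribution: three
#' components with uniform random means, Dirichlet(1) weights and
#' concentrations uniform in `[4, 16]`.
#'
#' @param n_components number of components.
#' @param kappa_range concentration range.
#' @param seed optional integer seed.
#' @return a [vmf_mixture()].
#' @export
random_vmf_mixture <- function(n_components = 3L, kappa_range = c(4, 16),
                               seed = NULL) {
  with_seed(seed, function() {
    mu <- matrix(stats::rnorm(3L * n_components), n_components, 3L)
    kappa <- stats::runif(n_components, kappa_range[1L], kappa_range[2L])
    w <- stats::rexp(n_components)
    vmf_mixture(mu, kappa, w)
  })
}

#' Pointwise density of a vMF mixture
#' @param mix a [vmf_mixture()].
#' @return function mapping an `m x 3` matrix of unit directions to density
#'   values (integrating to 1 on the sphere).
#' @export
vmf_density_function <- function(mix) {
  force(mix)
  function(u) {
    u <- rbind(u)
    out <- numeric(nrow(u))
    for (i in seq_len(nrow(mix$mu))) {
      k <- mix$kappa[i]
      cst <- if (k < 1e-12) 1 / (4 * pi) else k / (4 * pi * sinh(k))
      out <- out + mix$weights[i] * cst * exp(k * drop(u %*% mix$mu[i, ]))
    }
    out
  }
}

## Sample unit vectors from a single vMF component (closed-form inverse CDF
## for the S^2 case), mean direction mu.
sample_vmf <- function(n, mu, kappa) {
  if (kappa < 1e-12) {
    z <- stats::rnorm(3L * n)
    u <- matrix(z, n, 3L)
    return(u / sqrt(rowSums(u^2)))
  }
  xi <- stats::runif(n)
  w <- 1 + log(xi + (1 - xi) * exp(-2 * kappa)) / kappa
  ang <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w * w))
  local <- cbind(s * cos(ang), s * sin(ang), w)
  ## rotate +z to mu
  mu <- mu / sqrt(sum(mu^2))
  sp <- euler_zyz_from_dir(mu)
  R <- rot_zyz(sp[1L], sp[2L], 0)
  local %*% t(R)
}

euler_zyz_from_dir <- function(u) {
  c(atan2(u[2L], u[1L]), acos(pmin(1, pmax(-1, u[3L]))))
}

#' Sample particle rotations with vMF-mixture viewing directions
#'
#' Viewing directions (third column of each rotation) are i.i.d. from the
#' mixture; the in-plane angle is independently uniform on `[0, 2 pi)`.
#'
#' @param mix a [vmf_mixture()] (or a [viewing_density()], sampled by
#'   rejection from a uniform envelope — the density must be nonnegative).
#' @param n number of rotations.
#' @param seed integer seed for reproducibility.
#' @return `3 x 3 x n` array of rotations, with the sampled viewing
#'   directions attached as attribute `directions` (`n x 3`).
#' @export
sample_rotations <- function(mix, n, seed = NULL) {
  stopifnot(n >= 1L)
  with_seed(seed, function() {
  if (inherits(mix, "vmf_mixture")) {
    comp <- sample.int(nrow(mix$mu), n, replace = TRUE, prob = mix$weights)
    u <- matrix(0, n, 3L)
    for (i in seq_len(nrow(mix$mu))) {
      sel <- comp == i
      if (any(sel)) u[sel, ] <- sample_vmf(sum(sel), mix$mu[i, ], mix$kappa[i])
    }
  } else if (inherits(mix, "viewing_density")) {
    u <- sample_density_rejection(mix, n)
  } else stop("mix must be a vmf_mixture or viewing_density")
  gamma <- stats::runif(n, 0, 2 * pi)
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) {
    sp <- euler_zyz_from_dir(u[i, ])
    out[, , i] <- rot_zyz(sp[1L], sp[2L], gamma[i])
  }
  attr(out, "directions") <- u
  out
  })
}

## Rejection sampler for a (nonnegative) bandlimited density.
sample_density_rejection <- function(d, n) {
  M <- -density_min(d, 4000L)
  peak <- max(abs(eval_density(d, rbind(c(0, 0, 1)))), 1 / (4 * pi))
  ## conservative envelope: max probed value * 1.2
  i <- seq_len(4000L) - 0.5
  z <- 1 - 2 * i / 4000
  th <- acos(z); ph <- pi * (1 + sqrt(5)) * i
  probe <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), z)
  Mmax <- max(eval_density(d, probe)) * 1.2
  if (M > 1e-9) stop("cannot sample from a density with negative values")
  out <- matrix(0, 0, 3L)
  while (nrow(out) < n) {
    m <- 2L * (n - nrow(out)) + 16L
    z <- stats::rnorm(3L * m)
    u <- matrix(z, m, 3L) / sqrt(rowSums(matrix(z, m, 3L)^2))
    acc <- stats::runif(m) * Mmax < eval_density(d, u)
    out <- rbind(out, u[acc, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
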