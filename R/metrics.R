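## The two Kam metrics.
##
## Volume metric: the weighted deviation between the uniform-density
## moments of two structures,
##   d_vol = sqrt( ||m1_a - m1_b||^2 + lambda ||m2_a - m2_b||^2 ),
## with discrete norms approximating the continuous polar measures
## (entries weighted by k for m1 and k1 k2 for m2, times radial quadrature
## weights and the angular step). Being a norm of differences it is a
## genuine pseudometric, and it is rotation-invariant because uniform
## moments are.
##
## Image metric: the same residual between empirical moments and the
## moments a structure would produce under the best admissible viewing
## density, minimised in closed form — the moments are affine in the free
## density coefficients, so the minimisation is a small linear least
## squares and the unknown pose distribution is eliminated.

#' Metric configuration
#'
#' @param grid the [polar_grid()] moments are represented on.
#' @param L volume harmonic bandlimit; requires `grid$n_phi >= 2 (2L + 1)`.
#' @param P even viewing-density bandlimit (default 2).
#' @param lambda nonnegative weight of the second-moment term (default 1).
#' @return object of class `metric_config`.
#' @export
metric_config <- function(grid, L = 8L, P = 2L, lambda = 1) {
  stopifnot(inherits(grid, "polar_grid"), lambda >= 0, P %% 2L == 0L, L >= 0L)
  if (grid$n_phi < 2L * (2L * L + 1L))
    stop("grid n_phi must be at least 2 (2L + 1) to resolve the angular bandlimit")
  structure(list(grid = grid, L = as.integer(L), P = as.integer(P),
                 lambda = lambda), class = "metric_config")
}

#' Default metric configuration for a volume grid geometry
#' @param n grid size; @param voxel_size angstrom per voxel.
#' @param L,P,lambda see [metric_config()].
#' @return a [metric_config()].
#' @export
default_metric_config <- function(n = 32L, voxel_size = 2, L = 8L, P = 2L,
                                  lambda = 1) {
  metric_config(default_polar_grid(n, voxel_size, L = L), L = L, P = P,
                lambda = lambda)
}

#' @export
print.metric_config <- function(x, ...) {
  cat(sprintf("<metric_config> L = %d, P = %d, lambda = %g, grid %d x %d (k_max %.4g)\n",
              x$L, x$P, x$lambda, x$grid$n_k, x$grid$n_phi, x$grid$k_max))
  invisible(x)
}

## Discrete norm weights: w1[j] = k_j w_j for the first moment,
## w2[s,j1,j2] = k_j1 k_j2 w_j1 w_j2 (2 pi / n_phi) for the second.
moment_weights <- function(grid) {
  w1 <- grid$k * grid$w_k
  wk <- grid$k * grid$w_k
  w2 <- outer(rep(2 * pi / grid$n_phi, grid$n_phi), outer(wk, wk))
  list(w1 = w1, w2 = w2)
}

#' Discrete moment norms
#'
#' The two weighted norms entering both metrics:
#' `n1 = sqrt(sum_j k_j w_j |m1_j|^2)` and
#' `n2 = sqrt(sum_{j1 j2 s} k_j1 k_j2 w_j1 w_j2 (2 pi / n_phi) |m2|^2)`.
#'
#' @param m a [moment_pair()].
#' @param cfg a [metric_config()] on the same grid.
#' @return numeric `c(m1 = ..., m2 = ...)`.
#' @export
metric_norms <- function(m, cfg) {
  stopifnot(inherits(m, "moment_pair"), same_grid(m$grid, cfg$grid))
  w <- moment_weights(cfg$grid)
  c(m1 = sqrt(sum(w$w1 * abs(m$m1)^2)),
    m2 = sqrt(sum(w$w2 * abs(m$m2)^2)))
}

#' Kam volume metric
#'
#' Rotation-invariant distance between two structures through their
#' uniform-density moments: `sqrt(r1^2 + lambda r2^2)` where `r1`, `r2` are
#' the discrete weighted norms of the first- and second-moment differences.
#'
#' @param a,b [moment_pair()]s on the configuration's grid (uniform-density
#'   moments).
#' @param cfg a [metric_config()].
#' @return nonnegative scalar distance.
#' @export
d_volume <- function(a, b, cfg) {
  stopifnot(inherits(a, "moment_pair"), inherits(b, "moment_pair"))
  if (!same_grid(a$grid, cfg$grid) || !same_grid(b$grid, cfg$grid))
    stop("moment pairs are not on the configuration's grid")
  w <- moment_weights(cfg$grid)
  r1sq <- sum(w$w1 * abs(a$m1 - b$m1)^2)
  r2sq <- sum(w$w2 * abs(a$m2 - b$m2)^2)
  sqrt(r1sq + cfg$lambda * r2sq)
}

#' Kam image metric: distance between empirical moments and a structure
#'
#' Minimises the weighted moment residual over the admissible
#' viewing-density coefficients (normalisation fixed, realness folded in),
#' a linear least-squares problem solved by SVD; rank-deficient systems get
#' the minimum-norm solution and a condition-number note. The returned
#' distance is `sqrt(r1^2 + lambda r2^2)` at the optimum.
#'
#' @param emp empirical [moment_pair()] on `cfg$grid`.
#' @param design a [moment_design()] for the candidate structure, built
#'   with density bandlimit `cfg$P`.
#' @param cfg a [metric_config()].
#' @return object of class `kam_image_fit`: `distance`, `fitted_density`
#'   (a [viewing_density()]), `residuals` (`r1`, `r2`), `uniform_distance`
#'   (residual with the density pinned to uniform), `condition_number`,
#'   `normalized_distance` (distance divided by the norm of `emp`,
#'   diagnostic only).
#' @export
d_image <- function(emp, design, cfg) {
  stopifnot(inherits(emp, "moment_pair"), inherits(design, "moment_design"))
  if (!same_grid(emp$grid, cfg$grid) || !same_grid(design$grid, cfg$grid))
    stop("empirical moments and design are not on the configuration's grid")
  if (design$P != cfg$P)
    stop("design density bandlimit does not match the configuration")
  w <- moment_weights(cfg$grid)
  sw1 <- sqrt(w$w1)
  sw2 <- sqrt(cfg$lambda) * sqrt(as.vector(w$w2))
  y1 <- (emp$m1 - design$m1_0) * sw1
  y2 <- (as.vector(emp$m2) - as.vector(design$m2_0)) * sw2
  A1 <- design$L1 * sw1
  A2 <- design$L2 * sw2
  ## real stacking: b is real, data complex
  A <- rbind(Re(A1), Im(A1), Re(A2), Im(A2))
  y <- c(Re(y1), Im(y1), Re(y2), Im(y2))
  nb <- design$n_b
  if (nb == 0L) {
    b <- numeric(0)
    cond <- 1
  } else {
    sv <- svd(A)
    tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
    pos <- sv$d > tol
    cond <- if (all(pos)) sv$d[1L] / sv$d[nb] else Inf
    if (!all(pos))
      message("d_image: rank-deficient design (cond = Inf); using minimum-norm solution")
    b <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    b <- drop(b)
  }
  fit1 <- if (nb) drop(A1 %*% b) else 0
  fit2 <- if (nb) drop(A2 %*% b) else 0
  r1 <- sqrt(sum(abs(y1 - fit1)^2))
  r2sq_w <- sum(abs(y2 - fit2)^2)              # already includes lambda
  dist <- sqrt(r1^2 + r2sq_w)
  u1 <- sqrt(sum(abs(y1)^2)); u2 <- sqrt(sum(abs(y2)^2))
  nrm <- metric_norms(emp, cfg)
  denom <- sqrt(nrm[["m1"]]^2 + cfg$lambda * nrm[["m2"]]^2)
  structure(list(
    distance = dist,
    fitted_density = vector_to_density(b, design$P),
    residuals = c(m1 = r1,
                  m2 = if (cfg$lambda > 0) sqrt(r2sq_w / cfg$lambda) else sqrt(sum(abs(y2 - fit2)^2))),
    uniform_distance = sqrt(u1^2 + u2^2),
    condition_number = cond,
    coefficients = b,
    normalized_distance = if (denom > 0) dist / denom else NA_real_),
    class = "kam_image_fit")
}

#' @export
print.kam_image_fit <- function(x, ...) {
  cat(sprintf("<kam_image_fit> distance %.6g (uniform-density residual %.6g)\n",
              x$distance, x$uniform_distance))
  cat(sprintf("  residuals: m1 %.4g, m2 %.4g; condition number %.3g\n",
              x$residuals[["m1"]], x$residuals[["m2"]], x$condition_number))
  invisible(x)
}

#' @export
coef.kam_image_fit <- function(object, ...) object$coefficients
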