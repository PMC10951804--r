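## Empirical moments from particle image stacks.
##
## Each image's Fourier transform is evaluated directly on the polar grid
## by a precomputed nonuniform DFT matrix (exact for the pixel data; no
## gridding interpolation). Images are grouped by CTF; per-group moments
## are debiased (the white-noise contribution to the second moment is the
## known polar covariance sigma^2 E E^H of the transform) and the
## underlying moments are recovered by a per-entry weighted least squares
## across CTF groups, which never divides by CTF zeros:
##   m1(k)  = sum_g n_g H_g(k) m1_g(k)          / sum_g n_g H_g(k)^2
##   m2(..) = sum_g n_g H_g(k1) H_g(k2) m2_g(..) / sum_g n_g (H_g(k1) H_g(k2))^2.
## Accumulation is streaming: any chunking of the stack gives the same
## result.

## Nonuniform DFT matrix from centred pixels to the polar grid:
## E[(t, j), pix] = h^2 exp(-2 pi i k_j (cos phi_t, sin phi_t) . x_pix).
## Point index runs angle-fastest, matching an (n_phi x n_k) matrix per
## image. Cached per (grid, N, h).
polar_transform_matrix <- function(grid, n, voxel_size) {
  key <- sprintf("Epol:%d:%.10g:%d:%d:%.10g", n, voxel_size, grid$n_k,
                 grid$n_phi, grid$k_max)
  cache_get(key, function() {
    ax <- grid_axis(n, voxel_size)
    X <- as.matrix(expand.grid(x = ax, y = ax))
    kx <- as.numeric(outer(cos(grid$phi), grid$k))
    ky <- as.numeric(outer(sin(grid$phi), grid$k))
    K <- cbind(kx, ky)
    voxel_size^2 * exp(-2i * pi * (K %*% t(X)))
  })
}

## Mean circular-shifted noise covariance: the white-noise expectation of
## the raw second moment is sigma^2 * Gbar with
## Gbar[s, j1, j2] = (1/n_phi) sum_t (E E^H)[(t+s-1, j1), (t, j2)].
## Cached per (grid, N, h).
polar_noise_covariance <- function(grid, n, voxel_size) {
  key <- sprintf("Gbar:%d:%.10g:%d:%d:%.10g", n, voxel_size, grid$n_k,
                 grid$n_phi, grid$k_max)
  cache_get(key, function() {
    E <- polar_transform_matrix(grid, n, voxel_size)
    G <- E %*% Conj(t(E))
    np <- grid$n_phi; nk <- grid$n_k
    Gbar <- array(0i, c(np, nk, nk))
    for (s in seq_len(np)) {
      t2 <- seq_len(np)
      t1 <- ((t2 - 1L + s - 1L) %% np) + 1L
      for (j1 in seq_len(nk)) for (j2 in seq_len(nk)) {
        Gbar[s, j1, j2] <- mean(G[cbind((j1 - 1L) * np + t1, (j2 - 1L) * np + t2)])
      }
    }
    Gbar
  })
}

## Polar Fourier samples of a chunk of images: (n_phi * n_k) x n matrix.
polar_samples <- function(images, grid, voxel_size) {
  n <- dim(images)[1L]
  E <- polar_transform_matrix(grid, n, voxel_size)
  dim(images) <- c(n * n, dim(images)[3L])
  E %*% images
}

#' Estimate the per-pixel noise variance from image corners
#'
#' Uses pixels outside a given radius (the corner annulus beyond the
#' particle) across the whole stack.
#'
#' @param stack an [image_stack()] with images larger than 8 x 8.
#' @param corner_fraction radius threshold as a fraction of `N/2`; pixels
#'   at radius `>= corner_fraction * N/2` are treated as pure noise
#'   (default 1: outside the inscribed circle).
#' @return nonnegative scalar variance estimate (0 for an empty stack).
#' @export
estimate_noise_variance <- function(stack, corner_fraction = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$n_images == 0L) return(0)
  n <- stack$n
  stopifnot(n > 8L)
  ax <- seq_len(n) - 1 - n %/% 2
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  sel <- rr >= corner_fraction * n / 2
  px <- apply(stack$images, 3L, function(im) im[sel])
  max(0, stats::var(as.numeric(px)))
}

#' Empirical moments of an image stack
#'
#' Computes the first and second moments of the images' polar Fourier
#' samples, corrected for CTF by per-group weighted least squares and
#' debiased for white noise of known per-pixel variance (see the module
#' notes above). Deterministic and streaming: the result does not depend on
#' `chunk_size`.
#'
#' @param stack an [image_stack()]; `stack$ctf_assignment` indexes
#'   `ctf_bank` (all images form one trivial-CTF group if both are absent).
#' @param ctf_bank list of [ctf_params()], or `NULL` for no CTF.
#' @param noise_variance per-pixel white-noise variance used for
#'   second-moment debiasing (default 0 = clean images).
#' @param grid the [polar_grid()] to estimate on.
#' @param chunk_size images per accumulation block.
#' @return a [moment_pair()].
#' @export
empirical_moments <- function(stack, ctf_bank = NULL, noise_variance = 0,
                              grid, chunk_size = 512L) {
  stopifnot(inherits(stack, "image_stack"), noise_variance >= 0)
  if (stack$n_images < 1L) stop("empty image stack")
  np <- grid$n_phi; nk <- grid$n_k
  assign <- stack$ctf_assignment
  if (is.null(ctf_bank) || length(ctf_bank) == 0L) {
    assign <- rep(1L, stack$n_images)
    Hk <- matrix(1, nk, 1L)
  } else {
    if (is.null(assign)) stop("stack has no CTF assignment for the given bank")
    if (any(assign < 1L | assign > length(ctf_bank)))
      stop("CTF assignment indexes outside the bank")
    Hk <- vapply(ctf_bank, function(ct) eval_ctf(ct, grid$k), numeric(nk))
  }
  groups <- sort(unique(assign))
  ng_tot <- length(groups)
  m1_g <- matrix(0i, nk, ng_tot)
  m2_g <- vector("list", ng_tot)
  for (gi in seq_len(ng_tot)) m2_g[[gi]] <- array(0i, c(np, nk, nk))
  counts <- integer(ng_tot)
  idx_by_g <- split(seq_len(stack$n_images), match(assign, groups))
  for (gi in seq_len(ng_tot)) {
    ids <- idx_by_g[[gi]]
    counts[gi] <- length(ids)
    for (start in seq(1L, length(ids), by = chunk_size)) {
      sel <- ids[start:min(start + chunk_size - 1L, length(ids))]
      P <- polar_samples(stack$images[, , sel, drop = FALSE], grid,
                         stack$pixel_size)
      nc <- length(sel)
      dim(P) <- c(np, nk, nc)
      m1_g[, gi] <- m1_g[, gi] + colSums(aperm(P, c(1L, 3L, 2L)), dims = 2L)
      ## angular FFT per (radius, image), then cross-spectra
      Pm <- P; dim(Pm) <- c(np, nk * nc)
      Fh <- stats::mvfft(Pm)
      dim(Fh) <- c(np, nk, nc)
      for (j2 in seq_len(nk)) {
        B2c <- Conj(matrix(Fh[, j2, ], np, nc))
        for (j1 in seq_len(nk)) {
          cs <- rowSums(matrix(Fh[, j1, ], np, nc) * B2c)
          m2_g[[gi]][, j1, j2] <- m2_g[[gi]][, j1, j2] +
            stats::fft(cs, inverse = TRUE) / np^2
        }
      }
    }
  }
  for (gi in seq_len(ng_tot)) {
    m1_g[, gi] <- m1_g[, gi] / (np * counts[gi])
    m2_g[[gi]] <- m2_g[[gi]] / counts[gi]
  }
  ## debias each group's second moment by the white-noise polar covariance
  if (noise_variance > 0) {
    Gbar <- polar_noise_covariance(grid, stack$n, stack$pixel_size)
    for (gi in seq_len(ng_tot)) m2_g[[gi]] <- m2_g[[gi]] - noise_variance * Gbar
  }
  ## CTF correction: per-entry weighted least squares across groups
  Hg <- Hk[, groups, drop = FALSE]              # nk x ng
  num1 <- rowSums(sweep(m1_g, 2L, counts, "*") * Hg)
  den1 <- rowSums(sweep(Hg^2, 2L, counts, "*"))
  m1 <- num1 / den1
  num2 <- array(0i, c(np, nk, nk)); den2 <- array(0, c(np, nk, nk))
  for (gi in seq_len(ng_tot)) {
    HH <- outer(Hg[, gi], Hg[, gi])             # H(k1) H(k2)
    HHs <- aperm(array(HH, c(nk, nk, np)), c(3L, 1L, 2L))
    num2 <- num2 + counts[gi] * HHs * m2_g[[gi]]
    den2 <- den2 + counts[gi] * HHs^2
  }
  m2 <- num2 / den2
  moment_pair(m1, m2, grid)
}

#' Downsample, centre and mask an image stack
#'
#' Fourier-crop downsampling to `target_size` (pixel size rescaled by
#' `N / N'`), optional phase-ramp centering by per-image shifts, and a
#' circular binary mask of radius `mask_radius_fraction * N'/2` pixels.
#'
#' @param stack an [image_stack()].
#' @param target_size new side length `N' <= N`.
#' @param mask_radius_fraction mask radius as a fraction of the half-side
#'   (in `(0, 1]`).
#' @param shifts optional `n x 2` matrix of translations in angstrom; each
#'   image is shifted by `-shift` (i.e. the deposited shift is undone).
#'   Defaults to `stack$shifts` when present.
#' @return a new [image_stack()].
#' @export
preprocess_stack <- function(stack, target_size = stack$n,
                             mask_radius_fraction = 1, shifts = stack$shifts) {
  stopifnot(inherits(stack, "image_stack"),
            mask_radius_fraction > 0, mask_radius_fraction <= 1)
  n <- stack$n; np <- as.integer(target_size)
  if (np > n) stop("cannot upsample: target_size exceeds the stack size")
  half <- n %/% 2L; halfp <- np %/% 2L
  keep <- (half - halfp + 1L):(half + halfp)    # centred crop indices
  new_pix <- stack$pixel_size * n / np
  out <- array(0, c(np, np, stack$n_images))
  ## frequency axes (centred order) for the phase ramp
  qx <- (seq_len(n) - 1L - half) / (n * stack$pixel_size)
  for (i in seq_len(stack$n_images)) {
    Fc <- image_to_freq_grid(stack$images[, , i], stack$pixel_size)
    if (!is.null(shifts)) {
      ph <- exp(2i * pi * (outer(qx * shifts[i, 1L], rep(1, n)) +
                           outer(rep(1, n), qx * shifts[i, 2L])))
      Fc <- Fc * ph
    }
    Fcc <- Fc[keep, keep]
    out[, , i] <- freq_grid_to_image(Fcc, new_pix)
  }
  ax <- seq_len(np) - 1 - halfp
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  mask <- rr <= mask_radius_fraction * np / 2
  for (i in seq_len(stack$n_images)) out[, , i] <- out[, , i] * mask
  image_stack(out, new_pix, ctf_assignment = stack$ctf_assignment)
}

#' Multiplicative scale between two second moments
#'
#' Closed-form least-squares scalar `c` minimising the weighted deviation
#' between the diagonal entries (`k1 = k2`, `dphi = 0`) of `c * query$m2`
#' and `reference$m2`; `c` multiplies the SECOND moment (the corresponding
#' volume scale is `sqrt(c)`, which is what the first moment picks up under
#' [scale_moments()]).
#'
#' @param reference,query [moment_pair()]s on one grid.
#' @return positive scalar `c`.
#' @export
fit_moment_scale <- function(reference, query) {
  stopifnot(inherits(reference, "moment_pair"), inherits(query, "moment_pair"),
            same_grid(reference$grid, query$grid))
  g <- reference$grid
  jj <- cbind(1L, seq_len(g$n_k), seq_len(g$n_k))
  qd <- query$m2[jj]; rd <- reference$m2[jj]
  w <- (g$k * g$w_k)^2
  den <- sum(w * abs(qd)^2)
  if (den <= 0) stop("degenerate query second moment (zero diagonal)")
  sum(w * Re(Conj(qd) * rd)) / den
}

#' Rescale a moment pair by a second-moment scale factor
#' @param m a [moment_pair()].
#' @param c2 positive scale applied to `m2`; `m1` is scaled by `sqrt(c2)`.
#' @return the rescaled [moment_pair()].
#' @export
scale_moments <- function(m, c2) {
  stopifnot(c2 > 0)
  moment_pair(m$m1 * sqrt(c2), m$m2 * c2, m$grid)
}
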