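## Cubic voxel volumes and atomic-model voxelisation.

#' Construct a voxel volume
#'
#' A `volume_grid` is a real scalar field (electrostatic potential) sampled
#' on a cubic `N x N x N` grid with a physical voxel size. The grid centre
#' (origin of the physical coordinate system) sits at voxel index
#' `N/2 + 1` along each axis, matching the usual FFT-centred convention.
#'
#' @param values numeric `N x N x N` array, finite everywhere.
#' @param voxel_size voxel edge length in angstrom (> 0).
#' @return object of class `volume_grid` with fields `values`, `voxel_size`,
#'   `n`, and `side_length = n * voxel_size` (angstrom).
#' @export
volume_grid <- function(values, voxel_size) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L || d[1L] != d[2L] || d[1L] != d[3L])
    stop("volume must be a cubic N x N x N array")
  if (d[1L] < 2L) stop("volume grid must have N >= 2")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a positive finite scalar")
  if (!all(is.finite(values))) stop("volume values must be finite everywhere")
  structure(
    list(values = values, voxel_size = voxel_size, n = d[1L],
         side_length = d[1L] * voxel_size),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d^3 voxels, %.3g A/voxel (side %.4g A)\n",
              x$n, x$voxel_size, x$side_length))
  cat(sprintf("  values in [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Load a cubic volume from an MRC map
#'
#' @param path MRC file (mode 2 float or mode 1 int16).
#' @return a [volume_grid()] with voxel size taken from the header.
#' @export
load_volume <- function(path) {
  m <- read_mrc(path)
  d <- dim(m$data)
  if (d[1L] != d[2L] || d[1L] != d[3L])
    stop("unsupported non-cubic map (", paste(d, collapse = "x"), "): ", path)
  volume_grid(m$data, m$voxel_size)
}

#' Save a volume as an MRC map
#' @param v a [volume_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  write_mrc(v$values, path, v$voxel_size)
}

## Centred physical coordinates of voxel indices 1..n (angstrom).
grid_axis <- function(n, voxel_size) (seq_len(n) - 1 - n %/% 2) * voxel_size

## ---- atomic models ----------------------------------------------------

## Isotropic Gaussian scattering approximation per element: amplitude
## proportional to atomic number, width a fixed per-element RMS radius
## (angstrom). Deliberately simple and swappable via the `table` argument of
## atomic_model_to_volume().
default_form_factors <- function() {
  data.frame(
    element = c("H", "C", "N", "O", "P", "S", "FE", "MG", "ZN", "CA", "MN", "NA", "K", "CL"),
    weight  = c(1, 6, 7, 8, 15, 16, 26, 12, 30, 20, 25, 11, 19, 17),
    sigma   = c(0.6, 0.9, 0.9, 0.9, 1.1, 1.1, 1.2, 1.0, 1.2, 1.1, 1.2, 1.0, 1.1, 1.1),
    stringsAsFactors = FALSE)
}

#' Construct an atomic model
#' @param element character vector of element symbols.
#' @param xyz numeric `n x 3` matrix of coordinates (angstrom).
#' @param occupancy per-atom occupancies (default 1).
#' @param b_factor optional per-atom B-factors (carried, not used).
#' @return object of class `atomic_model`.
#' @export
atomic_model <- function(element, xyz, occupancy = NULL, b_factor = NULL) {
  xyz <- rbind(xyz)
  stopifnot(ncol(xyz) == 3L, nrow(xyz) == length(element), all(is.finite(xyz)))
  known <- default_form_factors()$element
  el <- toupper(trimws(element))
  if (!all(el %in% known))
    stop("unknown element symbol(s): ", paste(unique(el[!el %in% known]), collapse = ", "))
  if (is.null(occupancy)) occupancy <- rep(1, length(el))
  structure(list(element = el, xyz = xyz, occupancy = occupancy,
                 b_factor = b_factor), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms (%s)\n", nrow(x$xyz),
              paste(names(sort(table(x$element), decreasing = TRUE))[1:min(4, length(unique(x$element)))],
                    collapse = ", ")))
  invisible(x)
}

#' Read an atomic model from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb`: keeps ATOM/HETATM records, resolves
#' alternate locations by highest occupancy, and drops waters unless asked.
#'
#' @param path PDB file.
#' @param include_waters keep HOH/WAT residues (default `FALSE`).
#' @return an [atomic_model()].
#' @export
read_atomic_model <- function(path, include_waters = FALSE) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (!include_waters) at <- at[!at$resid %in% c("HOH", "WAT", "DOD"), , drop = FALSE]
  ## altloc: keep the highest-occupancy alternative per (chain, resno, atom name)
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key),
                        function(i) i[which.max(at$o[i])]), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  el <- toupper(trimws(at$elesy))
  el[el == ""] <- substr(trimws(at$elety[el == ""]), 1, 1)
  known <- default_form_factors()$element
  at <- at[el %in% known, , drop = FALSE]
  el <- el[el %in% known]
  atomic_model(el, cbind(at$x, at$y, at$z), occupancy = at$o)
}

#' Voxelise an atomic model into a potential map
#'
#' Each atom contributes an isotropic Gaussian
#' `w * exp(-|x - x_atom|^2 / (2 sigma^2))` with an element-dependent weight
#' `w` (proportional to atomic number, times occupancy) and width `sigma`
#' from a small per-element table. The model is first centred at its
#' (weight-weighted) centre of mass.
#'
#' @param model an [atomic_model()].
#' @param n grid size (voxels per side).
#' @param voxel_size angstrom per voxel.
#' @param table form-factor table (data.frame with `element`, `weight`,
#'   `sigma`); defaults to a tabulated set.
#' @return a [volume_grid()].
#' @export
atomic_model_to_volume <- function(model, n, voxel_size,
                                   table = default_form_factors()) {
  stopifnot(inherits(model, "atomic_model"))
  ff <- table[match(model$element, table$element), ]
  w <- ff$weight * model$occupancy
  com <- colSums(model$xyz * w) / sum(w)
  xyz <- sweep(model$xyz, 2L, com)
  half <- n * voxel_size / 2
  out_of_bounds <- which(apply(abs(xyz), 1L, max) >= half)
  if (length(out_of_bounds))
    stop("atom(s) outside grid after centering: ",
         paste(utils::head(out_of_bounds, 5L), collapse = ", "),
         if (length(out_of_bounds) > 5L) " ..." else "")
  ax <- grid_axis(n, voxel_size)
  vol <- array(0, c(n, n, n))
  for (a in seq_along(w)) {
    s <- ff$sigma[a]
    ## only voxels within 5 sigma matter
    rng <- lapply(1:3, function(d) which(abs(ax - xyz[a, d]) <= 5 * s))
    if (any(lengths(rng) == 0L)) next
    gx <- exp(-(ax[rng[[1L]]] - xyz[a, 1L])^2 / (2 * s * s))
    gy <- exp(-(ax[rng[[2L]]] - xyz[a, 2L])^2 / (2 * s * s))
    gz <- exp(-(ax[rng[[3L]]] - xyz[a, 3L])^2 / (2 * s * s))
    vol[rng[[1L]], rng[[2L]], rng[[3L]]] <-
      vol[rng[[1L]], rng[[2L]], rng[[3L]]] +
      w[a] * (gx %o% gy %o% gz)
  }
  volume_grid(vol, voxel_size)
}
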