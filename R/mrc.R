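## Minimal MRC2014 I/O (mode 2, little-endian). Covers cubic volumes and
## image stacks, which is all the package reads or writes; no installed R
## package handles the format.

mrc_header_template <- function(nx, ny, nz, voxel_size, is_stack = FALSE) {
  list(
    dims = c(nx, ny, nz),
    mode = 2L,
    nstart = c(0L, 0L, 0L),
    mgrid = c(nx, ny, if (is_stack) 1L else nz),
    cella = voxel_size * c(nx, ny, if (is_stack) 1L else nz),
    cellb = c(90, 90, 90),
    mapcrs = c(1L, 2L, 3L),
    ispg = if (is_stack) 0L else 1L
  )
}

#' Read an MRC file
#'
#' Supports MRC/MRC2014 mode 2 (32-bit float) and mode 1 (16-bit signed int)
#' files with axis order X, Y, Z. Returns the raw data array plus the voxel
#' size from the header; use [load_volume()] for validated cubic volumes and
#' [read_image_stack()] for particle stacks.
#'
#' @param path path to an `.mrc`/`.mrcs` file.
#' @return list with `data` (3D array, `nx x ny x nz`), `voxel_size`
#'   (angstrom, from `cella/mx`) and `nz`.
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("MRC file not found: ", path)
  if (file.size(path) < 1024) stop("malformed MRC file (truncated header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  mode <- readBin(con, "integer", 1, size = 4, endian = "little")
  readBin(con, "integer", 3, size = 4, endian = "little")       # nstart
  mgrid <- readBin(con, "integer", 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")       # cellb
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  if (any(dims <= 0L) || any(dims > 1e5))
    stop("malformed MRC header (bad dimensions): ", path)
  if (!mode %in% c(1L, 2L)) stop("unsupported MRC mode ", mode, " in ", path)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order in ", path)
  seek(con, 23L * 4L)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  n <- prod(dims)
  need <- 1024 + nsymbt + n * (if (mode == 2L) 4 else 2)
  if (file.size(path) < need)
    stop("malformed MRC file (data shorter than header promises): ", path)
  seek(con, 1024 + nsymbt)
  vals <- if (mode == 2L) {
    readBin(con, "numeric", n, size = 4, endian = "little")
  } else {
    as.numeric(readBin(con, "integer", n, size = 2, endian = "little"))
  }
  vox <- if (mgrid[1L] > 0L && cella[1L] > 0) cella[1L] / mgrid[1L] else 1
  list(data = array(vals, dims), voxel_size = vox, nz = dims[3L])
}

#' Write an MRC file (mode 2)
#'
#' @param data 3D numeric array (`nx x ny x nz`; a stack stores images along
#'   the third axis).
#' @param path output path.
#' @param voxel_size pixel/voxel size in angstrom.
#' @param is_stack logical; set the spacegroup/`mz` fields for an image
#'   stack rather than a volume.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, voxel_size, is_stack = FALSE) {
  stopifnot(length(dim(data)) == 3L, is.finite(voxel_size), voxel_size > 0)
  d <- dim(data)
  h <- mrc_header_template(d[1L], d[2L], d[3L], voxel_size, is_stack)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(h$dims); wi(h$mode); wi(h$nstart); wi(h$mgrid)
  wf(h$cella); wf(h$cellb); wi(h$mapcrs)
  wf(c(min(data), max(data), mean(data)))                       # dmin/dmax/dmean
  wi(h$ispg); wi(0L)                                            # nsymbt
  wi(rep(0L, 25L))                                              # extra
  wf(c(0, 0, 0))                                                # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)              # machst LE
  wf(stats::sd(as.numeric(data)))                               # rms
  wi(0L)                                                        # nlabl
  writeBin(raw(800L), con)                                      # labels
  wf(as.numeric(data))
  invisible(path)
}
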