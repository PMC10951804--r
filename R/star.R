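## Minimal RELION-style STAR I/O: named data blocks with loop_ tables.
## Covers the sidecar metadata written next to simulated stacks and plain
## CTF parameter tables; not a general STAR parser.

#' Write data frames as STAR blocks
#' @param blocks named list of data.frames; each becomes `data_<name>` with
#'   a `loop_` table of `_rln`-prefixed (or as-given) column names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_star <- function(blocks, path) {
  stopifnot(is.list(blocks), length(names(blocks)) == length(blocks))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(blocks)) {
    df <- blocks[[nm]]
    writeLines(c("", paste0("data_", nm), "", "loop_"), con)
    cols <- names(df)
    writeLines(sprintf("%s #%d", ifelse(startsWith(cols, "_"), cols,
                                        paste0("_", cols)), seq_along(cols)), con)
    lines <- do.call(paste, c(lapply(df, function(x)
      if (is.numeric(x)) sprintf("%.8g", x) else as.character(x)),
      list(sep = "  ")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read STAR blocks into data frames
#' @param path STAR file written by [write_star()] or RELION-style tools
#'   (loop_ tables only).
#' @return named list of data.frames; numeric-looking columns are converted.
#' @export
read_star <- function(path) {
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "data_")) {
      block <- substring(lines[i], 6L)
      i <- i + 1L
      while (i <= length(lines) && lines[i] != "loop_") i <- i + 1L
      i <- i + 1L
      cols <- character(0)
      while (i <= length(lines) && startsWith(lines[i], "_")) {
        cols <- c(cols, sub("\\s+#\\d+$", "", lines[i]))
        i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines) && nzchar(lines[i]) &&
             !startsWith(lines[i], "data_")) {
        rows[[length(rows) + 1L]] <- strsplit(lines[i], "\\s+")[[1L]]
        i <- i + 1L
      }
      if (length(rows)) {
        m <- do.call(rbind, rows)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- sub("^_", "", cols)
        for (j in seq_along(df)) {
          num <- suppressWarnings(as.numeric(df[[j]]))
          if (!anyNA(num)) df[[j]] <- num
        }
        out[[block]] <- df
      }
    } else i <- i + 1L
  }
  out
}

#' Write an image stack as MRCS with a STAR sidecar
#'
#' The sidecar records per-image ZYZ Euler angles (degrees, RELION
#' `AngleRot/AngleTilt/AnglePsi` order), the CTF assignment and defocus,
#' and the simulation seed, so external tools can consume the fixture.
#'
#' @param stack an [image_stack()].
#' @param path output `.mrcs` path; the sidecar is `<path>.star`.
#' @param rotations optional `3 x 3 x n` ground-truth rotations.
#' @param ctf_bank optional list of [ctf_params()].
#' @param seed optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, rotations = NULL, ctf_bank = NULL,
                              seed = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  write_mrc(stack$images, path, stack$pixel_size, is_stack = TRUE)
  blocks <- list()
  df <- data.frame(rlnImageName = sprintf("%06d@%s", seq_len(stack$n_images),
                                          basename(path)))
  if (!is.null(rotations)) {
    ang <- t(apply(rotations, 3L, euler_zyz)) * 180 / pi
    df$rlnAngleRot <- ang[, 1L]; df$rlnAngleTilt <- ang[, 2L]
    df$rlnAnglePsi <- ang[, 3L]
  }
  if (!is.null(stack$ctf_assignment) && length(ctf_bank)) {
    df$rlnOpticsGroup <- stack$ctf_assignment
    z <- vapply(ctf_bank, function(ct) ct$defocus, numeric(1L))
    df$rlnDefocusU <- z[stack$ctf_assignment]
    df$rlnDefocusV <- z[stack$ctf_assignment]
  }
  blocks$particles <- df
  if (length(ctf_bank)) {
    blocks$optics <- data.frame(
      rlnOpticsGroup = seq_along(ctf_bank),
      rlnDefocusU = vapply(ctf_bank, function(ct) ct$defocus, numeric(1L)),
      rlnSphericalAberration = vapply(ctf_bank, function(ct) ct$cs, numeric(1L)),
      rlnVoltage = vapply(ctf_bank, function(ct) ct$voltage, numeric(1L)),
      rlnAmplitudeContrast = vapply(ctf_bank, function(ct) ct$amp_contrast,
                                    numeric(1L)),
      rlnImagePixelSize = vapply(ctf_bank, function(ct) ct$pixel_size,
                                 numeric(1L)))
  }
  if (!is.null(seed))
    blocks$simulation <- data.frame(kamSeed = as.integer(seed))
  write_star(blocks, paste0(path, ".star"))
  invisible(path)
}

#' Read an MRCS particle stack (with optional STAR sidecar)
#'
#' @param path `.mrcs` file; if `<path>.star` exists, CTF parameters and
#'   assignment are restored from it (defocus U/V are averaged — only
#'   radial CTFs are modelled).
#' @return an [image_stack()]; any recovered CTF bank is attached as
#'   attribute `ctf_bank`.
#' @export
read_image_stack <- function(path) {
  m <- read_mrc(path)
  st <- image_stack(m$data, m$voxel_size)
  side <- paste0(path, ".star")
  if (file.exists(side)) {
    blocks <- read_star(side)
    if (!is.null(blocks$optics)) {
      o <- blocks$optics
      defoc <- if (!is.null(o$rlnDefocusV))
        (o$rlnDefocusU + o$rlnDefocusV) / 2 else o$rlnDefocusU
      bank <- lapply(seq_len(nrow(o)), function(i)
        ctf_params(defoc[i], cs = o$rlnSphericalAberration[i],
                   voltage = o$rlnVoltage[i],
                   amp_contrast = o$rlnAmplitudeContrast[i],
                   pixel_size = if (!is.null(o$rlnImagePixelSize))
                     o$rlnImagePixelSize[i] else m$voxel_size))
      attr(st, "ctf_bank") <- bank
    }
    if (!is.null(blocks$particles$rlnOpticsGroup))
      st$ctf_assignment <- as.integer(blocks$particles$rlnOpticsGroup)
  }
  st
}

#' Read a CTF bank from a plain CSV
#'
#' Columns `defocus` (angstrom; or `defocus_u`/`defocus_v`, averaged),
#' optional `cs` (mm), `voltage` (kV), `amp_contrast`, `pixel_size`.
#'
#' @param path CSV file.
#' @param pixel_size fallback pixel size when the file has none.
#' @return list of [ctf_params()].
#' @export
read_ctf_csv <- function(path, pixel_size = 1) {
  df <- utils::read.csv(path)
  defoc <- if ("defocus" %in% names(df)) df$defocus
           else (df$defocus_u + df$defocus_v) / 2
  lapply(seq_len(nrow(df)), function(i)
    ctf_params(defoc[i],
               cs = if ("cs" %in% names(df)) df$cs[i] else 2.0,
               voltage = if ("voltage" %in% names(df)) df$voltage[i] else 300,
               amp_contrast = if ("amp_contrast" %in% names(df))
                 df$amp_contrast[i] else 0.07,
               pixel_size = if ("pixel_size" %in% names(df))
                 df$pixel_size[i] else pixel_size))
}
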