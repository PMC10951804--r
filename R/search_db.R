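## Moment database over a structure library and nearest-neighbour search.
##
## Each entry stores a structure's uniform-density moments and the design
## operators of the image metric, precomputed once; volume and image
## queries are then a handful of small linear-algebra operations per entry,
## which is what makes the search scalable to large libraries.

#' Build a moment database over a structure library
#'
#' For every `(id, volume)` pair: harmonic expansion, uniform-density
#' moments, and the density-elimination design operators. Entries that fail
#' to expand are skipped with a warning and recorded in `skipped`.
#'
#' @param volumes named list of [volume_grid()]s and/or [atomic_model()]s
#'   (models are voxelised with `n`, `voxel_size` of the configuration
#'   grid geometry inferred from the first volume, or 32/2 by default).
#' @param cfg a [metric_config()].
#' @param voxel_n,voxel_size geometry used to voxelise atomic models.
#' @return object of class `kam_db` with `entries` (list of `id`,
#'   `moments`, `design`, `meta`), `cfg`, `skipped`.
#' @export
build_db <- function(volumes, cfg, voxel_n = 32L, voxel_size = 2) {
  stopifnot(length(volumes) >= 1L)
  ids <- names(volumes)
  if (is.null(ids) || any(!nzchar(ids))) stop("volumes must be a named list")
  if (anyDuplicated(ids)) stop("duplicate structure ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  entries <- list()
  skipped <- character(0)
  for (id in ids) {
    v <- volumes[[id]]
    meta <- list(source = NA_character_, atom_count = NA_integer_)
    res <- tryCatch({
      if (inherits(v, "atomic_model")) {
        meta$atom_count <- nrow(v$xyz)
        v <- atomic_model_to_volume(v, voxel_n, voxel_size)
      }
      stopifnot(inherits(v, "volume_grid"))
      e <- expand_volume(v, cfg$L, cfg$grid$k)
      list(id = id,
           moments = analytic_moments_uniform(e, cfg$grid),
           design = moment_design(e, cfg$grid, cfg$P),
           meta = meta)
    }, error = function(err) {
      warning("skipping entry '", id, "': ", conditionMessage(err))
      NULL
    })
    if (is.null(res)) skipped <- c(skipped, id) else entries[[id]] <- res
  }
  if (!length(entries)) stop("no database entries could be built")
  structure(list(entries = entries, cfg = cfg, skipped = skipped),
            class = "kam_db")
}

#' @export
print.kam_db <- function(x, ...) {
  cat(sprintf("<kam_db> %d entries (%d skipped), L = %d, P = %d, grid %d x %d\n",
              length(x$entries), length(x$skipped), x$cfg$L, x$cfg$P,
              x$cfg$grid$n_k, x$cfg$grid$n_phi))
  invisible(x)
}

#' Append entries to an existing database
#' @param db a [kam_db()] from [build_db()].
#' @param volumes named list of additional volumes/models.
#' @return the extended `kam_db`.
#' @export
db_append <- function(db, volumes) {
  stopifnot(inherits(db, "kam_db"))
  add <- build_db(volumes, db$cfg)
  dup <- intersect(names(add$entries), names(db$entries))
  if (length(dup)) stop("duplicate structure ids: ", paste(dup, collapse = ", "))
  db$entries <- c(db$entries, add$entries)
  db$skipped <- c(db$skipped, add$skipped)
  db
}

#' Persist a moment database to a directory
#'
#' One directory per database: a JSON manifest (grid, bandlimits, lambda,
#' package version, skip list) plus one moment file per entry, so the
#' database is appendable and a config change invalidates the cache
#' visibly.
#'
#' @param db a `kam_db`.
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "kam_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- db$cfg$grid
  manifest <- list(
    format = "kam_db/1",
    version = tryCatch(as.character(utils::packageVersion("kammetrics")),
                       error = function(e) "unknown"),
    L = db$cfg$L, P = db$cfg$P, lambda = db$cfg$lambda,
    grid = list(n_k = g$n_k, n_phi = g$n_phi, k_max = g$k_max, radial = g$radial),
    entries = names(db$entries), skipped = db$skipped)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (id in names(db$entries))
    saveRDS(db$entries[[id]], file.path(path, paste0("entry_", id, ".rds")))
  invisible(path)
}

#' Load a moment database from a directory
#' @param path directory written by [save_db()].
#' @return a `kam_db`.
#' @export
load_db <- function(path) {
  mf <- jsonlite::fromJSON(file.path(path, "manifest.json"))
  stopifnot(identical(mf$format, "kam_db/1"))
  grid <- polar_grid(mf$grid$n_k, mf$grid$n_phi, mf$grid$k_max, mf$grid$radial)
  cfg <- metric_config(grid, L = mf$L, P = mf$P, lambda = mf$lambda)
  entries <- lapply(mf$entries, function(id)
    readRDS(file.path(path, paste0("entry_", id, ".rds"))))
  names(entries) <- mf$entries
  structure(list(entries = entries, cfg = cfg,
                 skipped = as.character(mf$skipped)),
            class = "kam_db")
}

ranking_result <- function(tab, query_id, fits = NULL) {
  ## sort ascending by distance, ties broken lexicographically by id
  ord <- order(tab$distance, tab$id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(ranking = tab, query = query_id,
                 fits = if (is.null(fits)) NULL else fits[tab$id]),
            class = "kam_ranking")
}

#' @export
print.kam_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<kam_ranking> query '%s', %d candidates\n", x$query,
              nrow(x$ranking)))
  print(utils::head(x$ranking, n))
  invisible(x)
}

#' Rank database structures against a query volume's moments
#'
#' All-pairs Kam volume metric against the database, ascending.
#'
#' @param query a [moment_pair()] of uniform-density moments on the
#'   database grid.
#' @param db a `kam_db`.
#' @param query_id label for the result.
#' @return a `kam_ranking` with columns `id`, `distance`.
#' @export
rank_by_volume <- function(query, db, query_id = "query") {
  stopifnot(inherits(db, "kam_db"), inherits(query, "moment_pair"))
  if (!same_grid(query$grid, db$cfg$grid))
    stop("query moments are not on the database grid")
  d <- vapply(db$entries, function(en) d_volume(query, en$moments, db$cfg),
              numeric(1L))
  ranking_result(data.frame(id = names(db$entries), distance = unname(d),
                            stringsAsFactors = FALSE), query_id)
}

#' Rank database structures against empirical image moments
#'
#' Kam image metric per entry: the viewing density is eliminated by least
#' squares against each candidate's design; optionally, a per-candidate
#' multiplicative scale (matching second-moment diagonals, as used for
#' preprocessed maps with arbitrary intensity scale) is fitted first.
#'
#' @param emp empirical [moment_pair()] on the database grid.
#' @param db a `kam_db`.
#' @param scale_fit fit a per-candidate diagonal scale before the metric.
#' @param query_id label for the result.
#' @return a `kam_ranking` with columns `id`, `distance`, `uniform_distance`,
#'   plus the per-entry `kam_image_fit`s in `$fits`.
#' @export
rank_by_images <- function(emp, db, scale_fit = FALSE, query_id = "query") {
  stopifnot(inherits(db, "kam_db"), inherits(emp, "moment_pair"))
  if (!same_grid(emp$grid, db$cfg$grid))
    stop("empirical moments are not on the database grid")
  fits <- lapply(db$entries, function(en) {
    des <- en$design
    if (scale_fit) {
      c2 <- fit_moment_scale(emp, en$moments)   # scale candidate -> emp
      if (c2 > 0) {
        des$m1_0 <- des$m1_0 * sqrt(c2); des$L1 <- des$L1 * sqrt(c2)
        des$m2_0 <- des$m2_0 * c2;       des$L2 <- des$L2 * c2
      }
    }
    d_image(emp, des, db$cfg)
  })
  tab <- data.frame(id = names(db$entries),
                    distance = vapply(fits, function(f) f$distance, numeric(1L)),
                    uniform_distance = vapply(fits, function(f) f$uniform_distance,
                                              numeric(1L)),
                    stringsAsFactors = FALSE)
  ranking_result(tab, query_id, fits)
}

#' Write a ranking to CSV
#' @param x a `kam_ranking`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(x, path) {
  stopifnot(inherits(x, "kam_ranking"))
  tab <- cbind(query = x$query, x$ranking)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

## ---- NDCG --------------------------------------------------------------

#' Normalised discounted cumulative gain of a predicted ranking
#'
#' `DCG = sum_i gain(rel[pred_i]) / log2(i + 1)` over the predicted order,
#' divided by the DCG of the relevance-optimal order. Linear gain by
#' default; an exponential `2^rel - 1` variant is available.
#'
#' @param predicted character vector of ids in predicted order (best
#'   first), or a `kam_ranking`.
#' @param relevance named numeric vector of reference relevances (higher =
#'   more relevant); names must match the predicted ids.
#' @param gain `"linear"` or `"exp"`.
#' @return value in `[0, 1]` (1 for any relevance-optimal ordering).
#' @export
ndcg <- function(predicted, relevance, gain = c("linear", "exp")) {
  gain <- match.arg(gain)
  if (inherits(predicted, "kam_ranking")) predicted <- predicted$ranking$id
  if (is.null(names(relevance)) || !setequal(predicted, names(relevance)) ||
      length(predicted) != length(relevance))
    stop("relevance must be named by exactly the predicted ids")
  g <- function(r) if (gain == "linear") r else 2^r - 1
  disc <- 1 / log2(seq_along(predicted) + 1)
  dcg <- sum(g(relevance[predicted]) * disc)
  idcg <- sum(g(sort(relevance, decreasing = TRUE)) * disc)
  if (idcg == 0) return(1)
  dcg / idcg
}

#' Rank-based relevance scores from distances
#'
#' Converts distances to relevances by rank position: the closest id gets
#' relevance `n`, the farthest 1 (ties share the smaller relevance,
#' resolved lexicographically for determinism). The transform feeding
#' [ndcg()] is deliberately pluggable — pass any named scores instead.
#'
#' @param distances named numeric vector (smaller = more similar).
#' @return named numeric relevances.
#' @export
relevance_from_distances <- function(distances) {
  stopifnot(!is.null(names(distances)))
  ord <- order(distances, names(distances), method = "radix")
  rel <- numeric(length(distances))
  rel[ord] <- rev(seq_along(distances))
  names(rel) <- names(distances)
  rel
}
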