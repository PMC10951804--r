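# Database construction, retrieval, persistence and ranking agreement.
# A small shared library keeps these tests fast.

db_fix <- function() memo("db6", function() {
  lib <- make_phantom_library(6L, seed = 2L)
  list(lib = lib, db = build_db(lib, test_cfg()))
})

test_that("databases build, persist, append, and refuse duplicates", {
  fx <- db_fix()
  db <- fx$db
  expect_equal(length(db$entries), 6L)
  expect_length(db$skipped, 0L)
  td <- tempfile()
  save_db(db, td)
  db2 <- load_db(td)
  q <- db$entries[["ph03"]]$moments
  expect_equal(rank_by_volume(q, db2)$ranking, rank_by_volume(q, db)$ranking)
  # append and duplicate guard
  extra <- make_phantom_library(1L, seed = 77L)
  names(extra) <- "zz01"
  db3 <- db_append(db, extra)
  expect_equal(length(db3$entries), 7L)
  expect_error(db_append(db3, extra), "duplicate")
  expect_error(build_db(stats::setNames(fx$lib[1:2], c("a", "a")), test_cfg()),
               "duplicate")
  # a broken entry is skipped with a warning, not fatal
  bad <- c(fx$lib[1:2], list(broken = "not a volume"))
  expect_warning(db4 <- build_db(bad, test_cfg()), "skipping")
  expect_equal(db4$skipped, "broken")
  expect_equal(length(db4$entries), 2L)
})

test_that("self- and rotated-copy retrieval rank first with near-zero distance", {
  set.seed(60)
  fx <- db_fix(); db <- fx$db
  for (id in c("ph01", "ph04")) {
    rk <- rank_by_volume(db$entries[[id]]$moments, db, query_id = id)
    expect_equal(rk$ranking$id[1L], id)
    expect_lt(rk$ranking$distance[1L], 1e-10)
    expect_gt(rk$ranking$distance[2L], 1e-6)
  }
  # rotated copy
  R <- random_rotations(1L)[, , 1L]
  e5 <- expand_volume(fx$lib[["ph05"]], 8L, test_grid()$k)
  mrot <- analytic_moments_uniform(rotate_expansion(e5, R), test_grid())
  rk <- rank_by_volume(mrot, db)
  expect_equal(rk$ranking$id[1L], "ph05")
  expect_lt(rk$ranking$distance[1L], 1e-8 * rk$ranking$distance[2L])
  # a small perturbation of an entry's moments still retrieves it
  m3 <- db$entries[["ph03"]]$moments
  margin <- min(rank_by_volume(m3, db)$ranking$distance[-1L])
  pert <- moment_pair(m3$m1 * (1 + 1e-3), m3$m2 * (1 + 1e-3), m3$grid)
  expect_equal(rank_by_volume(pert, db)$ranking$id[1L], "ph03")
  expect_lt(d_volume(pert, m3, test_cfg()), 0.1 * margin)
  # ordering equals an independent sort of the distances
  rk2 <- rank_by_volume(pert, db)
  d <- vapply(db$entries, function(en) d_volume(pert, en$moments, test_cfg()),
              numeric(1L))
  expect_equal(rk2$ranking$id, names(sort(d)))
})

test_that("image queries retrieve the source structure and respect scale fitting", {
  fx <- db_fix(); db <- fx$db
  sim <- simulate_dataset(fx$lib[["ph02"]],
                          simulation_recipe(n_images = 400L,
                                            poses = random_vmf_mixture(seed = 8L),
                                            n_ctf = 0L, snr = Inf,
                                            seed = 61L, L = 8L))
  emp <- empirical_moments(sim$stack, NULL, 0, test_grid())
  rk <- rank_by_images(emp, db, query_id = "ph02-images")
  expect_equal(rk$ranking$id[1L], "ph02")
  expect_true(all(rk$ranking$distance <= rk$ranking$uniform_distance + 1e-9))
  # global intensity rescaling is absorbed by the scale fit
  a <- rank_by_images(emp, db, scale_fit = TRUE)
  b <- rank_by_images(scale_moments(emp, 7), db, scale_fit = TRUE)
  expect_identical(a$ranking$id, b$ranking$id)
  expect_equal(b$ranking$distance, 7 * a$ranking$distance, tolerance = 1e-5)
  # degenerate single-entry database
  db1 <- build_db(fx$lib["ph01"], test_cfg())
  expect_equal(rank_by_images(emp, db1)$ranking$id, "ph01")
  # rankings serialise
  p <- tempfile(fileext = ".csv")
  write_ranking(rk, p)
  expect_equal(utils::read.csv(p)$id, rk$ranking$id)
})

test_that("ndcg matches exhaustive enumeration and handles degenerate relevances", {
  rel <- c(a = 3, b = 2, c = 1)
  perms <- list(c("a", "b", "c"), c("a", "c", "b"), c("b", "a", "c"),
                c("b", "c", "a"), c("c", "a", "b"), c("c", "b", "a"))
  idcg <- sum(c(3, 2, 1) / log2(2:4))
  for (p in perms)
    expect_equal(ndcg(p, rel), sum(rel[p] / log2(2:4)) / idcg, tolerance = 1e-14)
  expect_equal(ndcg(c("a", "b", "c"), rel), 1)
  expect_equal(ndcg(c("c", "b", "a"), c(a = 1, b = 1, c = 1)), 1)
  expect_error(ndcg(c("a", "b"), rel), "ids")
  # exponential-gain variant agrees with its own enumeration
  expect_equal(ndcg(c("c", "b", "a"), rel, gain = "exp"),
               sum((2^rel[c("c", "b", "a")] - 1) / log2(2:4)) /
                 sum((2^c(3, 2, 1) - 1) / log2(2:4)))
  # rank-based relevances: closest id gets the highest score
  rel2 <- relevance_from_distances(c(x = 0.3, y = 0.1, z = 0.7))
  expect_equal(rel2, c(x = 2, y = 3, z = 1))
})

test_that("moment ranking agrees with a brute-force aligned Euclidean ranking", {
  set.seed(62)
  # small phantoms; the aligned Euclidean oracle scans a rotation sample
  lib <- make_phantom_library(6L, seed = 9L, grid_n = 24L, voxel_size = 2)
  cfg <- metric_config(default_polar_grid(24L, 2, L = 6L), L = 6L, P = 2L)
  moms <- lapply(lib, function(v)
    analytic_moments_uniform(expand_volume(v, 6L, cfg$grid$k), cfg$grid))
  ids <- names(lib)
  Rs <- random_rotations(40L)
  aligned_dist <- function(a, b) {
    best <- Inf
    for (i in seq_len(dim(Rs)[3L])) {
      br <- rotate_volume_trilinear(b, Rs[, , i])
      best <- min(best, sqrt(sum((a$values - br$values)^2)))
    }
    best
  }
  query <- "ph01"
  d_kam <- vapply(ids, function(j) d_volume(moms[[query]], moms[[j]], cfg),
                  numeric(1L))
  d_ali <- vapply(ids, function(j)
    if (j == query) 0 else aligned_dist(lib[[query]], lib[[j]]), numeric(1L))
  rel <- relevance_from_distances(d_ali)
  obs <- ndcg(names(sort(d_kam)), rel)
  # expectation under random orderings, by sampling permutations; the
  # moment ranking should sit near 1, well above that baseline
  rnd <- replicate(300L, ndcg(sample(ids), rel))
  expect_gt(obs, 0.95)
  expect_gt(obs - mean(rnd), 0.1)
})
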