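test_that("friction is the exact complement of favorability", {
  f <- matrix(c(0, 0.5, 0.8, 1), 2, 2)
  fr <- friction_surface(f)
  expect_equal(fr, 1 - f)
  expect_equal(fr[3], 0.2)        # at the patch threshold
  expect_true(all(fr + f == 1))
  # friction < 0.2 only where F > 0.8
  set.seed(5)
  f2 <- matrix(runif(100), 10, 10)
  fr2 <- friction_surface(f2)
  expect_true(all((fr2 < 0.2) == (f2 > 0.8)))
})

test_that("a single path accumulates mean-endpoint friction times distance", {
  fr <- matrix(0.5, 1, 3)
  src <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
  cs <- accumulate_cost(fr, src, neighborhood = "rook4")
  expect_equal(as.vector(cs$cost), c(0, 0.5, 1.0))
  # knight moves cannot help on a 1-row grid
  cs16 <- accumulate_cost(fr, src)
  expect_equal(cs$cost, cs16$cost)
  expect_true(all(cs$cost[src] == 0))
})

test_that("accumulated cost equals the brute-force graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(2024)
  sizes <- list(c(1, 3), c(4, 4), c(5, 8), c(12, 12), c(15, 15))
  for (sz in sizes) {
    for (rep in 1:3) {
      fr <- matrix(runif(sz[1] * sz[2]), sz[1], sz[2])
      if (rep == 3 && sz[1] * sz[2] >= 16) fr[sample(sz[1] * sz[2], 4)] <- NA
      src <- matrix(FALSE, sz[1], sz[2])
      cand <- which(!is.na(fr))
      src[sample(cand, min(2, length(cand)))] <- TRUE
      for (nb in c("knight16", "queen8", "rook4")) {
        got <- accumulate_cost(fr, src, neighborhood = nb)$cost
        want <- oracle_cost(fr, src, nb)
        expect_equal(got, want, tolerance = 1e-10)
      }
    }
  }
})

test_that("richer neighborhoods never increase cost; friction is monotone", {
  set.seed(71)
  fr <- matrix(runif(144), 12, 12)
  src <- matrix(FALSE, 12, 12); src[6, 6] <- TRUE
  c_rook <- accumulate_cost(fr, src, "rook4")$cost
  c_queen <- accumulate_cost(fr, src, "queen8")$cost
  c_knight <- accumulate_cost(fr, src, "knight16")$cost
  expect_true(all(c_knight <= c_queen + 1e-12))
  expect_true(all(c_queen <= c_rook + 1e-12))
  # uniformly higher friction never lowers any cost
  c_up <- accumulate_cost(fr + 0.2, src, "knight16")$cost
  expect_true(all(c_up >= c_knight - 1e-12))
})

test_that("NODATA isolates cells, which are flagged and zeroed", {
  fr <- matrix(0.5, 5, 5)
  fr[2, ] <- NA  # wall cutting row 1 off (knight moves jump 2 rows!)
  fr[3, ] <- NA  # second wall so not even knight moves cross
  src <- matrix(FALSE, 5, 5); src[5, 3] <- TRUE
  cs <- accumulate_cost(fr, src)
  expect_true(all(is.infinite(cs$cost[1, ])))
  expect_equal(cs$n_unreachable, 5)
  conn <- connectivity_from_cost(cs)
  expect_true(all(conn$connectivity[1, ] == 0))
  expect_error(accumulate_cost(fr, matrix(FALSE, 5, 5)), "no source")
})

test_that("connectivity rescaling pins 0.9 at min cost and 0 at max cost", {
  sc <- make_fragmented_scenario()
  f <- sc$truth$favorability
  ps <- detect_patches(f)
  cs <- accumulate_cost(friction_surface(f), ps)
  conn <- connectivity_from_cost(cs)
  mc <- !is.na(conn$connectivity) & !conn$source_mask
  expect_equal(conn$connectivity[which(cs$cost == cs$min_cost)[1]], 0.9)
  expect_equal(conn$connectivity[which(cs$cost == cs$max_cost)[1]], 0)
  expect_true(all(conn$connectivity[mc] >= 0 &
                    conn$connectivity[mc] <= 0.9))
  expect_true(all(conn$connectivity[conn$source_mask] == 1))
  # strictly decreasing in cost on matrix cells
  ord <- order(cs$cost[mc])
  expect_true(all(diff(conn$connectivity[mc][ord]) <= 1e-12))
})

test_that("a two-matrix-cell map rescales to exactly {0.9, 0}", {
  fr <- matrix(c(0, 0.5, 1), 1, 3)
  src <- matrix(c(TRUE, FALSE, FALSE), 1, 3)
  cs <- accumulate_cost(fr, src, "rook4")
  expect_equal(as.vector(cs$cost), c(0, 0.25, 1.0))
  conn <- connectivity_from_cost(cs)
  expect_equal(as.vector(conn$connectivity), c(1, 0.9, 0))
})

test_that("zero friction collapses to the degenerate rescale", {
  fr <- matrix(0, 4, 4)
  src <- matrix(FALSE, 4, 4); src[1, 1] <- TRUE
  cs <- accumulate_cost(fr, src)
  expect_true(all(cs$cost == 0))
  conn <- connectivity_from_cost(cs)
  expect_true(conn$degenerate)
  mc <- !conn$source_mask
  expect_true(all(conn$connectivity[mc] == 0.9))
})

test_that("binning yields the 18-level scale plus the patch class", {
  sc <- make_fragmented_scenario()
  f <- sc$truth$favorability
  ps <- detect_patches(f)
  conn <- bin_connectivity(connectivity_from_cost(
    accumulate_cost(friction_surface(f), ps)))
  lev <- conn$binned[!is.na(conn$binned)]
  expect_true(all(lev %in% 0:17))
  expect_true(all(is.na(conn$binned[conn$source_mask])))
  # <= 19 rendered classes: 18 matrix levels + the patch class
  expect_lte(length(unique(lev)) + 1, 19)
  # level arithmetic across the whole map
  m <- conn$connectivity
  mcells <- which(!is.na(m) & !conn$source_mask)
  expect_equal(conn$binned[mcells],
               pmin(as.integer(floor(m[mcells] / 0.05)), 17L))
})

test_that("bin levels hit the printed anchor values", {
  cm <- structure(list(
    connectivity = matrix(c(1, 0, 0.9, 0.23), 1, 4),
    source_mask = matrix(c(TRUE, FALSE, FALSE, FALSE), 1, 4),
    degenerate = FALSE, n_unreachable = 0L, binned = NULL),
    class = "connectivity_map")
  b <- bin_connectivity(cm)$binned
  expect_true(is.na(b[1]))          # patch cell: own class
  expect_identical(b[2], 0L)        # connectivity 0 -> level 0
  expect_identical(b[3], 17L)       # connectivity 0.9 -> 18th level
  expect_identical(b[4], 4L)        # floor(0.23 / 0.05)
})

test_that("inter-patch cost matrix is symmetric with zero diagonal", {
  f <- matrix(0.1, 7, 7)
  f[1:2, 1:2] <- 0.9
  f[6:7, 6:7] <- 0.9
  ps <- detect_patches(f)
  pm <- patch_cost_matrix(friction_surface(f), ps)
  expect_equal(dim(pm), c(2, 2))
  expect_equal(diag(pm), c(0, 0))
  expect_equal(pm[1, 2], pm[2, 1])
  expect_gt(pm[1, 2], 0)
})
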