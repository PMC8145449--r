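make_two_block_f <- function() {
  f <- matrix(0.1, 8, 8)
  f[2:4, 2:4] <- 0.85
  f[2:4, 7:8] <- 0   # keep an asymmetry
  f[6:8, 6:8] <- 0.85
  f
}

test_that("patch detection counts hand-checkable components", {
  expect_equal(detect_patches(matrix(0.9, 10, 10))$n_patches, 1)
  expect_equal(sum(detect_patches(matrix(0.9, 10, 10))$sizes), 100)
  f <- make_two_block_f()
  ps <- detect_patches(f, threshold = 0.8)
  expect_equal(ps$n_patches, 2)
  expect_equal(sort(ps$sizes), c(9, 9))
  expect_equal(detect_patches(matrix(0.5, 6, 6))$n_patches, 0)
})

test_that("queen and rook adjacency differ on diagonal contact", {
  f <- matrix(0.1, 4, 4)
  f[1:2, 1:2] <- 0.9
  f[3:4, 3:4] <- 0.9
  expect_equal(detect_patches(f, adjacency = "queen")$n_patches, 1)
  expect_equal(detect_patches(f, adjacency = "rook")$n_patches, 2)
})

test_that("labelling partitions the thresholded mask and matches igraph", {
  set.seed(99)
  for (i in 1:10) {
    f <- matrix(runif(15 * 12), 15, 12)
    f[sample(180, 10)] <- NA  # NODATA holes
    for (adj in c("queen", "rook")) {
      ps <- detect_patches(f, threshold = 0.6, adjacency = adj)
      mask <- !is.na(f) & f >= 0.6
      expect_equal(sum(ps$sizes), sum(mask))
      expect_true(all(sort(unique(ps$labels[ps$labels > 0])) ==
                        seq_len(ps$n_patches)))
      expect_equal(ps$n_patches, oracle_components(mask, adj))
      # every labelled cell is in the mask and vice versa
      expect_identical(ps$labels > 0, mask)
    }
  }
})

test_that("raising the threshold never grows the favorable area", {
  set.seed(123)
  f <- matrix(runif(400), 20, 20)
  areas <- vapply(seq(0.1, 0.9, by = 0.1),
                  function(t) sum(detect_patches(f, t)$sizes), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("occupancy labelling follows presence cells", {
  f <- make_two_block_f()
  land <- bare_landscape(8, 8)
  pres <- rep(0L, 64)
  patch1_cell <- which(f >= 0.8)[1]
  pres[patch1_cell] <- 1L
  occ <- species_occurrence(pres, land)
  ps <- label_occupancy(detect_patches(f), occ)
  lab1 <- ps$labels[patch1_cell]
  expect_true(ps$occupied[lab1])
  expect_false(all(ps$occupied))
  expect_equal(sum(ps$occupied), 1)
  # no presences anywhere: all patches empty
  ps0 <- label_occupancy(detect_patches(f),
                         species_occurrence(rep(0L, 64), land))
  expect_false(any(ps0$occupied))
  # presence in every patch: no empty patches
  pres_all <- rep(0L, 64)
  pres_all[which(f >= 0.8)] <- 1L
  ps2 <- label_occupancy(detect_patches(f),
                         species_occurrence(pres_all, land))
  expect_true(all(ps2$occupied))
})

test_that("structure classification applies the metapopulation rule", {
  land <- bare_landscape(10, 12)
  f <- matrix(0.1, 10, 12)
  f[1:2, 1:2] <- 0.9; f[5:6, 5:6] <- 0.9; f[9:10, 10:12] <- 0.9
  # 8 of 10 presences inside favorable cells -> metapopulation
  fav_cells <- which(f >= 0.8)
  pres <- rep(0L, 120)
  pres[fav_cells[1:8]] <- 1L
  pres[which(f < 0.8)[1:2]] <- 1L
  cls <- classify_structure(detect_patches(f), f,
                            species_occurrence(pres, land))
  expect_identical(cls$category, "metapopulation")
  expect_equal(cls$n_patches, 3)
  expect_equal(cls$presence_in_favorable_proportion, 0.8)
  expect_equal(cls$n_occupied_patches + cls$n_empty_patches, cls$n_patches)

  # single patch: non-fragmented regardless of the proportion
  f1 <- matrix(0.1, 10, 12); f1[3:6, 3:6] <- 0.9
  cls1 <- classify_structure(detect_patches(f1), f1,
                             species_occurrence(pres, land))
  expect_identical(cls1$category, "non_fragmented")

  # fragmented with 2 of 10 presences in favorable cells: not a metapopulation
  f4 <- matrix(0.1, 10, 12)
  f4[1, 1] <- 0.9; f4[1, 5] <- 0.9; f4[5, 1] <- 0.9; f4[10, 12] <- 0.9
  pres4 <- rep(0L, 120)
  pres4[which(f4 >= 0.8)[1:2]] <- 1L
  pres4[which(f4 < 0.8)[1:8]] <- 1L
  cls4 <- classify_structure(detect_patches(f4), f4,
                             species_occurrence(pres4, land))
  expect_identical(cls4$category, "fragmented_non_metapopulation")
  expect_equal(cls4$presence_in_favorable_proportion, 0.2)

  # proportion exactly 0.5 is NOT a metapopulation (strict rule)
  pres5 <- rep(0L, 120)
  pres5[which(f4 >= 0.8)[1:2]] <- 1L
  pres5[which(f4 < 0.8)[1:2]] <- 1L
  cls5 <- classify_structure(detect_patches(f4), f4,
                             species_occurrence(pres5, land))
  expect_identical(cls5$category, "fragmented_non_metapopulation")

  # no favorable area at all
  cls0 <- classify_structure(detect_patches(matrix(0.2, 10, 12)),
                             matrix(0.2, 10, 12),
                             species_occurrence(pres, land))
  expect_identical(cls0$category, "no_favorable_area")
})

test_that("the four categories are exhaustive and mutually exclusive", {
  set.seed(31)
  cats <- c("no_favorable_area", "non_fragmented", "metapopulation",
            "fragmented_non_metapopulation")
  land <- bare_landscape(12, 12)
  for (i in 1:30) {
    f <- matrix(runif(144), 12, 12)^sample(c(0.5, 1, 3), 1)
    pres <- rbinom(144, 1, 0.2)
    ps <- detect_patches(f)
    cls <- classify_structure(ps, f, species_occurrence(pres, land))
    expect_true(cls$category %in% cats)
    expected <- if (ps$n_patches == 0) "no_favorable_area"
    else if (ps$n_patches == 1) "non_fragmented"
    else if (sum(pres) > 0 &&
             mean(f[which(pres == 1)] >= 0.8) > 0.5) "metapopulation"
    else "fragmented_non_metapopulation"
    expect_identical(cls$category, expected)
  }
})

test_that("zero-presence species report a missing proportion", {
  land <- bare_landscape(6, 6)
  f <- matrix(0.1, 6, 6); f[1, 1] <- 0.9; f[6, 6] <- 0.9
  cls <- classify_structure(detect_patches(f), f,
                            species_occurrence(rep(0L, 36), land))
  expect_true(is.na(cls$presence_in_favorable_proportion))
  expect_identical(cls$category, "fragmented_non_metapopulation")
})
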