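test_that("patch geometry matches hand-counted examples", {
  map <- tiny_map()
  m <- landscape_mosaic(matrix(1L, 3, 3), 50, map)
  p <- label_patches(m, "natural")
  expect_identical(nrow(p), 1L)
  expect_equal(p$area_ha, 2.25)
  expect_equal(p$perimeter_m, 600)
  gh <- configurational_heterogeneity(m, "natural")
  expect_equal(gh$shape_index, 1)    # square minimises shape
  expect_equal(gh$lpi, 100)
  expect_equal(gh$edge_density, 0)

  # 1 x 4 line inside a production background: 0.25 * 10 / 2 = 1.25
  g <- matrix(3L, 4, 6)
  g[2, 2:5] <- 1L
  m2 <- landscape_mosaic(g, 50, map)
  gh2 <- configurational_heterogeneity(m2, "natural")
  expect_equal(gh2$shape_index, 1.25)

  # diagonal touch: one patch under 8-connectivity, two under 4
  g3 <- matrix(3L, 2, 2)
  g3[1, 1] <- 1L; g3[2, 2] <- 1L
  m3 <- landscape_mosaic(g3, 50, map)
  expect_identical(nrow(label_patches(m3, "natural", 8L)), 1L)
  expect_identical(nrow(label_patches(m3, "natural", 4L)), 2L)
})

test_that("edge density counts internal inter-category edges once", {
  map <- tiny_map()
  m <- landscape_mosaic(matrix(c(1L, 2L), 1, 2), 10, map)
  gh <- configurational_heterogeneity(m, "natural")
  expect_equal(gh$edge_density, 500)  # one 10 m edge over 0.02 ha
  # buffer boundary does not contribute
  m2 <- landscape_mosaic(matrix(c(1L, 0L, 1L, 0L), 2, 2), 10, map)
  expect_equal(configurational_heterogeneity(m2, "natural")$edge_density,
               0)
})

test_that("composition returns percent covers summing to 100", {
  map <- tiny_map()
  m <- landscape_mosaic(matrix(1L, 4, 4), 50, map)
  expect_equal(unname(composition(m)["nat1"]), 100)
  expect_equal(sum(composition(m)), 100)

  g <- matrix(c(rep(1L, 8), rep(3L, 8)), 4, 4)
  cv <- composition(landscape_mosaic(g, 50, map))
  expect_equal(unname(cv[c("nat1", "prod1")]), c(50, 50))

  g2 <- matrix(3L, 10, 10)
  g2[1:37] <- 2L
  cv2 <- composition(landscape_mosaic(g2, 50, map))
  expect_equal(unname(cv2["nat2"]), 37)
})

test_that("compositional heterogeneity follows the Shannon/Pielou forms", {
  map <- tiny_map(3L, 1L)
  m1 <- landscape_mosaic(matrix(1L, 4, 4), 50, map)
  ch1 <- compositional_heterogeneity(m1, "natural")
  expect_equal(ch1$richness, 1)
  expect_equal(ch1$diversity, 0)
  expect_equal(ch1$evenness, 0)

  g <- matrix(c(rep(1L, 8), rep(2L, 8)), 4, 4)
  ch2 <- compositional_heterogeneity(landscape_mosaic(g, 50, map),
                                     "natural")
  expect_equal(ch2$diversity, log(2), tolerance = 1e-12)
  expect_equal(ch2$evenness, 1, tolerance = 1e-12)

  g3 <- matrix(c(rep(1L, 10), rep(2L, 6), rep(3L, 4)), 4, 5)
  ch3 <- compositional_heterogeneity(landscape_mosaic(g3, 50, map),
                                     "natural")
  expect_equal(ch3$diversity,
               -sum(c(.5, .3, .2) * log(c(.5, .3, .2))),
               tolerance = 1e-12)
  expect_equal(ch3$diversity, 1.0297, tolerance = 1e-4)

  # absent component: all metrics zero
  ch0 <- compositional_heterogeneity(m1, "production")
  expect_equal(unlist(ch0), c(richness = 0, diversity = 0, evenness = 0))
  gh0 <- configurational_heterogeneity(m1, "production")
  expect_equal(unlist(gh0),
               c(lpi = 0, mean_patch_size = 0, edge_density = 0,
                 shape_index = 0))
})

test_that("metrics are invariant to code permutation, rotation and mirroring", {
  set.seed(7)
  map4 <- tiny_map(2L, 2L)
  for (rep in 1:10) {
    m <- random_mosaic(8L, 8L, codes = 1:4, map = map4)
    base <- landscape_metrics(m)
    het <- base[-(1:4)]   # heterogeneity block (covers permute with codes)

    # permute codes within each component
    perm <- c(2L, 1L, 4L, 3L)
    g2 <- matrix(perm[m$grid], nrow(m$grid), ncol(m$grid))
    het2 <- landscape_metrics(landscape_mosaic(g2, m$cell_size,
                                               map4))[-(1:4)]
    expect_equal(het2, het, tolerance = 1e-12)

    # rotation and mirroring leave every metric unchanged
    for (tr in list(function(g) t(g)[ncol(g):1, , drop = FALSE],
                    function(g) g[nrow(g):1, , drop = FALSE])) {
      mt <- landscape_mosaic(tr(m$grid), m$cell_size, map4)
      expect_equal(landscape_metrics(mt), base, tolerance = 1e-12)
    }
  }
})

test_that("merging two adjacent same-category patches never shrinks LPI or mean patch size", {
  map <- tiny_map()
  g <- matrix(3L, 5, 5)
  g[2, 1:2] <- 1L
  g[2, 4:5] <- 1L          # two separate natural patches
  before <- configurational_heterogeneity(
    landscape_mosaic(g, 50, map), "natural")
  g[2, 3] <- 1L            # bridge cell merges them
  after <- configurational_heterogeneity(
    landscape_mosaic(g, 50, map), "natural")
  expect_gte(after$lpi, before$lpi)
  expect_gte(after$mean_patch_size, before$mean_patch_size)
})

test_that("patch partition and metrics agree exactly with brute-force oracles", {
  set.seed(11)
  map4 <- tiny_map(2L, 2L)
  for (rep in 1:40) {
    m <- random_mosaic(10L, 10L, codes = sample(1:4, 2), map = map4)
    for (cmp in c("natural", "production")) {
      codes <- map4$code[map4$component == cmp]
      lab <- oracle_label(m$grid, codes)
      st <- oracle_patch_stats(m$grid, lab)
      p <- label_patches(m, cmp)
      expect_identical(nrow(p), nrow(st))
      expect_identical(sort(p$cells), sort(st$cells))
      o <- order(p$cells, p$perimeter_edges)
      oo <- order(st$cells, st$perimeter_edges)
      expect_identical(p$perimeter_edges[o], st$perimeter_edges[oo])
      expect_equal(configurational_heterogeneity(m, cmp),
                   oracle_config_het(m, cmp), tolerance = 1e-12)
    }
  }
})

test_that("empty buffers and invalid components are rejected", {
  map <- tiny_map()
  m_empty <- landscape_mosaic(matrix(0L, 2, 2), 50, map)
  expect_error(composition(m_empty), "empty buffer")
  expect_error(configurational_heterogeneity(m_empty, "natural"),
               "empty buffer")
  expect_error(label_patches(landscape_mosaic(matrix(1L, 2, 2), 50, map),
                             "natural", connectivity = 6L),
               "connectivity")
})
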