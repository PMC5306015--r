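test_that("mosaic simulation is deterministic per (config, site, period)", {
  sc <- sim_config(n_sites = 3, seed = 5)
  a <- simulate_mosaic(sc, 2, 1)
  b <- simulate_mosaic(sc, 2, 1)
  expect_identical(a$grid, b$grid)
  c2 <- simulate_mosaic(sc, 2, 2)
  expect_false(identical(a$grid, c2$grid))
  d <- simulate_mosaic(sim_config(n_sites = 3, seed = 6), 2, 1)
  expect_false(identical(a$grid, d$grid))
})

test_that("one dominant category with buffer-sized aggregation yields a single patch", {
  sc <- sim_config(n_sites = 1, grid_dim = 21, natural_share = 0,
                   presence_prob = c(natural = 0, production = 0),
                   aggregation = 1e6, seed = 9)
  m <- simulate_mosaic(sc, 1, 1)
  cv <- composition(m)
  expect_equal(max(cv), 100)
  p <- label_patches(m, "production")
  expect_identical(nrow(p), 1L)
  expect_equal(configurational_heterogeneity(m, "production")$lpi, 100)
})

test_that("realised composition matches drawn targets within rounding", {
  # the region grower claims exactly the integer targets, so realised
  # covers can deviate from *proportional* targets only by rounding:
  # at most one cell per category
  sc <- sim_config(n_sites = 20, grid_dim = 25, seed = 17)
  for (s in 1:20) {
    m <- simulate_mosaic(sc, s, 1)
    cv <- composition(m)
    n_buf <- sum(m$grid != 0)
    counts <- cv * n_buf / 100
    expect_equal(counts, round(counts), tolerance = 1e-9)
  }
})

test_that("richness targets across 100 simulated sites stay within 2 points of targets", {
  sc <- sim_config(n_sites = 100, grid_dim = 25, seed = 23)
  dev_max <- 0
  for (s in 1:100) {
    m <- simulate_mosaic(sc, s, 1)
    tgt <- attr(m, "targets")
    cv <- composition(m)
    if (!is.null(tgt))
      dev_max <- max(dev_max, max(abs(cv - tgt)))
  }
  expect_lte(dev_max, 2)
})

test_that("null response has the configured Poisson mean", {
  met <- random_metrics(1000, "T0", seed = 31)
  sc <- sim_config(n_sites = 1000, beta = c(woodland = 0),
                   beta0 = log(10), seed = 31)
  resp <- simulate_response(met, sc, seed = 32)
  expect_lt(abs(mean(resp$response) - 10), 3 * sqrt(10 / 1000))
})

test_that("fit_glm recovers generating coefficients from large simulations", {
  met <- random_metrics(500, "T0", seed = 41)
  beta <- c(annual_dry_crops = 0.3, woodland = -0.2)
  sc <- sim_config(n_sites = 500, beta = beta, beta0 = log(8), seed = 41)
  resp <- simulate_response(met, sc, seed = 42)
  rt <- data.frame(site_id = resp$site_id, period = "T0", group = "all",
                   richness = as.integer(resp$response),
                   stringsAsFactors = FALSE)
  mat <- build_matrix(met, rt, mode = "spatial_T0")
  f <- fit_glm(mat, names(beta))
  sm <- summary(f$glm)$coefficients
  # generator applies beta to unit-SD predictors: rescale to raw scale
  for (v in names(beta)) {
    b_raw <- beta[[v]] / sd(mat[[v]])
    row <- sm[rownames(sm) == v | rownames(sm) == sprintf("`%s`", v), ]
    expect_lt(abs(row["Estimate"] - b_raw), 3 * row["Std. Error"])
  }
})

test_that("spatially correlated noise shows up in the raw correlogram", {
  met <- random_metrics(80, "T0", seed = 51)
  set.seed(52)
  coords <- cbind(runif(80, 0, 10000), runif(80, 0, 10000))
  sc <- sim_config(n_sites = 80, beta = c(woodland = 0), beta0 = log(10),
                   spatial_sd = 0.6, spatial_range = 4000, seed = 51)
  resp <- simulate_response(met, sc, coords = coords, seed = 53)
  cg <- spline_correlogram(coords, resp$response, B = 60, seed = 54)
  expect_gt(cg$e0, 0.1)
  third <- floor(length(cg$distance) / 3)
  expect_gt(mean(cg$estimate[1:third]),
            mean(cg$estimate[(2 * third):length(cg$estimate)]))
})

test_that("simulated surveys pool back to their richness targets exactly", {
  set.seed(61)
  truth <- expand.grid(site_id = sprintf("s%02d", 1:6),
                       period = c("T0", "T1"),
                       group = c("woodland", "farmland", "steppe"),
                       stringsAsFactors = FALSE)
  truth$richness <- sample(0:8, nrow(truth), replace = TRUE)
  pool <- data.frame(
    species = sprintf("sp%03d", 1:40),
    group = rep(c("woodland", "farmland", "steppe", "excluded"), 10),
    stringsAsFactors = FALSE)
  recs <- simulate_survey(truth, pool, seed = 62)
  expect_true(all(recs$year %in% unlist(default_period_windows())))
  r <- richness(recs, pool, steppe_within_farmland = FALSE)
  for (i in seq_len(nrow(truth))) {
    got <- r$richness[r$site_id == truth$site_id[i] &
                        r$period == truth$period[i] &
                        r$group == truth$group[i]]
    if (length(got) == 0) got <- 0L   # site absent => no records at all
    expect_identical(as.integer(got), truth$richness[i])
  }
  # and the "all" column is the sum of the disjoint groups
  agg <- aggregate(richness ~ site_id + period,
                   truth, sum)
  for (i in seq_len(nrow(agg))) {
    got <- r$richness[r$site_id == agg$site_id[i] &
                        r$period == agg$period[i] & r$group == "all"]
    if (length(got) == 0) got <- 0L
    expect_identical(as.integer(got), agg$richness[i])
  }
  expect_error(
    simulate_survey(transform(truth, richness = 30), pool, seed = 1),
    "pool too small")
})
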