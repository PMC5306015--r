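test_that("GLM fits reproduce closed-form solutions", {
  d <- data.frame(response = c(2, 4, 6))
  f <- fit_glm(d, family = "poisson_log")
  expect_equal(unname(coef(f$glm)), log(4), tolerance = 1e-8)
  expect_equal(f$k, 1)

  set.seed(4)
  n <- 40
  d2 <- data.frame(response = rnorm(n), x = rnorm(n), z = rnorm(n))
  f2 <- fit_glm(d2, c("x", "z"), family = "gaussian_identity")
  X <- cbind(1, d2$x, d2$z)
  ols <- solve(crossprod(X), crossprod(X, d2$response))
  expect_equal(unname(f2$coefficients), as.numeric(ols),
               tolerance = 1e-8)
  expect_equal(f2$k, 4)   # intercept + 2 slopes + sigma
})

test_that("Poisson coefficient recovery at n = 500 is within 3 SE", {
  set.seed(77)
  n <- 500
  x <- rnorm(n)
  eta <- 0.5 + 0.3 * x
  d <- data.frame(response = rpois(n, exp(eta)), x = x)
  f <- fit_glm(d, "x", family = "poisson_log")
  se <- summary(f$glm)$coefficients[, "Std. Error"]
  expect_lt(abs(f$coefficients[1] - 0.5), 3 * se[1])
  expect_lt(abs(f$coefficients[2] - 0.3), 3 * se[2])
})

test_that("rank-deficient designs are refused with the offending column named", {
  set.seed(1)
  d <- data.frame(response = rpois(10, 5), x = rnorm(10))
  d$y <- 2 * d$x
  expect_error(fit_glm(d, c("x", "y"), family = "poisson_log"),
               "collinear.*y")
})

test_that("AICc matches its definition and tends to AIC for large n", {
  expect_equal(aicc(-50, 3, 73), 106 + 24 / 69, tolerance = 1e-12)
  expect_equal(aicc(-50, 3, 73), 106.3478, tolerance = 1e-4)
  expect_lt(abs(aicc(-50, 3, 1e8) - (-2 * -50 + 2 * 3)), 1e-6)
  expect_error(aicc(-50, 10, 11), "n > k")
  expect_equal(aicc(-10, 2, 50), aicc(-10, 2, 50))
})

test_that("Akaike weights normalise correctly and ignore constant shifts", {
  expect_equal(akaike_weights(c(100, 100, 100)), rep(1 / 3, 3))
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(w, exp(c(0, -1)) / sum(exp(c(0, -1))), tolerance = 1e-12)
  expect_equal(akaike_weights(c(13, 15, 19) + 57),
               akaike_weights(c(13, 15, 19)), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(runif(20, 50, 90))), 1,
               tolerance = 1e-12)
})

test_that("stage-1 enumeration is the full non-empty powerset of sets", {
  s3 <- list(a = "x1", b = "x2", c = c("x3", "x4"))
  cand <- enumerate_stage1(s3)
  expect_length(cand, 7L)
  for (nm in names(s3))
    expect_identical(
      sum(vapply(cand, function(cd) nm %in% cd$sets, logical(1))), 4L)
  expect_length(enumerate_stage1(list(a = "x1")), 1L)
  expect_error(enumerate_stage1(list(a = "x1", b = "x1")), "overlap")

  cand6 <- enumerate_stage1(variable_sets())
  expect_length(cand6, 63L)
  for (nm in names(variable_sets()))
    expect_identical(
      sum(vapply(cand6, function(cd) nm %in% cd$sets, logical(1))), 32L)
  # every variable meets every other variable in at least one model
  vars <- unlist(variable_sets(), use.names = FALSE)
  pair_met <- outer(vars, vars, Vectorize(function(a, b)
    any(vapply(cand6, function(cd)
      all(c(a, b) %in% cd$variables), logical(1)))))
  expect_true(all(pair_met))
})

test_that("stage-1 screen is invariant to the ordering of sets", {
  mat <- simulated_matrix(n = 60, seed = 3)
  sets <- variable_sets()
  s1 <- stage1_screen(mat, sets)
  s2 <- stage1_screen(mat, sets[c(4, 2, 6, 1, 3, 5)])
  m <- match(s1$set, s2$set)
  expect_equal(s1$w_plus, s2$w_plus[m], tolerance = 1e-10)
  expect_equal(sum(attr(s1, "candidates")$weight), 1, tolerance = 1e-12)
})

test_that("VIF matches its closed form", {
  set.seed(10)
  n <- 200
  x1 <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ x1))
  e <- as.numeric(scale(e))
  x2 <- 0.8 * x1 + sqrt(1 - 0.64) * e   # empirical cor exactly 0.8
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-8)
  expect_equal(unname(v), c(2.7778, 2.7778), tolerance = 1e-4)

  x3 <- as.numeric(scale(residuals(lm(rnorm(n) ~ x1))))
  expect_equal(unname(vif(cbind(x1, x3))), c(1, 1), tolerance = 1e-10)
  expect_equal(unname(vif(cbind(only = x1))), 1)
  expect_error(vif(cbind(x1, 2 * x1)), "collinear")
})

test_that("partial SD shrinks the sample SD by VIF and degrees of freedom", {
  x <- c(1, 3, 5, 2, 4, 6, 8, 7, 9, 0)
  x <- x / sd(x) * 2                      # sample SD exactly 2
  ps <- partial_sd(cbind(x = x), n = 10)
  expect_equal(unname(ps), 2 * sqrt(9 / 8), tolerance = 1e-12)
  expect_equal(unname(ps), 2.1213, tolerance = 1e-4)

  set.seed(2)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  ps3 <- partial_sd(X, n = 50)
  bound <- apply(X, 2, sd) * sqrt(49 / 46)
  expect_true(all(ps3 <= bound + 1e-12))
  expect_error(partial_sd(X, n = 3), "n > p")
  expect_error(partial_sd(cbind(X, d = 2 * X[, 1]), n = 50), "collinear")
})

test_that("stage-2 averaging follows the conditional-averaging contract", {
  mat <- simulated_matrix(
    n = 73, seed = 8,
    beta = c(annual_dry_crops = 0.45, woodland = 0.2))
  sets <- variable_sets()
  avg <- stage2_average(mat, sets["prod_comp"])
  expect_true(all(avg$importance >= 0 & avg$importance <= 1))
  expect_true(all(avg$w_plus >= 0 & avg$w_plus <= 1))
  expect_equal(sum(attr(avg, "candidates")$weight), 1, tolerance = 1e-12)

  # a variable present in exactly one candidate inherits that model's
  # standardized coefficient: enumerate a one-variable universe
  one <- stage2_average(mat, list(solo = "annual_dry_crops"))
  f <- fit_glm(mat, "annual_dry_crops")
  psd <- partial_sd(as.matrix(mat[, "annual_dry_crops", drop = FALSE]),
                    nrow(mat))
  expect_equal(one$avg_coef[1],
               unname(f$coefficients[2] * psd), tolerance = 1e-10)
  expect_equal(one$importance[1], 1)   # lone variable dominates its model
})

test_that("standardized coefficients are invariant to affine predictor rescaling", {
  mat <- simulated_matrix(n = 73, seed = 15,
                          beta = c(annual_dry_crops = 0.4))
  sets <- variable_sets()["prod_comp"]
  base <- stage2_average(mat, sets)
  mat2 <- mat
  mat2$annual_dry_crops <- 3.7 * mat2$annual_dry_crops + 11
  mat2$permanent_crops <- 0.01 * mat2$permanent_crops - 2
  resc <- stage2_average(mat2, sets)
  expect_equal(resc$avg_coef, base$avg_coef, tolerance = 1e-8)
  expect_equal(resc$importance, base$importance, tolerance = 1e-8)
})

test_that("within every model the largest-magnitude coefficient has importance 1", {
  mat <- simulated_matrix(n = 73, seed = 21,
                          beta = c(annual_dry_crops = 0.4))
  vars <- variable_sets()$prod_comp[1:3]
  f <- fit_glm(mat, vars)
  psd <- partial_sd(as.matrix(mat[, vars]), nrow(mat))
  std <- f$coefficients[vars] * psd
  imp <- abs(std) / max(abs(std))
  expect_equal(max(imp), 1)
  expect_identical(sum(imp == 1), 1L)
})

test_that("Poisson dispersion is near 1 for data generated from the model", {
  set.seed(99)
  disp <- replicate(20, {
    x <- rnorm(73)
    d <- data.frame(response = rpois(73, exp(2 + 0.3 * x)), x = x)
    fit_glm(d, "x", family = "poisson_log")$dispersion
  })
  expect_lt(abs(mean(disp) - 1), 0.15)
})

test_that("stage-2 refuses explosive enumerations", {
  mat <- simulated_matrix(n = 73, seed = 5)
  sets <- variable_sets()
  expect_error(
    stage2_average(mat, sets, max_variables = 5L),
    "raise")
})
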