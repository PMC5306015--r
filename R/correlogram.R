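pair_products <- function(coords, values) {
  n <- length(values)
  z <- (values - mean(values)) / stats::sd(values)
  D <- as.matrix(stats::dist(coords))
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  list(d = D[cbind(i, j)], p = z[i] * z[j], D = D)
}

fit_corr_spline <- function(d, p, df, grid) {
  sp <- stats::smooth.spline(d, p, df = df)
  est <- stats::predict(sp, grid)$y
  pmin(1, pmax(-1, est))
}

#' Nonparametric spline correlogram with bootstrap envelope
#'
#' Estimates spatial correlation as a smooth function of distance: values
#' are centred and scaled, all pairwise products z_i z_j are computed
#' against pairwise distances, and a cubic smoothing spline with `df`
#' equivalent degrees of freedom is fitted through them. A 95% pointwise
#' confidence envelope comes from resampling sites with replacement `B`
#' times (re-standardising within each resample) and refitting.
#'
#' @param coords Two-column matrix or data frame of site coordinates
#'   (metres).
#' @param values Numeric response (or residual) vector, one per site.
#' @param B Number of bootstrap resamples (1000 by default).
#' @param df Equivalent degrees of freedom of the smoother; default
#'   `min(10, sqrt(n))`.
#' @param max_dist Largest distance of the evaluation grid; default half
#'   the maximum pairwise distance, avoiding the sparse far tail.
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param n_grid Number of evaluation distances.
#' @return An object of class `spline_correlogram`: list with `distance`,
#'   `estimate`, `lower`, `upper` (2.5/97.5 bootstrap percentiles), `e0`
#'   (estimate at distance 0), `x_intercept` (first zero crossing, NA if
#'   none), `df`, `B`, `n`.
#' @export
spline_correlogram <- function(coords, values, B = 1000L, df = NULL,
                               max_dist = NULL, seed = NULL,
                               n_grid = 100L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) == length(values))
  n <- length(values)
  if (n < 10L) stop("need at least 10 sites (got ", n, ")")
  if (anyDuplicated(coords))
    stop("duplicate site coordinates")
  if (any(!is.finite(values))) stop("non-finite values")
  if (stats::sd(values) == 0)
    stop("all values identical: correlation undefined")
  if (is.null(df)) df <- min(10, sqrt(n))
  if (!is.null(seed)) set.seed(seed)

  pp <- pair_products(coords, values)
  if (is.null(max_dist)) max_dist <- max(pp$d) / 2
  grid <- seq(0, max_dist, length.out = n_grid)
  est <- fit_corr_spline(pp$d, pp$p, df, grid)

  boot <- base::matrix(NA_real_, B, n_grid)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    vb <- values[idx]
    if (stats::sd(vb) == 0) next
    zb <- (vb - mean(vb)) / stats::sd(vb)
    # pairs of distinct draws (repeated sites allowed, self-pairs not)
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
    keep <- idx[i] != idx[j]
    if (sum(keep) < 10L) next
    db <- pp$D[cbind(idx[i][keep], idx[j][keep])]
    boot[b, ] <- fit_corr_spline(db, zb[i][keep] * zb[j][keep], df, grid)
  }
  ok <- stats::complete.cases(boot)
  lo <- apply(boot[ok, , drop = FALSE], 2L, stats::quantile, 0.025)
  hi <- apply(boot[ok, , drop = FALSE], 2L, stats::quantile, 0.975)

  xi <- NA_real_
  sgn <- sign(est)
  cross <- which(sgn[-1L] != sgn[-length(sgn)] & sgn[-1L] != 0)
  if (length(cross)) {
    k <- cross[1L]
    xi <- grid[k] + (grid[k + 1L] - grid[k]) *
      est[k] / (est[k] - est[k + 1L])
  }
  structure(
    list(distance = grid, estimate = est, lower = lo, upper = hi,
         e0 = est[1L], x_intercept = xi, df = df, B = B, n = n),
    class = "spline_correlogram")
}

#' @export
print.spline_correlogram <- function(x, ...) {
  cat(sprintf(
    "spline_correlogram: n = %d sites, B = %d resamples, df = %.2f\n",
    x$n, x$B, x$df))
  cat(sprintf("  e0 = %.3f, x-intercept = %s m, grid 0..%.1f m\n",
              x$e0,
              if (is.na(x$x_intercept)) "none"
              else sprintf("%.1f", x$x_intercept),
              max(x$distance)))
  invisible(x)
}

#' @export
plot.spline_correlogram <- function(x, main = "Spline correlogram", ...) {
  graphics::plot(x$distance, x$estimate, type = "n",
                 ylim = range(c(x$lower, x$upper, 0), finite = TRUE),
                 xlab = "Distance (m)", ylab = "Correlation",
                 main = main, ...)
  graphics::polygon(c(x$distance, rev(x$distance)),
                    c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$distance, x$estimate, lwd = 2)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Check that a model removed spatial autocorrelation
#'
#' Computes spline correlograms of the raw response and of the model
#' residuals (deviance residuals by default, the natural choice for
#' Poisson richness models). Autocorrelation is judged removed when the
#' residual envelope contains zero over at least `cover_frac` of the
#' distance grid.
#'
#' @param fit A [fit_glm()] result.
#' @param matrix The analysis matrix the model was fitted on.
#' @param coords Site coordinates aligned with the matrix rows.
#' @param residual_type `"deviance"` or `"pearson"`.
#' @param cover_frac Required envelope-covers-zero fraction.
#' @param ... Passed to [spline_correlogram()] (`B`, `df`, `seed`, ...).
#' @return List with `raw` and `residual` correlograms and `removed`
#'   (logical).
#' @export
residual_check <- function(fit, matrix, coords,
                           residual_type = c("deviance", "pearson"),
                           cover_frac = 0.95, ...) {
  stopifnot(inherits(fit, "model_fit"))
  residual_type <- match.arg(residual_type)
  if (fit$n != nrow(matrix))
    stop("fit and matrix sizes differ")
  raw <- spline_correlogram(coords, matrix$response, ...)
  res <- spline_correlogram(
    coords, stats::residuals(fit$glm, type = residual_type), ...)
  covers <- mean(res$lower <= 0 & res$upper >= 0)
  list(raw = raw, residual = res, removed = covers >= cover_frac,
       cover_fraction = covers)
}
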