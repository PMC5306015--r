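#' Simulation configuration
#'
#' Bundles every knob of the synthetic-landscape generator. Defaults
#' emulate the study design the package targets: 73 sites surveyed in two
#' periods, each characterised inside a circular buffer mask inscribed in a
#' 45 x 45 grid of 50 m cells, with 5 natural and 5 production land-cover
#' categories. Composition targets per component are drawn Dirichlet-style
#' (normalised gamma draws) around component prevalences, patch structure
#' is controlled by an aggregation parameter (expected patch size in
#' cells), and responses are Poisson richness counts generated from a known
#' coefficient vector over the 24 landscape variables, optionally with a
#' spatially autocorrelated Gaussian field added to the linear predictor.
#'
#' @param n_sites Number of sites (transects).
#' @param grid_dim Grid side length in cells.
#' @param cell_size Cell side in metres.
#' @param category_map Category map; see [default_category_map()].
#' @param natural_share Expected share of buffer area in the natural
#'   component.
#' @param presence_prob Per-category presence probabilities, named
#'   `natural` and `production`: each category enters a buffer
#'   independently with this probability (at least one production
#'   category always present), so buffers hold only a few categories, as
#'   farmland buffers do.
#' @param concentration Dirichlet concentration of category shares within
#'   each component (smaller = more uneven landscapes).
#' @param aggregation Expected patch size in cells; controls the number of
#'   region-growing seeds per category.
#' @param beta0 Intercept of the response linear predictor (log scale for
#'   Poisson).
#' @param beta Named numeric vector of true coefficients on the
#'   unit-variance transformed predictors; names must be variables of
#'   [variable_info()].
#' @param family Response family, `"poisson_log"` or
#'   `"gaussian_identity"`.
#' @param sigma Residual SD for the Gaussian family.
#' @param spatial_range,spatial_sd Range (metres) and SD of the optional
#'   exponential-covariance spatial noise field; `spatial_sd = 0` disables
#'   it.
#' @param extent Side length (metres) of the square study region over
#'   which site coordinates are scattered.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_sites = 73L,
                       grid_dim = 45L,
                       cell_size = 50,
                       category_map = default_category_map(),
                       natural_share = 0.15,
                       presence_prob = c(natural = 0.3,
                                         production = 0.33),
                       concentration = 1,
                       aggregation = 60,
                       beta0 = log(10),
                       beta = c(annual_dry_crops = 0.3,
                                permanent_pastures = -0.3,
                                annual_irrigated_crops = -0.3,
                                arable_scattered_trees = 0.3,
                                permanent_crops = -0.3),
                       family = "poisson_log",
                       sigma = 1,
                       spatial_range = 3000,
                       spatial_sd = 0,
                       extent = 20000,
                       seed = 1L) {
  check_category_map(category_map)
  vi <- variable_info(category_map)
  bad <- setdiff(names(beta), vi$variable)
  if (length(bad))
    stop("beta names not among the landscape variables: ",
         paste(bad, collapse = ", "))
  if (aggregation < 1) stop("aggregation must be >= 1")
  if (is.null(seed)) stop("seed is mandatory for reproducibility")
  structure(list(
    n_sites = as.integer(n_sites), grid_dim = as.integer(grid_dim),
    cell_size = cell_size, category_map = category_map,
    natural_share = natural_share, presence_prob = presence_prob,
    concentration = concentration,
    aggregation = aggregation, beta0 = beta0, beta = beta,
    family = family, sigma = sigma,
    spatial_range = spatial_range, spatial_sd = spatial_sd,
    extent = extent, seed = as.integer(seed)),
    class = "sim_config")
}

# deterministic sub-seed per (site, period); kept below 2^31
derive_seed <- function(seed, site, period_index) {
  as.integer((as.numeric(seed) * 7919 + site * 131 + period_index * 17) %%
               2147483647)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[sample.int(length(g), 1L)] <- 1
  g / sum(g)
}

disk_mask <- function(dim) {
  r <- dim / 2
  ctr <- (dim + 1) / 2
  outer(seq_len(dim), seq_len(dim),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

#' Simulate one landscape mosaic
#'
#' Draws a target composition (Dirichlet within each component, components
#' weighted by `natural_share`) and realises it exactly by multi-seed
#' region growing inside the buffer mask: each category receives
#' `ceiling(target / aggregation)` seeds and categories claim unclaimed
#' frontier cells, largest deficit first, re-seeding whenever a deficit
#' category runs out of frontier. Realised cell counts equal the integer
#' targets exactly, so composition deviates from the drawn proportions by
#' at most the rounding residue. Deterministic per (config, site, period).
#'
#' @param config A [sim_config()].
#' @param site Site index (1-based).
#' @param period Period index (1 or 2) or label `"T0"`/`"T1"`.
#' @return A [landscape_mosaic()].
#' @export
simulate_mosaic <- function(config, site = 1L, period = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(period)) period <- match(period, c("T0", "T1"))
  set.seed(derive_seed(config$seed, site, period))
  dim <- config$grid_dim
  mask <- disk_mask(dim)
  n_buf <- sum(mask)
  cm <- config$category_map
  k_nat <- sum(cm$component == "natural")
  k_prod <- sum(cm$component == "production")

  # sparse category presence: most buffers hold only a few categories
  pres_nat <- stats::runif(k_nat) < config$presence_prob[["natural"]]
  pres_prod <- stats::runif(k_prod) < config$presence_prob[["production"]]
  if (!any(pres_prod)) pres_prod[sample.int(k_prod, 1L)] <- TRUE

  share_nat <- if (any(pres_nat))
    min(0.95, max(0.01,
      stats::rbeta(1, 4 * config$natural_share /
                     (1 - config$natural_share), 4)))
  else 0
  p_nat <- numeric(k_nat)
  if (any(pres_nat))
    p_nat[pres_nat] <-
      rdirichlet1(rep(config$concentration, sum(pres_nat))) * share_nat
  p_prod <- numeric(k_prod)
  p_prod[pres_prod] <-
    rdirichlet1(rep(config$concentration, sum(pres_prod))) *
    (1 - share_nat)
  p <- c(p_nat, p_prod)

  # integer targets by largest remainder, summing to the buffer size
  raw <- p * n_buf
  tgt <- floor(raw)
  rem <- n_buf - sum(tgt)
  if (rem > 0) {
    ord <- order(raw - tgt, decreasing = TRUE)
    tgt[ord[seq_len(rem)]] <- tgt[ord[seq_len(rem)]] + 1
  }
  if (sum(tgt) != n_buf) stop("infeasible composition targets")

  grid <- base::matrix(0L, dim, dim)
  unclaimed <- which(mask)
  claimed <- base::matrix(FALSE, dim, dim)
  deficit <- as.integer(tgt)
  codes <- cm$code
  frontier <- vector("list", length(codes))  # candidate cells per category
  for (ci in seq_along(codes)) frontier[[ci]] <- integer(0)

  neigh_idx <- function(cell) {
    r <- ((cell - 1L) %% dim) + 1L
    c <- ((cell - 1L) %/% dim) + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1L && rr <= dim && cc >= 1L && cc <= dim &&
          mask[rr, cc])
        out <- c(out, (cc - 1L) * dim + rr)
    }
    out
  }

  seed_category <- function(ci) {
    avail <- unclaimed[!claimed[unclaimed]]
    if (!length(avail)) return(FALSE)
    cell <- if (length(avail) == 1L) avail else sample(avail, 1L)
    grid[cell] <<- codes[ci]
    claimed[cell] <<- TRUE
    deficit[ci] <<- deficit[ci] - 1L
    frontier[[ci]] <<- c(frontier[[ci]], neigh_idx(cell))
    TRUE
  }

  # initial seeds: about one per `aggregation` cells of target
  for (ci in seq_along(codes)) {
    n_seeds <- if (tgt[ci] == 0) 0L else
      max(1L, ceiling(tgt[ci] / config$aggregation))
    for (s in seq_len(n_seeds)) {
      if (deficit[ci] > 0L) seed_category(ci)
    }
  }

  while (any(deficit > 0L)) {
    ci <- which.max(deficit)
    f <- frontier[[ci]]
    f <- f[!claimed[f]]
    if (!length(f)) {
      frontier[[ci]] <- integer(0)
      if (!seed_category(ci)) stop("infeasible composition (buffer full)")
      next
    }
    cell <- if (length(f) == 1L) f else sample(f, 1L)
    grid[cell] <- codes[ci]
    claimed[cell] <- TRUE
    deficit[ci] <- deficit[ci] - 1L
    frontier[[ci]] <- c(f[f != cell], neigh_idx(cell))
  }

  out <- landscape_mosaic(grid, config$cell_size, cm)
  attr(out, "targets") <- stats::setNames(100 * p, cm$name)
  out
}

#' Simulate a full landscape set
#'
#' Site coordinates plus one mosaic per (site, period).
#'
#' @param config A [sim_config()].
#' @param periods Period labels.
#' @return List with `sites` (data frame `site_id`, `x`, `y`) and
#'   `mosaics` (named list, `"<site>.<period>"`).
#' @export
simulate_landscape_set <- function(config, periods = c("T0", "T1")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 0L, 0L))
  n <- config$n_sites
  sites <- data.frame(
    site_id = sprintf("s%03d", seq_len(n)),
    x = stats::runif(n, 0, config$extent),
    y = stats::runif(n, 0, config$extent),
    stringsAsFactors = FALSE)
  mosaics <- list()
  for (pi in seq_along(periods))
    for (s in seq_len(n))
      mosaics[[paste(sites$site_id[s], periods[pi], sep = ".")]] <-
        simulate_mosaic(config, s, pi)
  list(sites = sites, mosaics = mosaics)
}

# exponential-covariance Gaussian field at the site coordinates (Cholesky)
spatial_field <- function(coords, range, sd) {
  D <- as.matrix(stats::dist(coords))
  S <- sd^2 * exp(-D / range)
  L <- chol(S + diag(1e-10, nrow(D)))
  as.numeric(crossprod(L, stats::rnorm(nrow(D))))
}

#' Simulate richness responses from landscape metrics
#'
#' Builds the transformed predictors, centres and scales them to unit
#' variance, forms the linear predictor `eta = beta0 + X beta` (plus an
#' exponential-covariance spatial field when `spatial_sd > 0`), and draws
#' Poisson counts with mean `exp(eta)` (spatial modes) or Gaussian values
#' with SD `sigma` (temporal differences). Because `beta` applies to
#' unit-variance predictors, its entries are effect sizes per predictor SD.
#'
#' @param metrics Metric table of the sites to simulate for (one period in
#'   Poisson mode; the package's temporal runs difference two such
#'   tables).
#' @param config A [sim_config()]; `beta`, `beta0`, `family`, `sigma` and
#'   the spatial-noise settings are used.
#' @param coords Optional site coordinates, required when
#'   `spatial_sd > 0`.
#' @param seed Optional seed override.
#' @return Data frame with `site_id` and `response`; attribute `eta` holds
#'   the linear predictor.
#' @export
simulate_response <- function(metrics, config, coords = NULL,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, 999983L, 1L))
  vi <- variable_info(config$category_map)
  X <- as.matrix(apply_transforms(metrics, vi))
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  beta_full <- stats::setNames(numeric(ncol(Xs)), colnames(Xs))
  beta_full[names(config$beta)] <- config$beta
  eta <- as.numeric(config$beta0 + Xs %*% beta_full)
  if (config$spatial_sd > 0) {
    if (is.null(coords))
      stop("coords required when spatial_sd > 0")
    eta <- eta + spatial_field(coords, config$spatial_range,
                               config$spatial_sd)
  }
  if (config$family == "poisson_log") {
    if (any(eta > 20))
      stop("exp(eta) overflow: reduce coefficients or beta0")
    y <- stats::rpois(length(eta), exp(eta))
  } else {
    y <- eta + stats::rnorm(length(eta), 0, config$sigma)
  }
  out <- data.frame(site_id = metrics$site_id, response = y,
                    stringsAsFactors = FALSE)
  attr(out, "eta") <- eta
  out
}

#' Simulate survey records matching richness targets exactly
#'
#' Emits per-year survey records whose pooled distinct-species counts
#' reproduce a richness truth table exactly: for each (site, period,
#' group) target, that many distinct species of the group are drawn from
#' the pool, each assigned to a random survey year of the period, with
#' extra duplicate records sprinkled across years (pooling must be
#' invariant to them).
#'
#' @param richness_truth Data frame `site_id`, `period`, `group`,
#'   `richness` with disjoint groups (`woodland`, `farmland`, `steppe`).
#' @param species_pool Data frame `species`, `group`; per group at least as
#'   many species as the largest target.
#' @param period_windows Named list of year vectors.
#' @param seed Integer seed.
#' @param dup_rate Expected number of duplicate records per species.
#' @return Data frame `site_id`, `year`, `species`.
#' @export
simulate_survey <- function(richness_truth, species_pool,
                            period_windows = default_period_windows(),
                            seed = 1L, dup_rate = 0.5) {
  stopifnot(is.data.frame(richness_truth), is.data.frame(species_pool))
  set.seed(as.integer(seed))
  recs <- list()
  for (r in seq_len(nrow(richness_truth))) {
    tgt <- richness_truth$richness[r]
    if (tgt == 0) next
    g <- richness_truth$group[r]
    pool <- species_pool$species[species_pool$group == g]
    if (length(pool) < tgt)
      stop("species pool too small for group '", g, "': need ", tgt,
           ", have ", length(pool))
    yrs <- period_windows[[richness_truth$period[r]]]
    if (is.null(yrs))
      stop("unknown period: ", richness_truth$period[r])
    sp <- sample(pool, tgt)
    year <- sample(yrs, tgt, replace = TRUE)
    n_dup <- stats::rpois(1L, dup_rate * tgt)
    if (n_dup > 0) {
      di <- sample.int(tgt, n_dup, replace = TRUE)
      sp <- c(sp, sp[di])
      year <- c(year, sample(yrs, n_dup, replace = TRUE))
    }
    recs[[r]] <- data.frame(site_id = richness_truth$site_id[r],
                            year = year, species = sp,
                            stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(site_id = character(), year = integer(),
                      species = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
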