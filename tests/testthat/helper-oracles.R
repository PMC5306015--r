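# Independent brute-force oracles and small fixtures used across the suite.

# two-category map used by small constructed mosaics
tiny_map <- function(n_nat = 2L, n_prod = 2L) {
  data.frame(
    code = seq_len(n_nat + n_prod),
    name = c(sprintf("nat%d", seq_len(n_nat)),
             sprintf("prod%d", seq_len(n_prod))),
    component = rep(c("natural", "production"), c(n_nat, n_prod)),
    stringsAsFactors = FALSE)
}

random_mosaic <- function(nr = 10L, nc = 10L, codes = 1:2,
                          cell_size = 10, map = tiny_map()) {
  g <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  landscape_mosaic(g, cell_size, map)
}

# recursive flood fill, the slow reference for patch delineation
oracle_label <- function(grid, codes, connectivity = 8L) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
          c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  next_id <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!(grid[r0, c0] %in% codes) || lab[r0, c0] != 0L) next
    next_id <- next_id + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- next_id
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[k, 1]; cc <- cur[2] + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (grid[rr, cc] == grid[cur[1], cur[2]] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- next_id
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# perimeter of each labelled patch by explicit per-side enumeration
oracle_patch_stats <- function(grid, lab) {
  nr <- nrow(grid); nc <- ncol(grid)
  ids <- sort(unique(lab[lab > 0L]))
  cells <- perim <- integer(length(ids))
  for (idx in seq_along(ids)) {
    id <- ids[idx]
    cs <- which(lab == id, arr.ind = TRUE)
    cells[idx] <- nrow(cs)
    p <- 0L
    for (i in seq_len(nrow(cs))) {
      r <- cs[i, 1]; c <- cs[i, 2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc ||
            grid[rr, cc] != grid[r, c]) p <- p + 1L
      }
    }
    perim[idx] <- p
  }
  data.frame(id = ids, cells = cells, perimeter_edges = perim)
}

# exhaustive internal-edge enumeration for one component
oracle_edge_count <- function(grid, codes) {
  nr <- nrow(grid); nc <- ncol(grid)
  e <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    a <- grid[r, c]
    if (c < nc) {
      b <- grid[r, c + 1]
      if (a != 0 && b != 0 && a != b && (a %in% codes || b %in% codes))
        e <- e + 1L
    }
    if (r < nr) {
      b <- grid[r + 1, c]
      if (a != 0 && b != 0 && a != b && (a %in% codes || b %in% codes))
        e <- e + 1L
    }
  }
  e
}

oracle_config_het <- function(mosaic, component, connectivity = 8L) {
  codes <- mosaic$category_map$code[
    mosaic$category_map$component == component]
  g <- mosaic$grid
  lab <- oracle_label(g, codes, connectivity)
  st <- oracle_patch_stats(g, lab)
  n_buf <- sum(g != 0L)
  buf_ha <- n_buf * mosaic$cell_size^2 / 1e4
  if (nrow(st) == 0L)
    return(list(lpi = 0, mean_patch_size = 0, edge_density = 0,
                shape_index = 0))
  area <- st$cells * mosaic$cell_size^2 / 1e4
  list(
    lpi = 100 * max(area) / buf_ha,
    mean_patch_size = mean(area),
    edge_density = oracle_edge_count(g, codes) * mosaic$cell_size / buf_ha,
    shape_index = mean(0.25 * st$perimeter_edges / sqrt(st$cells)))
}

# valid random metric tables without rasterising (for model-level tests):
# covers are Dirichlet draws scaled to percent, heterogeneity metrics drawn
# inside their admissible ranges
random_metrics <- function(n, periods = "T0", seed = 1) {
  set.seed(seed)
  vi <- variable_info()
  out <- list()
  for (p in periods) {
    g <- matrix(rgamma(n * 10, shape = 0.6), n, 10)
    covers <- 100 * g / rowSums(g)
    colnames(covers) <- vi$variable[1:10]
    het <- function(pre) {
      S <- sample(1:5, n, replace = TRUE)
      H <- runif(n, 0, log(pmax(S, 2)))
      data.frame(
        richness = S, diversity = H,
        evenness = ifelse(S > 1, H / log(S), 0),
        lpi = runif(n, 0, 100), mps = runif(n, 0.1, 30),
        ed = runif(n, 0, 300), shape = runif(n, 1, 3)) |>
        stats::setNames(paste0(pre, c("cover_richness", "cover_diversity",
                                      "cover_evenness", "lpi",
                                      "mean_patch_size", "edge_density",
                                      "shape_index")))
    }
    out[[p]] <- cbind(
      data.frame(site_id = sprintf("s%03d", seq_len(n)), period = p,
                 stringsAsFactors = FALSE),
      as.data.frame(covers), het("nat_"), het("prod_"))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# analysis matrix with a known Poisson response over chosen variables
simulated_matrix <- function(n = 73, beta = c(annual_dry_crops = 0.3),
                             beta0 = log(10), seed = 1,
                             family = "poisson_log", sigma = 1) {
  met <- random_metrics(n, "T0", seed = seed)
  cfg <- sim_config(n_sites = n, beta = beta, beta0 = beta0,
                    family = family, sigma = sigma, seed = seed)
  resp <- simulate_response(met, cfg, seed = seed + 1000)
  rt <- data.frame(site_id = resp$site_id, period = "T0", group = "all",
                   richness = pmax(0L, as.integer(round(resp$response))),
                   stringsAsFactors = FALSE)
  if (family == "gaussian_identity") {
    mat <- build_matrix(met, rt, mode = "spatial_T0", group = "all")
    mat$response <- resp$response
    attr(mat, "family") <- "gaussian_identity"
    mat
  } else {
    build_matrix(met, rt, mode = "spatial_T0", group = "all")
  }
}
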