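component_codes <- function(mosaic, component) {
  cm <- mosaic$category_map
  cm$code[cm$component == component]
}

shift_mat <- function(m, dr, dc, fill = NA_integer_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs0 <- max(1L, 1L + dr); rs1 <- min(nr, nr + dr)
  cs0 <- max(1L, 1L + dc); cs1 <- min(nc, nc + dc)
  if (rs0 > rs1 || cs0 > cs1) return(out)
  rs <- rs0:rs1; cs <- cs0:cs1
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 8L) {
    list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
         c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  } else if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else stop("connectivity must be 4 or 8")
}

#' Delineate patches of a landscape component
#'
#' Patches are maximal connected sets of same-category cells restricted to
#' one component's categories (8-connectivity by default, the common
#' raster-analysis convention; 4-connectivity available). Patch perimeter
#' counts every cell edge adjacent to a different category, an
#' outside-buffer cell, or the grid border.
#'
#' @param mosaic A [landscape_mosaic()].
#' @param component `"natural"` or `"production"`.
#' @param connectivity 8 (default) or 4.
#' @return Data frame with one row per patch: `id`, `code`, `cells`,
#'   `area_ha`, `perimeter_edges` (cell-edge count) and `perimeter_m`.
#'   Zero rows when the component is absent.
#' @export
label_patches <- function(mosaic, component, connectivity = 8L) {
  stopifnot(inherits(mosaic, "landscape_mosaic"))
  g <- mosaic$grid
  codes <- component_codes(mosaic, component)
  mask <- matrix(g %in% codes, nrow(g), ncol(g))
  if (!any(mask))
    return(data.frame(id = integer(), code = integer(), cells = integer(),
                      area_ha = numeric(), perimeter_edges = integer(),
                      perimeter_m = numeric()))

  # min-label propagation: seed each component cell with its own index and
  # repeatedly take the minimum over same-category neighbours until stable
  lab <- matrix(0L, nrow(g), ncol(g))
  lab[mask] <- which(mask)
  offs <- neighbour_offsets(as.integer(connectivity))
  repeat {
    changed <- FALSE
    for (o in offs) {
      nl <- shift_mat(lab, o[1L], o[2L], fill = 0L)
      ng <- shift_mat(g, o[1L], o[2L], fill = -1L)
      ok <- mask & nl > 0L & ng == g
      upd <- ok & nl < lab
      if (any(upd)) {
        lab[upd] <- nl[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  # per-cell perimeter contribution over the 4 orthogonal sides
  perim_cell <- matrix(0L, nrow(g), ncol(g))
  for (o in neighbour_offsets(4L)) {
    ng <- shift_mat(g, o[1L], o[2L], fill = -1L)  # -1 = beyond grid border
    perim_cell <- perim_cell + (mask & ng != g)
  }

  ids <- sort(unique(lab[mask]))
  relab <- match(lab[mask], ids)
  cells <- tabulate(relab, nbins = length(ids))
  perim <- as.integer(tapply(perim_cell[mask], relab, sum))
  code <- as.integer(g[mask][match(seq_along(ids), relab)])
  data.frame(
    id = seq_along(ids),
    code = code,
    cells = cells,
    area_ha = cells * mosaic$cell_size^2 / 1e4,
    perimeter_edges = perim,
    perimeter_m = perim * mosaic$cell_size
  )
}

#' Proportional cover per land-cover category
#'
#' @param mosaic A [landscape_mosaic()].
#' @return Named numeric vector, one entry per category in the map, in
#'   percent of buffer area; entries sum to 100.
#' @export
composition <- function(mosaic) {
  stopifnot(inherits(mosaic, "landscape_mosaic"))
  g <- mosaic$grid
  n_buf <- sum(g != 0L)
  if (n_buf == 0L) stop("empty buffer: no nonzero cells")
  cm <- mosaic$category_map
  counts <- vapply(cm$code, function(cd) sum(g == cd), numeric(1L))
  stats::setNames(100 * counts / n_buf, cm$name)
}

#' Compositional heterogeneity of one landscape component
#'
#' Richness is the number of component categories present; diversity is
#' Shannon entropy H = -sum p_i log p_i with proportions taken relative to
#' the component's own area; evenness is Pielou's H / log(richness), defined
#' as 0 when richness <= 1. All three are 0 for an absent component.
#'
#' @inheritParams label_patches
#' @return Named list `richness`, `diversity`, `evenness`.
#' @export
compositional_heterogeneity <- function(mosaic, component) {
  stopifnot(inherits(mosaic, "landscape_mosaic"))
  g <- mosaic$grid
  codes <- component_codes(mosaic, component)
  counts <- vapply(codes, function(cd) sum(g == cd), numeric(1L))
  counts <- counts[counts > 0]
  if (!length(counts))
    return(list(richness = 0, diversity = 0, evenness = 0))
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  S <- length(counts)
  list(richness = S, diversity = H,
       evenness = if (S > 1L) H / log(S) else 0)
}

#' Configurational heterogeneity of one landscape component
#'
#' Four patch-structure metrics: largest patch index (largest patch area as
#' a percentage of buffer area), mean patch size (ha), edge density (m/ha)
#' and mean shape index. Edge density counts internal edges between two
#' in-buffer cells of different categories where at least one cell belongs
#' to the component, each edge once; buffer boundary and grid border are
#' excluded (they contribute to patch perimeter only). The shape index is
#' the raster form 0.25 P / sqrt(A) in cell units, 1 for a square patch.
#' All four metrics are 0 for an absent component.
#'
#' @inheritParams label_patches
#' @return Named list `lpi`, `mean_patch_size`, `edge_density`,
#'   `shape_index`.
#' @export
configurational_heterogeneity <- function(mosaic, component,
                                          connectivity = 8L) {
  stopifnot(inherits(mosaic, "landscape_mosaic"))
  g <- mosaic$grid
  n_buf <- sum(g != 0L)
  if (n_buf == 0L) stop("empty buffer: no nonzero cells")
  buf_ha <- n_buf * mosaic$cell_size^2 / 1e4
  patches <- label_patches(mosaic, component, connectivity)
  if (nrow(patches) == 0L)
    return(list(lpi = 0, mean_patch_size = 0, edge_density = 0,
                shape_index = 0))
  codes <- component_codes(mosaic, component)

  edge_len <- 0
  # horizontal neighbours (side by side in a row)
  a <- g[, -ncol(g), drop = FALSE]; b <- g[, -1L, drop = FALSE]
  sel <- a != 0L & b != 0L & a != b & (a %in% codes | b %in% codes)
  edge_len <- edge_len + sum(sel)
  # vertical neighbours
  a <- g[-nrow(g), , drop = FALSE]; b <- g[-1L, , drop = FALSE]
  sel <- a != 0L & b != 0L & a != b & (a %in% codes | b %in% codes)
  edge_len <- edge_len + sum(sel)
  edge_m <- edge_len * mosaic$cell_size

  list(
    lpi = 100 * max(patches$area_ha) / buf_ha,
    mean_patch_size = mean(patches$area_ha),
    edge_density = edge_m / buf_ha,
    shape_index = mean(0.25 * patches$perimeter_edges /
                         sqrt(patches$cells))
  )
}

#' Names, sets and transforms of the 24 landscape variables
#'
#' The analysis uses 24 variables in six sets: per component the
#' composition block (five category covers, percent of buffer), the
#' compositional-heterogeneity block (cover richness, Shannon diversity,
#' Pielou evenness) and the configurational-heterogeneity block (largest
#' patch index, mean patch size, edge density, mean shape index).
#' Proportional variables (covers, LPI, evenness) receive the angular
#' transform; continuous/count variables receive log(x + 1).
#'
#' @param category_map Category map defining the cover variables.
#' @return Data frame with columns `variable`, `set`, `transform`
#'   (`"angular"` or `"log"`) and `scale` (divisor applied before the
#'   angular transform; 100 for percent variables).
#' @export
variable_info <- function(category_map = default_category_map()) {
  check_category_map(category_map)
  nat <- category_map$name[category_map$component == "natural"]
  prod <- category_map$name[category_map$component == "production"]
  het <- function(pre, set_c, set_g) data.frame(
    variable = paste0(pre, c("cover_richness", "cover_diversity",
                             "cover_evenness", "lpi", "mean_patch_size",
                             "edge_density", "shape_index")),
    set = c(rep(set_c, 3L), rep(set_g, 4L)),
    transform = c("log", "log", "angular", "angular", "log", "log", "log"),
    scale = c(1, 1, 1, 100, 1, 1, 1),
    stringsAsFactors = FALSE
  )
  rbind(
    data.frame(variable = nat, set = "nat_comp", transform = "angular",
               scale = 100, stringsAsFactors = FALSE),
    data.frame(variable = prod, set = "prod_comp", transform = "angular",
               scale = 100, stringsAsFactors = FALSE),
    het("nat_", "nat_compos_het", "nat_config_het"),
    het("prod_", "prod_compos_het", "prod_config_het")
  )
}

#' The six a priori variable sets
#'
#' @inheritParams variable_info
#' @return Named list of character vectors partitioning the 24 variables
#'   into the six sets used by the candidate-model design.
#' @export
variable_sets <- function(category_map = default_category_map()) {
  vi <- variable_info(category_map)
  split(vi$variable, factor(vi$set, levels = unique(vi$set)))
}

#' All 24 landscape variables for one mosaic
#'
#' @inheritParams label_patches
#' @return Named numeric vector of the 24 variables of [variable_info()].
#' @export
landscape_metrics <- function(mosaic, connectivity = 8L) {
  stopifnot(inherits(mosaic, "landscape_mosaic"))
  comp <- composition(mosaic)
  out <- as.list(comp)
  for (cmp in c("natural", "production")) {
    pre <- if (cmp == "natural") "nat_" else "prod_"
    ch <- compositional_heterogeneity(mosaic, cmp)
    gh <- configurational_heterogeneity(mosaic, cmp, connectivity)
    out[[paste0(pre, "cover_richness")]] <- ch$richness
    out[[paste0(pre, "cover_diversity")]] <- ch$diversity
    out[[paste0(pre, "cover_evenness")]] <- ch$evenness
    out[[paste0(pre, "lpi")]] <- gh$lpi
    out[[paste0(pre, "mean_patch_size")]] <- gh$mean_patch_size
    out[[paste0(pre, "edge_density")]] <- gh$edge_density
    out[[paste0(pre, "shape_index")]] <- gh$shape_index
  }
  vi <- variable_info(mosaic$category_map)
  unlist(out)[vi$variable]
}

#' Metric table for a collection of mosaics
#'
#' @param mosaics Named list of [landscape_mosaic()] objects; names must be
#'   `"<site_id>.<period>"`, or supply `site_id`/`period` explicitly.
#' @param site_id,period Optional character vectors overriding the parsed
#'   names.
#' @param connectivity Patch connectivity, 8 or 4.
#' @return Data frame with `site_id`, `period` and the 24 variable columns.
#' @export
metric_table <- function(mosaics, site_id = NULL, period = NULL,
                         connectivity = 8L) {
  stopifnot(is.list(mosaics), length(mosaics) > 0L)
  if (is.null(site_id) || is.null(period)) {
    nm <- names(mosaics)
    if (is.null(nm) || any(!grepl(".", nm, fixed = TRUE)))
      stop("supply site_id and period, or name mosaics '<site>.<period>'")
    parts <- strsplit(nm, ".", fixed = TRUE)
    site_id <- vapply(parts, `[[`, character(1L), 1L)
    period <- vapply(parts, function(p) paste(p[-1L], collapse = "."),
                     character(1L))
  }
  rows <- lapply(mosaics, landscape_metrics, connectivity = connectivity)
  out <- cbind(
    data.frame(site_id = site_id, period = period,
               stringsAsFactors = FALSE),
    as.data.frame(do.call(rbind, rows), row.names = FALSE)
  )
  rownames(out) <- NULL
  out
}
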