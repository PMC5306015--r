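#' Default land-cover category map
#'
#' Eleven integer codes describe each 250-m buffer: code 0 marks cells
#' outside the buffer, codes 1-5 the natural component (woodlands, open
#' woodlands, shrublands, streams, water bodies) and codes 6-10 the
#' production component (arable land with scattered trees, annual dry crops
#' and fallows, permanent pastures, annual irrigated crops, permanent
#' crops).
#'
#' @return A data frame with columns `code`, `name` and `component`
#'   (`"natural"` or `"production"`).
#' @export
default_category_map <- function() {
  data.frame(
    code = 1:10,
    name = c("woodland", "open_woodland", "shrubland", "streams",
             "water_bodies",
             "arable_scattered_trees", "annual_dry_crops",
             "permanent_pastures", "annual_irrigated_crops",
             "permanent_crops"),
    component = rep(c("natural", "production"), each = 5),
    stringsAsFactors = FALSE
  )
}

check_category_map <- function(category_map) {
  stopifnot(is.data.frame(category_map))
  need <- c("code", "name", "component")
  if (!all(need %in% names(category_map)))
    stop("category_map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(category_map$code))
    stop("duplicated category codes in category_map")
  if (any(category_map$code == 0))
    stop("code 0 is reserved for outside-buffer cells")
  if (!all(category_map$component %in% c("natural", "production")))
    stop("component must be 'natural' or 'production'")
  invisible(category_map)
}

#' Construct a landscape mosaic
#'
#' A mosaic is a categorical raster for one site and period: an integer
#' matrix of land-cover codes (0 = outside the buffer), the cell size in
#' metres, and a category map assigning each nonzero code a name and a
#' landscape component.
#'
#' @param grid Integer matrix of category codes; 0 marks cells outside the
#'   buffer.
#' @param cell_size Cell side length in metres (> 0).
#' @param category_map Data frame as returned by [default_category_map()].
#' @param xllcorner,yllcorner Grid origin, kept for raster round trips.
#' @return An object of class `landscape_mosaic`.
#' @export
landscape_mosaic <- function(grid, cell_size,
                             category_map = default_category_map(),
                             xllcorner = 0, yllcorner = 0) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  if (any(grid != round(grid)))
    stop("mosaic grid must contain integer category codes")
  storage.mode(grid) <- "integer"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  check_category_map(category_map)
  codes <- sort(unique(grid[grid != 0L]))
  unknown <- setdiff(codes, category_map$code)
  if (length(unknown))
    stop("unknown category code(s) in grid: ",
         paste(unknown, collapse = ", "))
  m <- structure(
    list(grid = grid, cell_size = cell_size, category_map = category_map,
         xllcorner = xllcorner, yllcorner = yllcorner),
    class = "landscape_mosaic"
  )
  if (sum(grid != 0L) > 0L && !buffer_connected(grid))
    stop("buffer mask (nonzero cells) is not connected")
  m
}

# 8-connected check that the nonzero mask forms one region
buffer_connected <- function(grid) {
  mask <- grid != 0L
  idx <- which(mask)
  if (!length(idx)) return(TRUE)
  nr <- nrow(grid); nc <- ncol(grid)
  seen <- matrix(FALSE, nr, nc)
  stack <- idx[1L]
  seen[stack] <- TRUE
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    r <- ((cur - 1L) %% nr) + 1L
    c <- ((cur - 1L) %/% nr) + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (mask[rr, cc] && !seen[rr, cc]) {
        seen[rr, cc] <- TRUE
        stack <- c(stack, (cc - 1L) * nr + rr)
      }
    }
  }
  sum(seen) == length(idx)
}

#' @export
print.landscape_mosaic <- function(x, ...) {
  nb <- sum(x$grid != 0L)
  cat(sprintf(
    "landscape_mosaic: %d x %d cells of %g m (%d buffer cells, %.2f ha)\n",
    nrow(x$grid), ncol(x$grid), x$cell_size, nb,
    nb * x$cell_size^2 / 1e4))
  tab <- table(factor(x$grid[x$grid != 0L], levels = x$category_map$code))
  present <- tab[tab > 0]
  if (length(present)) {
    nm <- x$category_map$name[match(as.integer(names(present)),
                                    x$category_map$code)]
    cat("categories:",
        paste(sprintf("%s (%d)", nm, present), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line ESRI ASCII header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by row-major cell
#' values. NODATA cells are mapped to 0 (outside buffer).
#'
#' @param path Path to an `.asc` file.
#' @return A list with `grid`, `cell_size`, `xllcorner`, `yllcorner`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L) stop("malformed header line: ", lines[i])
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("missing header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cell values, got %d", nr * nc, length(vals)))
  if (any(vals != round(vals)))
    stop("non-integer raster values; categorical grid required")
  vals[vals == hdr$nodata_value] <- 0
  grid <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  list(grid = grid, cell_size = hdr$cellsize,
       xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner)
}

#' Read a mosaic from an ESRI ASCII grid file
#'
#' @param path Path to the raster file.
#' @param category_map Category map validating the codes in the file.
#' @return A [landscape_mosaic()].
#' @export
read_mosaic <- function(path, category_map = default_category_map()) {
  g <- read_ascii_grid(path)
  landscape_mosaic(g$grid, g$cell_size, category_map,
                   xllcorner = g$xllcorner, yllcorner = g$yllcorner)
}

#' Write a mosaic as an ESRI ASCII grid
#'
#' The header is written in fixed order so that a write/read/write cycle is
#' byte-identical. Outside-buffer cells (code 0) are written as the NODATA
#' value 0.
#'
#' @param mosaic A [landscape_mosaic()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "landscape_mosaic"))
  g <- mosaic$grid
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %s", format(mosaic$xllcorner, trim = TRUE)),
    sprintf("yllcorner %s", format(mosaic$yllcorner, trim = TRUE)),
    sprintf("cellsize %s", format(mosaic$cell_size, trim = TRUE)),
    "NODATA_value 0"
  )
  body <- apply(g, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
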