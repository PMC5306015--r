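#' Default survey period windows
#'
#' Two three-year windows bracketing the 2003 CAP reform: T0 = 1995-1997
#' (before) and T1 = 2010-2012 (after). Windows are configuration, not a
#' constant of the method.
#'
#' @return Named list of integer year vectors.
#' @export
default_period_windows <- function() {
  list(T0 = 1995:1997, T1 = 2010:2012)
}

check_period_windows <- function(period_windows) {
  if (!is.list(period_windows) || is.null(names(period_windows)) ||
      any(names(period_windows) == ""))
    stop("period_windows must be a named list of year vectors")
  yrs <- unlist(period_windows)
  if (anyDuplicated(yrs))
    stop("period windows overlap: year(s) ",
         paste(unique(yrs[duplicated(yrs)]), collapse = ", "))
  invisible(period_windows)
}

#' Species richness per site, period and habitat group
#'
#' Pools survey records within each period window and counts distinct
#' species per transect. Four richness columns are produced: `all`
#' (every non-excluded species), and the habitat groups `woodland`,
#' `farmland` and `steppe`. Steppe birds are open-grassland farmland
#' specialists; when `steppe_within_farmland` is `TRUE` (the default)
#' steppe-tagged species also count toward the farmland column. Species
#' tagged `excluded` (aquatic birds, inadequately sampled by transects)
#' never count in any column.
#'
#' @param records Data frame with columns `site_id`, `year`, `species`.
#' @param groups Data frame with columns `species` and `group`, the latter
#'   one of `"woodland"`, `"farmland"`, `"steppe"`, `"excluded"`; exactly
#'   one row per surveyed species.
#' @param period_windows Named list of year vectors; see
#'   [default_period_windows()].
#' @param steppe_within_farmland Logical; count steppe species in the
#'   farmland column as well.
#' @return Data frame with columns `site_id`, `period`, `group`,
#'   `richness`, complete over all combinations (zeros where a group was
#'   absent).
#' @export
richness <- function(records, groups,
                     period_windows = default_period_windows(),
                     steppe_within_farmland = TRUE) {
  stopifnot(is.data.frame(records), is.data.frame(groups))
  need_r <- c("site_id", "year", "species")
  if (!all(need_r %in% names(records)))
    stop("records needs columns: ", paste(need_r, collapse = ", "))
  if (!all(c("species", "group") %in% names(groups)))
    stop("groups needs columns: species, group")
  valid_tags <- c("woodland", "farmland", "steppe", "excluded")
  bad_tag <- setdiff(unique(groups$group), valid_tags)
  if (length(bad_tag))
    stop("unknown group tag(s): ", paste(bad_tag, collapse = ", "))
  if (anyDuplicated(groups$species))
    stop("duplicated species in group table: ",
         paste(unique(groups$species[duplicated(groups$species)]),
               collapse = ", "))
  if (any(!nzchar(as.character(records$species))))
    stop("empty species identifiers in records")
  check_period_windows(period_windows)

  year_to_period <- function(y) {
    for (p in names(period_windows))
      if (y %in% period_windows[[p]]) return(p)
    NA_character_
  }
  period <- vapply(records$year, year_to_period, character(1L))
  if (anyNA(period)) {
    bad <- which(is.na(period))
    stop("record year(s) outside all period windows: ",
         paste(sprintf("(site %s, year %d, species %s)",
                       records$site_id[bad], records$year[bad],
                       records$species[bad]),
               collapse = "; "))
  }
  tag <- groups$group[match(records$species, groups$species)]
  if (anyNA(tag))
    stop("species missing from group table: ",
         paste(unique(records$species[is.na(tag)]), collapse = ", "))

  sites <- sort(unique(as.character(records$site_id)))
  periods <- names(period_windows)
  out_groups <- c("all", "woodland", "farmland", "steppe")

  member <- function(g) {
    switch(g,
      all      = tag != "excluded",
      woodland = tag == "woodland",
      farmland = if (steppe_within_farmland) tag %in% c("farmland", "steppe")
                 else tag == "farmland",
      steppe   = tag == "steppe")
  }

  res <- expand.grid(site_id = sites, period = periods, group = out_groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$richness <- 0L
  for (g in out_groups) {
    keep <- member(g)
    if (!any(keep)) next
    key <- paste(records$site_id[keep], period[keep], sep = "\r")
    counts <- tapply(as.character(records$species[keep]), key,
                     function(s) length(unique(s)))
    rows <- res$group == g
    res_key <- paste(res$site_id, res$period, sep = "\r")
    hit <- match(res_key[rows], names(counts))
    res$richness[rows][!is.na(hit)] <-
      as.integer(counts[hit[!is.na(hit)]])
  }
  res[order(res$site_id, res$period, match(res$group, out_groups)), ,
      drop = FALSE] -> res
  rownames(res) <- NULL
  res
}
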