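#' Angular (arcsine square-root) transform for proportions
#'
#' Standard variance-stabilising transform for proportional data subject to
#' the unit-sum constraint: `asin(sqrt(p))`, mapping `[0, 1]` onto
#' `[0, pi/2]`.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Transformed values.
#' @export
angular <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  bad <- which(p < 0 | p > 1 | is.na(p))
  if (length(bad))
    stop("proportion(s) outside [0, 1]: ",
         paste(format(p[bad]), collapse = ", "))
  asin(sqrt(p))
}

#' Shifted log transform for non-negative continuous variables
#'
#' `log(x + offset)` with a default offset of 1, so that the frequent zero
#' values of landscape metrics map to 0 rather than -Inf.
#'
#' @param x Non-negative numeric vector.
#' @param offset Positive shift added before taking the log.
#' @return Transformed values.
#' @export
log_trans <- function(x, offset = 1) {
  if (!is.numeric(x)) stop("x must be numeric")
  bad <- which(x < 0 | is.na(x))
  if (length(bad))
    stop("negative or missing value(s): ",
         paste(format(x[bad]), collapse = ", "))
  log(x + offset)
}

apply_transforms <- function(metrics, vinfo, log_offset = 1) {
  X <- as.data.frame(metrics[, vinfo$variable, drop = FALSE])
  for (i in seq_len(nrow(vinfo))) {
    v <- vinfo$variable[i]
    if (vinfo$transform[i] == "angular") {
      p <- X[[v]] / vinfo$scale[i]
      if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("variable '", v, "' declared proportional but has values ",
             "outside [0, ", vinfo$scale[i], "]")
      X[[v]] <- angular(p)
    } else {
      X[[v]] <- log_trans(X[[v]], offset = log_offset)
    }
  }
  X
}

#' Build an analysis-ready predictor/response matrix
#'
#' Joins a metric table with a richness table into one modelling frame.
#' Proportional variables are angular-transformed, continuous variables
#' log(x+1)-transformed. In the two spatial modes the response is the
#' richness count of `group` in the chosen period. In temporal mode both
#' response and predictors are period differences (T1 minus T0); by
#' default predictors are differenced after transformation
#' (`delta_on = "transformed"`), with `delta_on = "raw"` differencing the
#' raw metrics first.
#'
#' @param metrics Data frame from [metric_table()].
#' @param responses Data frame from [richness()] (or a compatible
#'   `site_id`/`period`/`group`/`richness` table).
#' @param mode One of `"spatial_T0"`, `"spatial_T1"`, `"temporal"`.
#' @param group Response group: `"all"`, `"woodland"`, `"farmland"` or
#'   `"steppe"`.
#' @param vinfo Variable/transform declaration, see [variable_info()].
#' @param periods Character vector of the two period labels, T0 first.
#' @param delta_on `"transformed"` or `"raw"` (temporal mode only).
#' @param log_offset Offset of the log transform.
#' @return An object of class `analysis_matrix`: a data frame with
#'   `site_id`, `response` and one column per predictor, plus attributes
#'   `mode`, `group` and `family` (`"poisson_log"` for spatial counts,
#'   `"gaussian_identity"` for temporal differences).
#' @export
build_matrix <- function(metrics, responses,
                         mode = c("spatial_T0", "spatial_T1", "temporal"),
                         group = "all",
                         vinfo = variable_info(),
                         periods = c("T0", "T1"),
                         delta_on = c("transformed", "raw"),
                         log_offset = 1) {
  mode <- match.arg(mode)
  delta_on <- match.arg(delta_on)
  stopifnot(is.data.frame(metrics), is.data.frame(responses),
            length(periods) == 2L)
  miss <- setdiff(vinfo$variable, names(metrics))
  if (length(miss))
    stop("metric table lacks variable(s): ", paste(miss, collapse = ", "))
  resp <- responses[responses$group == group, , drop = FALSE]
  if (nrow(resp) == 0L) stop("no responses for group '", group, "'")

  get_period <- function(df, p, what) {
    sub <- df[df$period == p, , drop = FALSE]
    if (anyDuplicated(sub$site_id))
      stop("duplicated ", what, " rows for period ", p)
    sub
  }

  if (mode != "temporal") {
    p <- periods[if (mode == "spatial_T0") 1L else 2L]
    m <- get_period(metrics, p, "metric")
    r <- get_period(resp, p, "response")
    sites <- sort(unique(m$site_id))
    miss_m <- setdiff(r$site_id, m$site_id)
    miss_r <- setdiff(sites, r$site_id)
    if (length(miss_m) || length(miss_r))
      stop("site/period mismatch between metrics and responses: ",
           paste(c(miss_m, miss_r), collapse = ", "))
    m <- m[match(sites, m$site_id), , drop = FALSE]
    r <- r[match(sites, r$site_id), , drop = FALSE]
    X <- apply_transforms(m, vinfo, log_offset)
    out <- cbind(data.frame(site_id = sites,
                            response = as.numeric(r$richness),
                            stringsAsFactors = FALSE), X)
    family <- "poisson_log"
  } else {
    m0 <- get_period(metrics, periods[1L], "metric")
    m1 <- get_period(metrics, periods[2L], "metric")
    r0 <- get_period(resp, periods[1L], "response")
    r1 <- get_period(resp, periods[2L], "response")
    sites <- sort(Reduce(intersect, list(m0$site_id, m1$site_id,
                                         r0$site_id, r1$site_id)))
    all_sites <- unique(c(m0$site_id, m1$site_id, r0$site_id, r1$site_id))
    if (length(setdiff(all_sites, sites)))
      stop("site(s) missing a period: ",
           paste(setdiff(all_sites, sites), collapse = ", "))
    m0 <- m0[match(sites, m0$site_id), , drop = FALSE]
    m1 <- m1[match(sites, m1$site_id), , drop = FALSE]
    if (delta_on == "transformed") {
      X <- apply_transforms(m1, vinfo, log_offset) -
           apply_transforms(m0, vinfo, log_offset)
    } else {
      d <- m1[, vinfo$variable, drop = FALSE] -
           m0[, vinfo$variable, drop = FALSE]
      X <- as.data.frame(d)
    }
    dr <- as.numeric(r1$richness[match(sites, r1$site_id)]) -
          as.numeric(r0$richness[match(sites, r0$site_id)])
    out <- cbind(data.frame(site_id = sites, response = dr,
                            stringsAsFactors = FALSE), X)
    family <- "gaussian_identity"
  }
  if (anyNA(out)) stop("missing values in analysis matrix")
  rownames(out) <- NULL
  structure(out, mode = mode, group = group, family = family,
            class = c("analysis_matrix", "data.frame"))
}

#' Paired t-test of temporal change
#'
#' Classical paired t-test (wrapping [stats::t.test()]) of the differences
#' `y - x`, used to describe temporal change of each landscape variable
#' between periods.
#'
#' @param x,y Numeric vectors of equal length (period 1 and period 2).
#' @return List with `t`, `p`, `mean_diff`, `se`, `df`.
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two pairs")
  d <- y - x
  if (stats::sd(d) == 0)
    stop("zero variance of differences: paired t statistic undefined")
  tt <- stats::t.test(y, x, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), se = unname(tt$stderr),
       df = unname(tt$parameter))
}
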