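glm_family <- function(family) {
  switch(family,
    poisson_log = stats::poisson(link = "log"),
    gaussian_identity = stats::gaussian(link = "identity"),
    stop("unknown family: ", family))
}

#' Fit one candidate GLM
#'
#' Maximum-likelihood fit of a species-richness model: Poisson errors with
#' log link for spatial richness counts, Gaussian errors with identity link
#' for temporal richness differences. The parameter count `k` includes the
#' intercept and, for the Gaussian family, the residual variance (both
#' taken from the exact model log-likelihood), so AICc is comparable
#' across candidate models.
#'
#' @param matrix An [build_matrix()] result (or any data frame with a
#'   `response` column and predictor columns).
#' @param variables Character vector of predictor names; empty for the
#'   intercept-only model.
#' @param family `"poisson_log"` or `"gaussian_identity"`; defaults to the
#'   matrix's `family` attribute.
#' @return An object of class `model_fit`: list with `variables`,
#'   `coefficients`, `loglik`, `k`, `n`, `aicc`, `dispersion` (Pearson
#'   chi-square / (n - p)), `family` and the underlying `glm` object.
#' @export
fit_glm <- function(matrix, variables = character(),
                    family = attr(matrix, "family")) {
  if (is.null(family)) stop("family must be given")
  stopifnot(is.data.frame(matrix), "response" %in% names(matrix))
  miss <- setdiff(variables, names(matrix))
  if (length(miss))
    stop("variable(s) not in matrix: ", paste(miss, collapse = ", "))
  n <- nrow(matrix)
  if (length(variables)) {
    X <- as.matrix(matrix[, variables, drop = FALSE])
    qrX <- qr(cbind(1, X))
    if (qrX$rank < ncol(X) + 1L) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      dropped <- setdiff(seq_len(ncol(X) + 1L), keep) - 1L
      stop("rank-deficient design; collinear column(s): ",
           paste(variables[dropped], collapse = ", "))
    }
  }
  fml <- if (length(variables))
    stats::reformulate(sprintf("`%s`", variables), response = "response")
  else response ~ 1
  fit <- stats::glm(fml, family = glm_family(family), data = matrix)
  if (!fit$converged)
    stop("GLM did not converge after ", fit$iter, " iterations (family ",
         family, ", ", length(variables), " predictors)")
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")          # counts intercept, slopes, sigma if Gaussian
  p <- length(stats::coef(fit))
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / (n - p)
  structure(
    list(variables = variables,
         coefficients = stats::coef(fit),
         loglik = as.numeric(ll), k = k, n = n,
         aicc = aicc(as.numeric(ll), k, n),
         dispersion = disp, family = family, glm = fit),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit (%s): %d predictor(s), n = %d\n", x$family,
              length(x$variables), x$n))
  cat(sprintf("  logLik = %.3f, k = %d, AICc = %.3f, dispersion = %.3f\n",
              x$loglik, x$k, x$aicc, x$dispersion))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param LL Model log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(LL, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * LL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights of a candidate-model list
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min AICc`; interpretable as model probabilities.
#'
#' @param aicc_values Numeric vector of AICc values, one per candidate.
#' @return Weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || any(!is.finite(aicc_values)))
    stop("aicc_values must be a non-empty finite numeric vector")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Enumerate the stage-1 candidate-model design
#'
#' All non-empty combinations of the variable sets: with six sets this is
#' the 63-model a priori design in which every set appears in exactly 32
#' candidates and every variable meets every other variable in some model.
#'
#' @param sets Named list of disjoint, non-empty character vectors (the
#'   variable sets).
#' @return List of candidates; each element has `sets` (names) and
#'   `variables` (union of member variables).
#' @export
enumerate_stage1 <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  if (any(lengths(sets) == 0L)) stop("empty variable set")
  allv <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(allv))
    stop("variable sets overlap: ",
         paste(unique(allv[duplicated(allv)]), collapse = ", "))
  m <- length(sets)
  out <- vector("list", 2^m - 1L)
  for (i in seq_len(2^m - 1L)) {
    in_set <- bitwAnd(i, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    out[[i]] <- list(sets = names(sets)[in_set],
                     variables = unlist(sets[in_set], use.names = FALSE))
  }
  out
}

#' Stage-1 screen: summed Akaike weights per variable set
#'
#' Fits every candidate of the set design, computes Akaike weights, and
#' sums them over the models containing each set (`w_plus`, written w_i+).
#' Sets with `w_plus` above the screening threshold (0.5) are retained for
#' stage-2 variable-level averaging.
#'
#' @inheritParams fit_glm
#' @param sets Named list of variable sets; see [variable_sets()].
#' @param threshold Retention threshold on `w_plus`.
#' @return Data frame with `set`, `w_plus`, `retained`; attribute
#'   `candidates` holds the per-model log (sets, k, AICc, weight).
#' @export
stage1_screen <- function(matrix, sets = variable_sets(),
                          family = attr(matrix, "family"),
                          threshold = 0.5) {
  cand <- enumerate_stage1(sets)
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    fits[[i]] <- tryCatch(
      fit_glm(matrix, cand[[i]]$variables, family),
      error = function(e)
        stop("candidate {", paste(cand[[i]]$sets, collapse = " + "),
             "} failed: ", conditionMessage(e)))
  }
  aiccs <- vapply(fits, `[[`, numeric(1L), "aicc")
  w <- akaike_weights(aiccs)
  w_plus <- vapply(names(sets), function(s)
    sum(w[vapply(cand, function(cd) s %in% cd$sets, logical(1L))]),
    numeric(1L))
  res <- data.frame(set = names(sets), w_plus = unname(w_plus),
                    retained = unname(w_plus) > threshold,
                    stringsAsFactors = FALSE)
  log <- data.frame(
    model = vapply(cand, function(cd) paste(cd$sets, collapse = "+"),
                   character(1L)),
    n_variables = vapply(cand, function(cd) length(cd$variables),
                         integer(1L)),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1L)),
    aicc = aiccs, weight = w, stringsAsFactors = FALSE)
  attr(res, "candidates") <- log
  attr(res, "fits") <- fits
  res
}

#' Variance inflation factors of a design
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor j
#' on the remaining predictors; 1 for a lone predictor. Computed from the
#' inverse correlation matrix.
#'
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column).
#' @return Named vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (any(apply(X, 2L, stats::sd) == 0))
    stop("constant predictor column; VIF undefined")
  if (ncol(X) == 1L)
    return(stats::setNames(1, colnames(X)))
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv) || any(!is.finite(diag(inv))) || any(diag(inv) > 1e12))
    stop("perfect collinearity among predictors: infinite VIF")
  stats::setNames(diag(inv), colnames(X))
}

#' Partial standard deviations of predictors
#'
#' The partial SD shrinks each predictor's sample SD by its variance
#' inflation factor and a degrees-of-freedom factor:
#' `s*_j = s_j sqrt(1 / VIF_j) sqrt((n - 1) / (n - p))`, with `p` the
#' number of estimated mean-structure coefficients, counting the intercept
#' (configurable via `count_intercept`). Multiplying an unstandardized GLM
#' coefficient by its partial SD yields a standardized coefficient that
#' remains comparable across models with different collinearity structure.
#'
#' @inheritParams vif
#' @param n Sample size; must exceed `p`.
#' @param count_intercept Logical; include the intercept in `p`.
#' @return Named vector of partial SDs.
#' @export
partial_sd <- function(design, n, count_intercept = TRUE) {
  X <- as.matrix(design)
  p <- ncol(X) + as.integer(count_intercept)
  if (n <= p)
    stop("partial SD undefined: need n > p (n = ", n, ", p = ", p, ")")
  v <- vif(X)
  s <- apply(X, 2L, stats::sd)
  s * sqrt(1 / v) * sqrt((n - 1) / (n - p))
}

model_standardized <- function(fit, matrix, response_sd_scale,
                               count_intercept = TRUE) {
  vars <- fit$variables
  X <- as.matrix(matrix[, vars, drop = FALSE])
  psd <- partial_sd(X, fit$n, count_intercept)
  b <- fit$coefficients[sprintf("`%s`", vars)]
  if (anyNA(b)) b <- fit$coefficients[vars]
  std <- unname(b) * unname(psd)
  if (fit$family == "gaussian_identity" && response_sd_scale)
    std <- std / stats::sd(matrix$response)
  names(std) <- vars
  std
}

#' Stage-2 model averaging of partial standardized coefficients
#'
#' Enumerates all subsets (including the intercept-only model) of the
#' variables in the retained sets, fits each candidate, and computes for
#' every variable in every model its partial standardized coefficient
#' (coefficient times partial SD) and its relative importance, the ratio of
#' its absolute standardized coefficient to the largest absolute
#' standardized coefficient in that model (so the dominant variable of each
#' model scores exactly 1; ties share the 1). Both quantities are then
#' averaged across the models containing the variable with Akaike weights
#' renormalized over those models (conditional averaging).
#'
#' @inheritParams fit_glm
#' @param retained_sets Named list of retained variable sets (e.g. the
#'   `retained` rows of [stage1_screen()] mapped back through
#'   [variable_sets()]).
#' @param response_sd_scale Logical; for Gaussian models additionally
#'   divide standardized coefficients by the response SD so they are
#'   comparable across responses.
#' @param count_intercept Passed to [partial_sd()].
#' @param max_variables Guard on the subset enumeration (2^v candidates).
#' @return An object of class `averaged_model`: data frame with
#'   `variable`, `avg_coef` (averaged partial standardized coefficient),
#'   `importance` (averaged relative importance), `w_plus` (variable-level
#'   summed weight); attributes `pseudo_r2` (deviance-based, from the
#'   global model), `n_models`, and the candidate log.
#' @export
stage2_average <- function(matrix, retained_sets,
                           family = attr(matrix, "family"),
                           response_sd_scale = TRUE,
                           count_intercept = TRUE,
                           max_variables = 20L) {
  stopifnot(is.list(retained_sets), length(retained_sets) >= 1L)
  vars <- unlist(retained_sets, use.names = FALSE)
  if (anyDuplicated(vars)) stop("retained sets overlap")
  v <- length(vars)
  if (v > max_variables)
    stop(v, " variables would give 2^", v, " candidates; raise ",
         "max_variables to allow this")
  nmod <- 2^v
  fits <- vector("list", nmod)
  aiccs <- numeric(nmod)
  member <- base::matrix(FALSE, nmod, v, dimnames = list(NULL, vars))
  for (i in seq_len(nmod)) {
    in_m <- bitwAnd(i - 1L, bitwShiftL(1L, seq_len(v) - 1L)) > 0L
    member[i, ] <- in_m
    fits[[i]] <- fit_glm(matrix, vars[in_m], family)
    aiccs[i] <- fits[[i]]$aicc
  }
  w <- akaike_weights(aiccs)

  std <- base::matrix(NA_real_, nmod, v, dimnames = list(NULL, vars))
  imp <- base::matrix(NA_real_, nmod, v, dimnames = list(NULL, vars))
  for (i in seq_len(nmod)) {
    if (!any(member[i, ])) next
    s <- model_standardized(fits[[i]], matrix, response_sd_scale,
                            count_intercept)
    std[i, names(s)] <- s
    imp[i, names(s)] <- abs(s) / max(abs(s))
  }

  avg_coef <- avg_imp <- wp <- numeric(v)
  for (j in seq_len(v)) {
    in_j <- member[, j]
    wj <- w[in_j]
    wp[j] <- sum(wj)
    wj <- wj / sum(wj)
    avg_coef[j] <- sum(wj * std[in_j, j])
    avg_imp[j] <- sum(wj * imp[in_j, j])
  }

  global <- fits[[nmod]]$glm   # last candidate = all variables
  pseudo_r2 <- 1 - global$deviance / global$null.deviance
  res <- data.frame(variable = vars, avg_coef = avg_coef,
                    importance = avg_imp, w_plus = wp,
                    stringsAsFactors = FALSE)
  structure(res,
            pseudo_r2 = pseudo_r2, n_models = nmod,
            candidates = data.frame(
              aicc = aiccs, weight = w,
              n_variables = rowSums(member)),
            class = c("averaged_model", "data.frame"))
}

#' @export
print.averaged_model <- function(x, digits = 3, ...) {
  cat(sprintf(
    "averaged_model over %d candidates (pseudo-R2 of global model: %.3f)\n",
    attr(x, "n_models"), attr(x, "pseudo_r2")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
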