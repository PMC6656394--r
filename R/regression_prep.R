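# Turning direct size estimates into regression data.
#
# Each direct estimate n_ij (method j in area i) becomes a log-fraction
# response y_ij = log(n_ij / N_i), where N_i is the male 18-29 population of
# the area. The 95% CI of n_ij maps to a CI of y_ij whose squared log-width
# w_ij = (log ci_high - log ci_low)^2 is proportional to the sampling variance
# of y_ij, giving the heteroscedastic model y_ij ~ N(x_i' beta, tau^2 w_ij):
# wide, imprecise direct estimates are down-weighted.

#' Young-male population from a total male count
#'
#' Applies a constant age-structure assumption: a fixed fraction of the total
#' male population is aged 18--29 (default 55%, the assumption used when no
#' department-level age-stratified data exist). The fraction is exposed as a
#' parameter because published department totals are not always consistent
#' with a single value.
#'
#' @param total_male total male population count (> 0), vectorized.
#' @param fraction proportion aged 18--29, in (0, 1].
#' @return Rounded person count(s).
#' @export
derive_young_male_population <- function(total_male, fraction = 0.55) {
  if (any(!is.finite(total_male)) || any(total_male <= 0))
    stop("total_male must be positive")
  if (length(fraction) != 1L || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  round(fraction * total_male)
}

#' Log fraction of the young-male population
#'
#' `y = log(n_hat / N_male)`, the response of the extrapolation regression.
#'
#' @param n_hat direct size estimate(s), persons, > 0.
#' @param N_male male 18--29 population of the area, persons, > 0.
#' @export
to_log_fraction <- function(n_hat, N_male) {
  if (any(n_hat <= 0)) stop("n_hat must be positive")
  if (any(N_male <= 0)) stop("N_male must be positive")
  log(n_hat / N_male)
}

#' Squared log-width variance weight from a confidence interval
#'
#' The variance of a normal variable is proportional to the square of its 95%
#' inter-quantile range, so each observation's variance is modelled as
#' tau^2 * w with `w = (log(ci_high) - log(ci_low))^2`. Since
#' `log(ci/N) - log(ci'/N) = log(ci/ci')`, the weight depends only on the
#' ratio of the CI bounds and is invariant to the population denominator.
#'
#' @param ci_low,ci_high 95% CI bounds of the direct estimate, persons,
#'   `0 < ci_low < ci_high`. Vectorized.
#' @return Positive weight(s) `w`.
#' @export
ci_to_weight <- function(ci_low, ci_high) {
  if (any(ci_low <= 0)) stop("ci_low must be positive")
  if (any(ci_low >= ci_high))
    stop("ci_low must be strictly below ci_high (zero-width intervals give a zero-variance observation, unsupported)")
  (log(ci_high) - log(ci_low))^2
}

#' Build the regression observations from direct estimates
#'
#' Joins direct estimates to the area table and computes the response `y` and
#' weight `w` for each estimate. Multiple direct estimates in one area are
#' treated as independent given the area covariates.
#'
#' @param estimates data.frame with `area_id`, `method_label`, `n_hat`,
#'   `ci_low`, `ci_high`.
#' @param areas area table with `area_id` and `male_pop_18_29`.
#' @return data.frame with `area_id`, `method_label`, `y`, `w`.
#' @export
prepare_regression_data <- function(estimates, areas) {
  .check_area_table(areas, require = c("area_id", "male_pop_18_29"))
  need <- c("area_id", "method_label", "n_hat", "ci_low", "ci_high")
  miss <- setdiff(need, names(estimates))
  if (length(miss)) stop("estimates lack column(s): ", paste(miss, collapse = ", "))
  idx <- match(estimates$area_id, areas$area_id)
  if (anyNA(idx))
    stop("estimates reference unknown area_id: ",
         paste(unique(estimates$area_id[is.na(idx)]), collapse = ", "))
  N <- areas$male_pop_18_29[idx]
  data.frame(area_id = estimates$area_id,
             method_label = estimates$method_label,
             y = to_log_fraction(estimates$n_hat, N),
             w = ci_to_weight(estimates$ci_low, estimates$ci_high),
             stringsAsFactors = FALSE)
}

# resolve a covariate name to a numeric column of the area table
.covariate_column <- function(areas, name) {
  val <- switch(name,
    log_male_pop = log(areas$male_pop_18_29),
    hiv_prev = areas$hiv_prev_pct,
    log_pop_density = log(areas$pop_density),
    log_landscan = log(areas$landscan_density),
    density_change = areas$density_change,
    areas[[name]])
  if (is.null(val)) stop("unknown covariate '", name, "'")
  val
}

#' Area-level design matrix
#'
#' One row per area: an intercept followed by the requested covariates.
#' Recognized names: `log_male_pop` (log of `male_pop_18_29`), `hiv_prev`
#' (HIV prevalence, percent scale), `log_pop_density`, `log_landscan`,
#' `density_change`; any other name is taken verbatim from the area table.
#'
#' @param areas area table.
#' @param covariates character vector of covariate names; default the final
#'   model, log male population and HIV prevalence.
#' @param require_complete if `TRUE` (training use) an `NA` covariate value is
#'   an error; set `FALSE` for prediction-time areas whose prevalence will be
#'   imputed.
#' @return Numeric matrix with rownames `area_id` and an intercept column.
#' @export
build_design <- function(areas, covariates = c("log_male_pop", "hiv_prev"),
                         require_complete = TRUE) {
  .check_area_table(areas, require = "area_id")
  cols <- lapply(covariates, function(nm) .covariate_column(areas, nm))
  X <- cbind(`(Intercept)` = rep(1, nrow(areas)))
  for (i in seq_along(cols)) X <- cbind(X, cols[[i]])
  colnames(X) <- c("(Intercept)", covariates)
  rownames(X) <- areas$area_id
  if (require_complete && nrow(X) && anyNA(X)) {
    bad <- which(apply(X, 1, anyNA))
    stop("missing covariate value(s) for training area(s): ",
         paste(rownames(X)[bad], collapse = ", "))
  }
  X
}

#' Population truncation threshold for prediction
#'
#' Empirical `q`-quantile (linear interpolation between order statistics) of
#' the male 18--29 population across all prediction areas. At prediction time
#' the log-population covariate is floored at this threshold: the training
#' areas are all comparatively large, so the fitted negative population slope
#' is not extrapolated below the bulk of the population distribution.
#'
#' @param areas area table (at least 2 areas).
#' @param q quantile level in (0, 1), default 0.10.
#' @return Threshold in persons.
#' @export
population_truncation_threshold <- function(areas, q = 0.10) {
  .check_area_table(areas, require = c("area_id", "male_pop_18_29"))
  if (nrow(areas) < 2L) stop("need at least 2 areas")
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  unname(quantile(areas$male_pop_18_29, probs = q, type = 7))
}
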