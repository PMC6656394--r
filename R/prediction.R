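# Composition-sampling posterior prediction.
#
# Each retained MCMC draw is pushed through the predictive pipeline: for an
# area with observed prevalence the covariate H is fixed; for a missing-H
# area, H is drawn from the kriging conditional normal under that draw's GP
# parameters (so imputation uncertainty propagates into the prediction).
# The linear predictor uses the truncated log population covariate; the
# resulting fraction exp(y) is converted to a count with the area's true
# population (configurable).

#' Posterior predictive draws of key-population counts for all areas
#'
#' For each retained draw m: prevalence `H` is the observed value when
#' present, otherwise a draw from the kriging conditional given the observed
#' prevalence field under `(mu, sigma2, phi)` of draw m (negative draws
#' truncated at 0). Then
#' `y = beta0 + beta1 * log(max(N, threshold)) + beta2 * H` and the count
#' draw is `N * exp(y)`. By default missing-prevalence areas are imputed
#' independently given the observed field; `joint = TRUE` draws them jointly
#' from the full conditional covariance.
#'
#' @param areas area table of prediction areas.
#' @param draws a `kpsae_draws` object (or data.frame of posterior draws).
#' @param observed_areas areas supplying the observed prevalence field;
#'   defaults to the rows of `areas` with observed `hiv_prev_pct`.
#' @param threshold population truncation threshold (persons); defaults to
#'   [population_truncation_threshold] of `areas` at q = 0.10. Use 0 to
#'   disable.
#' @param seed optional seed for the imputation draws.
#' @param joint draw missing-prevalence areas jointly per iteration.
#' @param truncate_count_N if `TRUE`, the fraction-to-count conversion also
#'   uses the truncated population; default `FALSE` (truncation flattens the
#'   regression relationship but does not alter the area's size).
#' @return list of class `kpsae_prediction`: `counts` (draws x areas matrix),
#'   `hiv` (prevalence values used, draws x areas), `areas`, `threshold`.
#' @seealso [summarize_predictions], [predict_area]
#' @export
predict_msm <- function(areas, draws, observed_areas = NULL, threshold = NULL,
                        seed = NULL, joint = FALSE,
                        truncate_count_N = FALSE) {
  .check_area_table(areas)
  dr <- if (inherits(draws, "kpsae_draws")) draws$draws else as.data.frame(draws)
  if (nrow(dr) == 0L) stop("no posterior draws")
  if (is.null(observed_areas)) {
    observed_areas <- areas[!is.na(areas$hiv_prev_pct), , drop = FALSE]
  }
  if (is.null(threshold))
    threshold <- if (nrow(areas) >= 2L)
      population_truncation_threshold(areas, 0.10) else 0
  if (!is.null(seed)) set.seed(seed)

  M <- nrow(dr)
  n <- nrow(areas)
  H <- matrix(rep(areas$hiv_prev_pct, each = M), M, n)
  miss <- which(is.na(areas$hiv_prev_pct))
  if (length(miss)) {
    if (nrow(observed_areas) == 0L)
      stop("missing prevalence but no observed areas to krige from")
    Hobs <- observed_areas$hiv_prev_pct
    D <- .coord_dist(observed_areas)
    Dc <- .coord_dist(observed_areas, areas[miss, , drop = FALSE])
    nm <- length(miss)
    for (m in seq_len(M)) {
      U <- .chol_corr(D, dr$phi[m])
      z <- backsolve(U, Hobs - dr$mu[m], transpose = TRUE)
      Vt <- exp(-dr$phi[m] * Dc)
      Zt <- backsolve(U, Vt, transpose = TRUE)
      mean_m <- dr$mu[m] + drop(crossprod(Zt, z))
      if (joint) {
        Rm <- exp(-dr$phi[m] * .coord_dist(areas[miss, , drop = FALSE]))
        Cm <- dr$sigma2[m] * (Rm - crossprod(Zt))
        Cm <- (Cm + t(Cm)) / 2
        diag(Cm) <- pmax(diag(Cm), 0) + 1e-10 * dr$sigma2[m]
        Um <- chol(Cm)
        H[m, miss] <- mean_m + drop(rnorm(nm) %*% Um)
      } else {
        var_m <- dr$sigma2[m] * pmax(0, 1 - colSums(Zt^2))
        H[m, miss] <- mean_m + sqrt(var_m) * rnorm(nm)
      }
    }
    H[, miss] <- pmax(H[, miss, drop = FALSE], 0)  # prevalence is nonnegative
  }

  logN <- log(pmax(areas$male_pop_18_29, threshold))
  Y <- dr$beta0 + dr$beta1 %o% logN + dr$beta2 * H
  N_out <- if (truncate_count_N)
    pmax(areas$male_pop_18_29, threshold) else areas$male_pop_18_29
  counts <- exp(Y) * rep(N_out, each = M)
  colnames(counts) <- colnames(H) <- areas$area_id
  structure(list(counts = counts, hiv = H, areas = areas,
                 threshold = threshold),
            class = "kpsae_prediction")
}

#' Posterior predictive count draws for a single area
#'
#' Convenience wrapper around [predict_msm] for one area.
#'
#' @param area one-row area table.
#' @param draws posterior draws.
#' @param observed_areas areas with observed prevalence to krige from.
#' @param threshold population truncation threshold (persons).
#' @param seed optional seed.
#' @return Numeric vector of count draws (one per retained draw).
#' @export
predict_area <- function(area, draws, observed_areas, threshold, seed = NULL) {
  if (nrow(area) != 1L) stop("'area' must be a single row")
  p <- predict_msm(area, draws, observed_areas = observed_areas,
                   threshold = threshold, seed = seed)
  drop(p$counts[, 1])
}

#' Leverage of a covariate vector against a training design
#'
#' `x' (X'X)^{-1} x`, the diagonal element of the hat matrix that the row
#' would have: a scale-free measure of how extreme an area's covariates are
#' relative to the training design. Training rows have leverage in (0, 1].
#'
#' @param X training design matrix (full column rank).
#' @param x covariate vector (or matrix of rows) to score.
#' @return Leverage value(s).
#' @export
leverage <- function(X, x) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  rowSums((x %*% xtx_inv) * x)
}

#' Summarize posterior predictive count draws per area
#'
#' Posterior median, central interval, percentage of the young-male
#' population, relative interval width (width over median), imputation flag,
#' and (when a training design is supplied) leverage of the area's covariate
#' vector. The covariate vector used for leverage matches the predictor:
#' intercept, truncated log population, and the posterior mean of the
#' prevalence values actually used.
#'
#' @param pred a `kpsae_prediction` from [predict_msm].
#' @param training_design optional design matrix of the training
#'   observations (intercept, log N, H) for leverage scores.
#' @param level interval coverage, default 0.95 (at least 100 draws per
#'   area).
#' @return data.frame: `area_id`, `name`, `n_median`, `n_low`, `n_high`,
#'   `pct_median`, `relative_width`, `hiv_was_imputed`, `leverage`.
#' @export
summarize_predictions <- function(pred, training_design = NULL, level = 0.95) {
  stopifnot(inherits(pred, "kpsae_prediction"))
  counts <- pred$counts
  if (nrow(counts) < 100L) stop("need at least 100 draws per area")
  alpha <- (1 - level) / 2
  qs <- apply(counts, 2, quantile, probs = c(0.5, alpha, 1 - alpha),
              type = 7, names = FALSE)
  areas <- pred$areas
  med <- qs[1, ]; lo <- qs[2, ]; hi <- qs[3, ]
  lev <- rep(NA_real_, nrow(areas))
  if (!is.null(training_design)) {
    logN <- log(pmax(areas$male_pop_18_29, pred$threshold))
    h_used <- colMeans(pred$hiv)
    lev <- leverage(training_design, cbind(1, logN, h_used))
  }
  data.frame(area_id = areas$area_id,
             name = if ("name" %in% names(areas)) areas$name else areas$area_id,
             n_median = med, n_low = lo, n_high = hi,
             pct_median = 100 * med / areas$male_pop_18_29,
             relative_width = ifelse(med > 0, (hi - lo) / med, 0),
             hiv_was_imputed = is.na(areas$hiv_prev_pct),
             leverage = lev,
             row.names = NULL, stringsAsFactors = FALSE)
}
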