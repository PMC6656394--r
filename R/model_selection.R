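# Leave-one-area-out covariate selection.
#
# Candidate models always keep HIV prevalence (the epidemiologically
# motivated covariate) and add at most one more. Each candidate is scored by
# leaving all of one area's direct estimates out, fitting weighted least
# squares (weights 1/w) on the rest, and predicting the left-out area's mean
# estimated fraction. The magnitudes of the published cross-validation errors
# are consistent with the fraction scale (n/N), which is the default; a
# count-scale option is provided.

#' The five candidate covariate sets
#'
#' HIV prevalence alone, and HIV prevalence with each of: log male 18--29
#' population, log night-light (Landscan) density, log population density,
#' and population density change.
#'
#' @return Named list of candidates, each a list with `label` and
#'   `covariates`.
#' @export
candidate_models <- function() {
  list(
    log_male_pop = list(label = "log male population + HIV prevalence",
                        covariates = c("log_male_pop", "hiv_prev")),
    landscan = list(label = "Landscan density + HIV prevalence",
                    covariates = c("log_landscan", "hiv_prev")),
    pop_density = list(label = "population density + HIV prevalence",
                       covariates = c("log_pop_density", "hiv_prev")),
    density_change = list(label = "density change + HIV prevalence",
                          covariates = c("density_change", "hiv_prev")),
    hiv_only = list(label = "only HIV prevalence",
                    covariates = "hiv_prev")
  )
}

#' Leave-one-area-out cross-validated MSE for one candidate model
#'
#' For each training area i: fit weighted least squares (weights `1/w`) on
#' the observations of the remaining areas, predict the fraction
#' `f_hat = exp(x_i' beta_hat)`, and compare against the target
#' `f_i = mean_j(n_ij / N_i) = mean_j exp(y_ij)`. The MSE is the mean of the
#' squared errors over areas (on the fraction scale by default; with
#' `scale = "count"` both target and prediction are multiplied by `N_i`).
#'
#' @param model a candidate from [candidate_models()] (list with `label`,
#'   `covariates`), or a character vector of covariate names.
#' @param observations regression observations (`area_id`, `y`, `w`).
#' @param areas area table with the candidate covariates observed for all
#'   training areas (at least 3 training areas).
#' @param scale `"fraction"` (default) or `"count"`.
#' @return MSE with attribute `n_folds_ok`.
#' @export
loocv_mse <- function(model, observations, areas,
                      scale = c("fraction", "count")) {
  scale <- match.arg(scale)
  covs <- if (is.character(model)) model else model$covariates
  ids <- unique(observations$area_id)
  if (length(ids) < 3L) stop("need at least 3 training areas")
  tr_areas <- areas[match(ids, areas$area_id), , drop = FALSE]
  if (anyNA(match(ids, areas$area_id)))
    stop("observations reference unknown area_id")
  Xa <- build_design(tr_areas, covs)        # one row per training area
  err2 <- numeric(length(ids))
  for (i in seq_along(ids)) {
    hold <- observations$area_id == ids[i]
    fit_obs <- observations[!hold, , drop = FALSE]
    rows <- match(fit_obs$area_id, ids)
    Xf <- Xa[rows, , drop = FALSE]
    if (qr(Xf)$rank < ncol(Xf))
      stop("design rank-deficient when leaving out area ", ids[i])
    f <- lm.wfit(Xf, fit_obs$y, w = 1 / fit_obs$w)
    bh <- f$coefficients
    f_hat <- exp(sum(Xa[i, ] * bh))
    f_tgt <- mean(exp(observations$y[hold]))
    e <- f_tgt - f_hat
    if (scale == "count") e <- e * tr_areas$male_pop_18_29[i]
    err2[i] <- e^2
  }
  out <- mean(err2)
  attr(out, "n_folds_ok") <- length(ids)
  attr(out, "fold_errors") <- setNames(err2, ids)
  out
}

#' Rank candidate models by cross-validated MSE
#'
#' @param candidates list of candidate models (default [candidate_models()]).
#' @param observations regression observations.
#' @param areas area table.
#' @param scale passed to [loocv_mse].
#' @return data.frame `label`, `mse`, `n_covariates`, `n_folds_ok` in
#'   ascending MSE order, ties broken by fewer covariates.
#' @export
rank_models <- function(candidates = candidate_models(), observations, areas,
                        scale = c("fraction", "count")) {
  scale <- match.arg(scale)
  if (length(candidates) < 1L) stop("need at least one candidate")
  rows <- lapply(candidates, function(cm) {
    m <- loocv_mse(cm, observations, areas, scale = scale)
    data.frame(label = cm$label, mse = as.numeric(m),
               n_covariates = length(cm$covariates),
               n_folds_ok = attr(m, "n_folds_ok"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab[order(tab$mse, tab$n_covariates), , drop = FALSE]
}
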