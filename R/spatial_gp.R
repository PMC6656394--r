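# Spatial Gaussian-process model for HIV prevalence.
#
# Prevalence H(s) over area coordinates s is modelled as a GP with constant
# mean mu and exponential covariance sigma^2 * exp(-phi * ||s_i - s_j||),
# distances Euclidean in decimal degrees. The empirical variogram diagnoses
# spatial structure; the GP likelihood supports maximum-likelihood fitting;
# kriging gives the conditional-normal prediction used to impute missing
# prevalence values.

#' Gaussian-process parameter container
#'
#' @param mu constant mean prevalence (percent).
#' @param sigma2 marginal variance (percent^2), > 0.
#' @param phi exponential decay rate per degree of distance, > 0.
#' @return An object of class `gp_params`.
#' @export
gp_params <- function(mu, sigma2, phi) {
  if (!is.finite(mu)) stop("mu must be finite")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.finite(phi) || phi <= 0) stop("phi must be positive")
  structure(list(mu = mu, sigma2 = sigma2, phi = phi), class = "gp_params")
}

#' @export
print.gp_params <- function(x, ...) {
  cat(sprintf("GP parameters: mu = %.4g, sigma2 = %.4g, phi = %.4g\n",
              x$mu, x$sigma2, x$phi))
  invisible(x)
}

# relative jitter added to the correlation diagonal before factorization
.gp_jitter <- 1e-8

.chol_corr <- function(D, phi) {
  R <- exp(-phi * D)
  diag(R) <- diag(R) + .gp_jitter
  tryCatch(chol(R), error = function(e)
    stop("covariance matrix not positive definite after jitter"))
}

# log N(H | mu 1, sigma2 * (R + jitter I)) via one Cholesky factorization
.gp_loglik <- function(H, D, mu, sigma2, phi) {
  k <- length(H)
  U <- .chol_corr(D, phi)
  z <- backsolve(U, H - mu, transpose = TRUE)
  -0.5 * k * log(2 * pi * sigma2) - sum(log(diag(U))) - sum(z^2) / (2 * sigma2)
}

#' Empirical variogram of observed HIV prevalence
#'
#' For each distance bin (I_{k-1}, I_k], averages the squared prevalence
#' difference over all unordered area pairs whose Euclidean distance falls in
#' the bin:
#' \deqn{v(m_k) = \frac{\sum_{(i,j)\in B_k} (H(s_i)-H(s_j))^2}{|B_k|}.}
#' Note this is the average squared difference as such, without the factor
#' 1/2 of the classical semivariogram; for data from a GP with exponential
#' covariance its expectation is \eqn{2\sigma^2(1 - e^{-\phi m})}.
#'
#' @param areas area table; only rows with observed `hiv_prev_pct` are used
#'   (at least 2 required).
#' @param edges strictly increasing distance bin boundaries; the first bin is
#'   closed on the left.
#' @return data.frame of class `variogram_bins`: `lower`, `upper`,
#'   `midpoint`, `value` (NA for empty bins), `count`.
#' @export
empirical_variogram <- function(areas, edges) {
  obs <- .observed_h(areas)
  if (nrow(obs) < 2L) stop("need at least 2 areas with observed prevalence")
  if (length(edges) < 2L || any(diff(edges) <= 0))
    stop("edges must be strictly increasing with at least 2 values")
  d <- as.vector(dist(cbind(obs$lon, obs$lat)))
  h2 <- as.vector(dist(obs$hiv_prev_pct))^2  # (H_i - H_j)^2 per pair
  bin <- cut(d, breaks = edges, include.lowest = TRUE, labels = FALSE)
  nb <- length(edges) - 1L
  counts <- tabulate(bin, nbins = nb)
  sums <- vapply(seq_len(nb), function(k) sum(h2[which(bin == k)]), numeric(1))
  value <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(data.frame(lower = edges[-length(edges)], upper = edges[-1],
                       midpoint = (edges[-length(edges)] + edges[-1]) / 2,
                       value = value, count = counts),
            class = c("variogram_bins", "data.frame"))
}

#' Fit the exponential variogram curve
#'
#' Least-squares fit of \eqn{\sigma^2 (1 - e^{-\phi m})} to the nonempty
#' variogram bins, weighted by pair counts. The fit is profiled: for fixed
#' phi the sill has a closed-form weighted least-squares solution, and phi is
#' optimized by Brent's method on a bounded interval. Intended for
#' diagnostics and as an initial value for maximum likelihood; because the
#' empirical variogram is the plain average squared difference, fitting data
#' from a GP with variance sigma^2 yields a sill near `2 * sigma^2`. Pass
#' `gp_scale = TRUE` to halve the fitted sill so the return value estimates
#' the GP variance itself.
#'
#' @param bins a `variogram_bins` object from [empirical_variogram] (at least
#'   3 nonempty bins).
#' @param gp_scale halve the fitted sill to the GP-variance scale.
#' @return list with `sigma2`, `phi`, and `objective` (weighted residual sum
#'   of squares).
#' @export
fit_variogram_curve <- function(bins, gp_scale = FALSE) {
  bins <- bins[!is.na(bins$value) & bins$count > 0, , drop = FALSE]
  if (nrow(bins) < 3L) stop("need at least 3 nonempty bins")
  m <- bins$midpoint; v <- bins$value; cnt <- bins$count
  if (max(v) - min(v) < 1e-12 * max(abs(v), 1))
    stop("flat variogram: decay rate unidentifiable")
  sill_for <- function(phi) {
    g <- 1 - exp(-phi * m)
    sum(cnt * v * g) / sum(cnt * g^2)
  }
  obj <- function(lphi) {
    phi <- exp(lphi)
    g <- 1 - exp(-phi * m)
    s <- sum(cnt * v * g) / sum(cnt * g^2)
    sum(cnt * (v - s * g)^2)
  }
  hi <- 500 / min(m[m > 0])
  op <- optimize(obj, interval = log(c(1e-8, hi)), tol = 1e-10)
  phi <- exp(op$minimum)
  if (phi > 0.99 * hi)
    stop("variogram decay estimate diverged (boundary): bins carry no range information")
  sigma2 <- sill_for(phi)
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("variogram curve fit failed: nonpositive sill; last phi = ", phi)
  if (gp_scale) sigma2 <- sigma2 / 2
  list(sigma2 = sigma2, phi = phi, objective = op$objective)
}

#' Gaussian-process log likelihood of observed prevalence
#'
#' Multivariate normal log density of the observed prevalence vector under
#' mean `mu` and covariance `sigma2 * exp(-phi * dist)` (plus a relative
#' diagonal jitter of 1e-8 for numerical stability).
#'
#' @param params a [gp_params] object.
#' @param areas area table; rows with observed `hiv_prev_pct` enter the
#'   likelihood.
#' @return Log density (scalar).
#' @export
gp_log_likelihood <- function(params, areas) {
  stopifnot(inherits(params, "gp_params"))
  obs <- .observed_h(areas)
  if (nrow(obs) == 0L) stop("no observed prevalence values")
  D <- .coord_dist(obs)
  .gp_loglik(obs$hiv_prev_pct, D, params$mu, params$sigma2, params$phi)
}

#' Kriging prediction of HIV prevalence
#'
#' Conditional-normal prediction at new coordinates given the observed
#' prevalence field, including the mean correction:
#' \deqn{E[H(s) | H(S)] = \mu + v(s)^\top \Sigma^{-1} (H(S) - \mu 1)}
#' \deqn{Var[H(s) | H(S)] = \sigma^2 - v(s)^\top \Sigma^{-1} v(s)}
#' with \eqn{v(s) = \sigma^2 e^{-\phi \|s - s_i\|}}. A target coinciding with
#' an observed site returns that site's value with variance 0; a target far
#' from all data reverts to the prior `(mu, sigma2)`.
#'
#' @param params a [gp_params] object.
#' @param areas area table supplying the observed prevalence field (at least
#'   one observed row).
#' @param targets data.frame with `lon`, `lat` for the prediction locations.
#' @return data.frame with columns `mean` and `var` (variance clamped to
#'   `[0, sigma2]`).
#' @export
krige <- function(params, areas, targets) {
  stopifnot(inherits(params, "gp_params"))
  obs <- .observed_h(areas)
  if (nrow(obs) == 0L) stop("need at least one observed area")
  if (!all(c("lon", "lat") %in% names(targets)))
    stop("targets need lon and lat")
  H <- obs$hiv_prev_pct
  D <- .coord_dist(obs)
  Dc <- .coord_dist(obs, targets)             # k x n_target
  U <- .chol_corr(D, params$phi)
  z <- backsolve(U, H - params$mu, transpose = TRUE)
  Vt <- exp(-params$phi * Dc)
  Zt <- backsolve(U, Vt, transpose = TRUE)
  mean <- params$mu + drop(crossprod(Zt, z))
  var <- params$sigma2 * pmin(1, pmax(0, 1 - colSums(Zt^2)))
  exact <- apply(Dc, 2, function(col) {
    i <- which.min(col)
    if (col[i] < 1e-10) i else NA_integer_
  })
  hit <- which(!is.na(exact))
  if (length(hit)) {
    mean[hit] <- H[exact[hit]]
    var[hit] <- 0
  }
  data.frame(mean = mean, var = var)
}

#' Maximum-likelihood fit of the exponential-covariance GP
#'
#' Profiles the likelihood: for fixed phi, the mean has the generalized
#' least-squares closed form and the variance its plug-in estimate, leaving a
#' one-dimensional profile likelihood in phi optimized by Brent's method on
#' the log scale over `interval`.
#'
#' @param areas area table with at least 3 observed prevalence values.
#' @param interval search range for phi (per degree).
#' @return A [gp_params] object with attribute `loglik`.
#' @export
fit_gp_mle <- function(areas, interval = c(1e-3, 1e3)) {
  obs <- .observed_h(areas)
  k <- nrow(obs)
  if (k < 3L) stop("need at least 3 observed areas")
  H <- obs$hiv_prev_pct
  D <- .coord_dist(obs)
  one <- rep(1, k)
  prof <- function(lphi) {
    U <- .chol_corr(D, exp(lphi))
    z1 <- backsolve(U, one, transpose = TRUE)
    zH <- backsolve(U, H, transpose = TRUE)
    mu <- sum(z1 * zH) / sum(z1^2)
    s2 <- sum((zH - mu * z1)^2) / k
    s2 <- max(s2, 1e-12)
    -0.5 * k * log(2 * pi * s2) - sum(log(diag(U))) - k / 2
  }
  op <- optimize(prof, interval = log(interval), maximum = TRUE, tol = 1e-8)
  phi <- exp(op$maximum)
  U <- .chol_corr(D, phi)
  z1 <- backsolve(U, one, transpose = TRUE)
  zH <- backsolve(U, H, transpose = TRUE)
  mu <- sum(z1 * zH) / sum(z1^2)
  s2 <- max(sum((zH - mu * z1)^2) / k, 1e-12)
  out <- gp_params(mu, s2, phi)
  attr(out, "loglik") <- op$objective
  out
}

#' Leave-one-out imputation mean squared error
#'
#' For each area with observed prevalence, refits on the remaining observed
#' areas (GP maximum likelihood for `method = "kriging"`; arithmetic mean for
#' `method = "mean"`), predicts the held-out value, and averages the squared
#' errors. Folds whose refit fails are skipped with a warning.
#'
#' @param areas area table with at least 3 observed prevalence values.
#' @param method `"kriging"` or `"mean"`.
#' @return MSE (percent^2) with attribute `n_folds_ok`.
#' @export
loocv_imputation_mse <- function(areas, method = c("kriging", "mean")) {
  method <- match.arg(method)
  obs <- .observed_h(areas)
  k <- nrow(obs)
  if (k < 3L) stop("need at least 3 observed areas")
  err2 <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    train <- obs[-i, , drop = FALSE]
    pred <- tryCatch({
      if (method == "kriging") {
        fit <- fit_gp_mle(train)
        krige(fit, train, obs[i, c("lon", "lat"), drop = FALSE])$mean
      } else {
        mean(train$hiv_prev_pct)
      }
    }, error = function(e) {
      warning("fold ", i, " skipped: ", conditionMessage(e))
      NA_real_
    })
    err2[i] <- (pred - obs$hiv_prev_pct[i])^2
  }
  ok <- !is.na(err2)
  out <- mean(err2[ok])
  attr(out, "n_folds_ok") <- sum(ok)
  out
}

#' Kriging-based imputation table for HIV prevalence
#'
#' Fits the GP by maximum likelihood to the observed prevalence values and
#' kriges every area, returning observed values untouched (sd 0). This is the
#' plug-in (non-Bayesian) imputation; the hierarchical model propagates
#' parameter uncertainty instead (see [predict_msm]).
#'
#' @param areas area table.
#' @param level interval coverage for the normal predictive bounds.
#' @return data.frame: `area_id`, `hiv_prev_pct_imputed`, `sd`, `q2.5`,
#'   `q97.5` (at `level`), `was_observed`.
#' @export
impute_hiv <- function(areas, level = 0.95) {
  fit <- fit_gp_mle(areas)
  kr <- krige(fit, areas, areas[, c("lon", "lat")])
  obs <- !is.na(areas$hiv_prev_pct)
  est <- ifelse(obs, areas$hiv_prev_pct, pmax(0, kr$mean))
  sd <- ifelse(obs, 0, sqrt(kr$var))
  zq <- -qnorm((1 - level) / 2)
  data.frame(area_id = areas$area_id,
             hiv_prev_pct_imputed = est,
             sd = sd,
             q2.5 = pmax(0, est - zq * sd),
             q97.5 = est + zq * sd,
             was_observed = obs,
             stringsAsFactors = FALSE)
}
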