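# Synthetic study generator.
#
# Emulates the statistical structure the analysis assumes: 61 prediction
# areas over a country-sized bounding box; log-normal male 18-29 populations;
# HIV prevalence drawn jointly from the exponential-covariance GP and floored
# at zero; roughly half the non-training areas with prevalence masked; 5
# training areas spread over the upper population range (the surveyed cities
# were all comparatively large, reproducing the extrapolation pathology that
# motivates population truncation) with 3-5 direct estimates each whose log
# CI half-widths set the heteroscedastic weights. Default
# parameter values are the fitted posterior medians of the real study, so
# synthetic data reproduce the published orders of magnitude (direct
# estimates in the hundreds to thousands, CI ratios ~1.3-3.2).

#' Configuration of a synthetic study
#'
#' @param n_areas number of prediction areas (default 61).
#' @param n_training number of areas carrying direct estimates (default 5).
#' @param methods_per_area inclusive range of direct estimates per training
#'   area (default 3 to 5).
#' @param beta regression coefficients (intercept, log-population slope,
#'   prevalence slope).
#' @param tau2 regression variance scale.
#' @param gp a [gp_params] for the prevalence field (percent scale).
#' @param missing_H_fraction fraction of all areas with prevalence masked
#'   (applied to non-training areas only), in [0, 1).
#' @param pop_meanlog,pop_sdlog log-normal law of the male 18--29 population.
#' @param bbox bounding box `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees; default approximates Cote d'Ivoire.
#' @param ci_halfwidth range of the uniform law for log-scale CI half-widths
#'   of the synthetic direct estimates.
#' @param seed optional integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_areas = 61L, n_training = 5L,
                       methods_per_area = c(3L, 5L),
                       beta = c(2.62, -0.79, 0.63), tau2 = 0.65,
                       gp = gp_params(2.55, 0.86, 7.68),
                       missing_H_fraction = 0.5,
                       pop_meanlog = 10.3, pop_sdlog = 1.0,
                       bbox = c(lon_min = -8.6, lon_max = -2.5,
                                lat_min = 4.3, lat_max = 10.7),
                       ci_halfwidth = c(0.13, 0.58),
                       seed = NULL) {
  if (n_training > n_areas) stop("n_training must not exceed n_areas")
  if (missing_H_fraction < 0 || missing_H_fraction >= 1)
    stop("missing_H_fraction must be in [0, 1)")
  if (tau2 <= 0) stop("tau2 must be positive")
  stopifnot(inherits(gp, "gp_params"), length(beta) == 3,
            length(methods_per_area) == 2)
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) stop("degenerate bounding box")
  structure(list(n_areas = as.integer(n_areas),
                 n_training = as.integer(n_training),
                 methods_per_area = as.integer(methods_per_area),
                 beta = beta, tau2 = tau2, gp = gp,
                 missing_H_fraction = missing_H_fraction,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 bbox = bbox, ci_halfwidth = ci_halfwidth, seed = seed),
            class = "sim_config")
}

#' Generate a synthetic area table
#'
#' Coordinates uniform in the bounding box; populations log-normal (floored
#' at 100 persons); prevalence drawn jointly from the GP and floored at 0;
#' training areas are spread over the upper population range, from roughly
#' the 36th percentile up to the largest area; the missingness mask is
#' applied to non-training areas only. The auxiliary density covariates
#' (`pop_density`, `landscan_density`) correlate strongly with population on
#' the log scale, as population-based measures do, while `density_change` is
#' pure noise, so covariate selection has both realistic competitors and an
#' irrelevant control. The latent prevalence before masking is kept in
#' `hiv_true`.
#'
#' @param config a [sim_config].
#' @return Area data.frame with columns `area_id`, `name`, `lon`, `lat`,
#'   `male_pop_18_29`, `hiv_prev_pct` (NA where masked), `hiv_true`,
#'   `pop_density`, `density_change`, `landscan_density`, `is_training`.
#' @export
generate_areas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_areas
  lon <- runif(n, config$bbox[1], config$bbox[2])
  lat <- runif(n, config$bbox[3], config$bbox[4])
  N <- pmax(round(rlnorm(n, config$pop_meanlog, config$pop_sdlog)), 100)
  D <- as.matrix(dist(cbind(lon, lat)))
  R <- exp(-config$gp$phi * D)
  diag(R) <- diag(R) + .gp_jitter
  H_true <- pmax(config$gp$mu +
                   sqrt(config$gp$sigma2) * drop(rnorm(n) %*% chol(R)), 0)
  # training areas sit in the upper population range: the largest area plus
  # areas spread from about the 36th percentile upward, mirroring the real
  # design (the smallest surveyed city sat at the 36th percentile of male
  # population, the largest was the top) and preserving the extrapolation
  # pathology that motivates prediction-time truncation
  ranks <- pmin(n, pmax(1L, round(seq(0.36, 1, length.out = config$n_training) * n)))
  is_training <- seq_len(n) %in% order(N)[unique(ranks)]
  while (sum(is_training) < config$n_training) {  # resolve rank collisions
    pool0 <- which(!is_training)
    is_training[pool0[which.max(N[pool0])]] <- TRUE
  }
  H <- H_true
  n_miss <- round(config$missing_H_fraction * n)
  pool <- which(!is_training)
  n_miss <- min(n_miss, length(pool))
  if (n_miss > 0) H[sample(pool, n_miss)] <- NA
  z <- as.vector(scale(log(N)))
  data.frame(area_id = sprintf("A%02d", seq_len(n)),
             name = sprintf("Area %02d", seq_len(n)),
             lon = lon, lat = lat,
             male_pop_18_29 = N,
             hiv_prev_pct = H,
             hiv_true = H_true,
             pop_density = exp(4 + 0.7 * z + 0.5 * rnorm(n)),
             density_change = rnorm(n),
             landscan_density = exp(2 + 0.8 * z + 0.5 * rnorm(n)),
             is_training = is_training,
             stringsAsFactors = FALSE)
}

#' Generate synthetic direct estimates for the training areas
#'
#' For each training area, draws 3--5 method-level estimates from the
#' generative form of the regression model: log CI half-widths
#' `h ~ Unif(ci_halfwidth)` give weights `w = (2h)^2`; responses
#' `y ~ N(x' beta, tau2 * w)`; the reported estimate is `N * exp(y)` with CI
#' `(N * exp(y - h), N * exp(y + h))`. Draws implying a fraction of 1 or
#' more are redrawn (capped with a warning). The latent per-area true
#' fraction `exp(x' beta)` is returned alongside.
#'
#' @param areas area table from [generate_areas] (training areas must have
#'   observed prevalence).
#' @param config the [sim_config] used to generate `areas`.
#' @param seed optional seed (the area-generation seed is not reused).
#' @return list with `estimates` (direct-estimate data.frame) and
#'   `true_fractions` (`area_id`, `fraction`).
#' @export
generate_direct_estimates <- function(areas, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  tr <- areas[areas$is_training, , drop = FALSE]
  if (anyNA(tr$hiv_prev_pct))
    stop("training areas must have observed prevalence")
  X <- cbind(1, log(tr$male_pop_18_29), tr$hiv_prev_pct)
  eta <- drop(X %*% config$beta)
  labels <- c("ngo", "service", "social_event", "unique_object", "ngo_2")
  rows <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    kj <- sample(seq(config$methods_per_area[1], config$methods_per_area[2]), 1)
    h <- runif(kj, config$ci_halfwidth[1], config$ci_halfwidth[2])
    w <- (2 * h)^2
    y <- rnorm(kj, eta[i], sqrt(config$tau2 * w))
    for (tries in seq_len(100)) {
      bad <- exp(y) >= 1
      if (!any(bad)) break
      y[bad] <- rnorm(sum(bad), eta[i], sqrt(config$tau2 * w[bad]))
    }
    if (any(exp(y) >= 1)) {
      warning("resample cap reached; fraction capped below 1")
      y[exp(y) >= 1] <- log(0.99)
    }
    N <- tr$male_pop_18_29[i]
    rows[[i]] <- data.frame(area_id = tr$area_id[i],
                            method_label = labels[seq_len(kj)],
                            n_hat = N * exp(y),
                            ci_low = N * exp(y - h),
                            ci_high = N * exp(y + h),
                            stringsAsFactors = FALSE)
  }
  list(estimates = do.call(rbind, rows),
       true_fractions = data.frame(area_id = areas$area_id,
                                   fraction = exp(drop(
                                     cbind(1, log(areas$male_pop_18_29),
                                           areas$hiv_true) %*% config$beta)),
                                   stringsAsFactors = FALSE))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [generate_areas] then [generate_direct_estimates]
#' under one seed stream.
#'
#' @param config a [sim_config].
#' @return list: `areas`, `estimates`, `true_fractions`, `config`.
#' @export
generate_study <- function(config = sim_config()) {
  areas <- generate_areas(config)
  de <- generate_direct_estimates(areas, config)
  list(areas = areas, estimates = de$estimates,
       true_fractions = de$true_fractions, config = config)
}

#' Generate a synthetic hidden population and RDS-style sample
#'
#' Builds a population of `M` members with degrees `1 + Poisson(mean - 1)`,
#' assigns source memberships uniformly at random to match the requested
#' programme-log totals, and samples respondents without replacement with
#' probability proportional to degree (the inclusion regime the RDS-II
#' estimator assumes). Membership is independent of degree by construction.
#'
#' @param M population size.
#' @param source_totals named vector (or data.frame `source_label`, `total`)
#'   of programme-log totals, each at most `M`.
#' @param n_respondents sample size (at most `M`).
#' @param seed optional seed.
#' @param degree_mean mean reported network size.
#' @return list: `respondents` (sampled rows with `respondent_id`, `degree`,
#'   one 0/1 column per source), `counts` (`source_label`, `total`),
#'   `population` (full frame, for oracle checks).
#' @export
generate_rds_population <- function(M, source_totals, n_respondents,
                                    seed = NULL, degree_mean = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(source_totals))
    source_totals <- setNames(source_totals$total, source_totals$source_label)
  if (any(source_totals > M)) stop("source totals cannot exceed M")
  if (any(source_totals < 0)) stop("source totals must be nonnegative")
  if (n_respondents > M) stop("cannot sample more respondents than members")
  pop <- data.frame(respondent_id = sprintf("R%06d", seq_len(M)),
                    degree = 1 + rpois(M, degree_mean - 1),
                    stringsAsFactors = FALSE)
  for (src in names(source_totals)) {
    b <- integer(M)
    b[sample.int(M, source_totals[[src]])] <- 1L
    pop[[src]] <- b
  }
  idx <- sample.int(M, n_respondents, prob = pop$degree)
  list(respondents = pop[idx, , drop = FALSE],
       counts = data.frame(source_label = names(source_totals),
                           total = as.integer(unname(source_totals)),
                           stringsAsFactors = FALSE),
       population = pop)
}
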