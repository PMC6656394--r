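# Variogram, GP likelihood, kriging, and imputation cross-validation.

test_that("empirical variogram averages squared differences per bin", {
  two <- data.frame(area_id = c("a", "b"), lon = c(0, 1), lat = c(0, 0),
                    male_pop_18_29 = 1000, hiv_prev_pct = c(2, 4))
  vb <- empirical_variogram(two, edges = c(0, 2))
  expect_equal(vb$value, 4.0)  # plain squared difference, no 1/2
  expect_equal(vb$count, 1L)

  const <- two; const$hiv_prev_pct <- c(3, 3)
  expect_equal(empirical_variogram(const, c(0, 2))$value, 0)

  sq <- data.frame(area_id = letters[1:4], lon = c(0, 1, 0, 1),
                   lat = c(0, 0, 1, 1), male_pop_18_29 = 1000,
                   hiv_prev_pct = c(1, 2, 3, 4))
  edges <- c(0, 0.5, 1.2, 2)
  vb <- empirical_variogram(sq, edges)
  # brute force over all 6 unordered pairs
  pairs <- combn(4, 2)
  d <- sqrt(colSums((t(cbind(sq$lon, sq$lat))[, pairs[1, ]] -
                     t(cbind(sq$lon, sq$lat))[, pairs[2, ]])^2))
  h2 <- (sq$hiv_prev_pct[pairs[1, ]] - sq$hiv_prev_pct[pairs[2, ]])^2
  for (k in 1:3) {
    inbin <- if (k == 1) d <= edges[2] else d > edges[k] & d <= edges[k + 1]
    if (any(inbin)) {
      expect_equal(vb$value[k], mean(h2[inbin]))
      expect_equal(vb$count[k], sum(inbin))
    } else {
      expect_true(is.na(vb$value[k]))
      expect_equal(vb$count[k], 0L)
    }
  }
})

test_that("variogram curve fit inverts exactly and degrades gracefully", {
  m <- seq(0.1, 1.2, length.out = 6)
  bins <- structure(data.frame(lower = m - 0.05, upper = m + 0.05,
                               midpoint = m, value = 1 * (1 - exp(-5 * m)),
                               count = rep(10L, 6)),
                    class = c("variogram_bins", "data.frame"))
  fit <- fit_variogram_curve(bins)
  expect_equal(fit$sigma2, 1, tolerance = 1e-6)
  expect_equal(fit$phi, 5, tolerance = 1e-6)

  set.seed(9)
  pert <- bins
  pert$value <- pert$value * (1 + rnorm(6, 0, 0.01))
  fitp <- fit_variogram_curve(pert)
  expect_lt(abs(fitp$sigma2 - 1), 0.1)
  expect_lt(abs(fitp$phi - 5) / 5, 0.1)

  flat <- bins; flat$value <- rep(2, 6)
  expect_error(fit_variogram_curve(flat), "flat|unidentifiable|diverged")
})

test_that("GP log likelihood matches closed forms and a dense MVN oracle", {
  one <- data.frame(area_id = "a", lon = 0.3, lat = 0.7,
                    male_pop_18_29 = 1000, hiv_prev_pct = 2.5)
  p <- gp_params(mu = 2.5, sigma2 = 0.8, phi = 3)
  expect_equal(gp_log_likelihood(p, one), -0.5 * log(2 * pi * 0.8),
               tolerance = 1e-7)  # diagonal jitter enters at 1e-8

  far <- data.frame(area_id = c("a", "b"), lon = c(0, 4000), lat = c(0, 0),
                    male_pop_18_29 = 1000, hiv_prev_pct = c(2.0, 3.1))
  ll_indep <- sum(dnorm(c(2.0, 3.1), 2.5, sqrt(0.8), log = TRUE))
  expect_equal(gp_log_likelihood(p, far), ll_indep, tolerance = 1e-7)

  a5 <- tiny_areas(5)
  D <- as.matrix(dist(cbind(a5$lon, a5$lat)))
  S <- 0.8 * (exp(-3 * D) + diag(1e-8, 5))
  oracle <- mvn_logdens_oracle(a5$hiv_prev_pct, rep(2.5, 5), S)
  expect_equal(gp_log_likelihood(p, a5), oracle, tolerance = 1e-8)
})

test_that("GP log likelihood is invariant to area ordering", {
  a <- tiny_areas(8, seed = 13)
  p <- gp_params(2.2, 1.1, 4)
  set.seed(2)
  for (i in 1:5) {
    perm <- a[sample(nrow(a)), , drop = FALSE]
    expect_equal(gp_log_likelihood(p, perm), gp_log_likelihood(p, a),
                 tolerance = 1e-10)
  }
})

test_that("kriging reproduces conditional-normal conditioning", {
  p <- gp_params(mu = 2.5, sigma2 = 0.9, phi = 2)
  obs <- data.frame(area_id = c("a", "b"), lon = c(0, 1), lat = c(0, 0.5),
                    male_pop_18_29 = 1000, hiv_prev_pct = c(1.8, 3.2))
  targ <- data.frame(lon = c(0.4, 2.5), lat = c(0.1, 1.9))
  kr <- krige(p, obs, targ)
  oracle <- cond_mvn_oracle(2.5, 0.9, 2, cbind(obs$lon, obs$lat),
                            obs$hiv_prev_pct, as.matrix(targ))
  expect_equal(kr$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(kr$var, oracle$var, tolerance = 1e-6)

  # exact interpolation at an observed site
  at_site <- krige(p, obs, data.frame(lon = 0, lat = 0))
  expect_equal(at_site$mean, 1.8)
  expect_equal(at_site$var, 0)

  # prior limit far from all data
  faraway <- krige(p, obs, data.frame(lon = 500, lat = 500))
  expect_equal(faraway$mean, 2.5, tolerance = 1e-6)
  expect_equal(faraway$var, 0.9, tolerance = 1e-6)
})

test_that("kriging variance is bounded by sigma2 and shrinks with data", {
  p <- gp_params(2, 1, 3)
  a <- gp_field_areas(12, 2, 1, 3, seed = 8)
  targ <- data.frame(lon = 0.35, lat = 0.65)
  vprev <- Inf
  for (k in c(3, 6, 9, 12)) {
    kr <- krige(p, a[seq_len(k), , drop = FALSE], targ)
    expect_lte(kr$var, 1 + 1e-8)
    expect_gte(kr$var, 0)
    expect_lte(kr$var, vprev + 1e-10)
    vprev <- kr$var
  }
})

test_that("GP maximum likelihood recovers simulated parameters", {
  # decay chosen so the correlation range is several times smaller than the
  # domain: with an exponential covariance on a fixed domain the variance
  # and decay are only weakly identified individually when the range rivals
  # the domain size (only their product is microergodic)
  truth <- c(mu = 3, sigma2 = 1, phi = 6)
  err <- t(vapply(1:20, function(s) {
    a <- gp_field_areas(100, truth["mu"], truth["sigma2"], truth["phi"],
                        seed = 300 + s, box = c(0, 2))
    f <- fit_gp_mle(a)
    abs(c(f$mu, f$sigma2, f$phi) / truth - 1)
  }, numeric(3)))
  expect_lt(median(err[, 1]), 0.25)
  expect_lt(median(err[, 2]), 0.25)
  expect_lt(median(err[, 3]), 0.25)
})

test_that("leave-one-out imputation: degenerate and control cases", {
  const <- tiny_areas(6, seed = 4)
  const$hiv_prev_pct <- 2.5
  expect_equal(as.numeric(loocv_imputation_mse(const, "kriging")), 0,
               tolerance = 1e-6)
  expect_equal(as.numeric(loocv_imputation_mse(const, "mean")), 0)

  # i.i.d. field: no spatial signal, the two methods should tie on average
  ratio <- vapply(1:20, function(s) {
    set.seed(500 + s)
    a <- tiny_areas(15, seed = 500 + s)
    a$hiv_prev_pct <- rnorm(15, 2.5, 0.8)
    mk <- as.numeric(loocv_imputation_mse(a, "kriging"))
    mm <- as.numeric(loocv_imputation_mse(a, "mean"))
    mk / mm
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.10)
})

test_that("plug-in imputation table flags observed areas and orders bounds", {
  a <- gp_field_areas(20, 2.5, 0.9, 3, seed = 12)
  a$hiv_prev_pct[c(3, 7, 11)] <- NA
  imp <- impute_hiv(a)
  expect_equal(sum(!imp$was_observed), 3)
  expect_true(all(imp$sd[imp$was_observed] == 0))
  expect_true(all(imp$q2.5 <= imp$hiv_prev_pct_imputed + 1e-12))
  expect_true(all(imp$q97.5 >= imp$hiv_prev_pct_imputed - 1e-12))
})
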