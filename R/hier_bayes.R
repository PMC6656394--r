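# Joint hierarchical Bayesian model.
#
# The joint posterior combines (a) the heteroscedastic log-fraction
# regression y_ij ~ N(beta0 + beta1 log N_i + beta2 H_i, tau^2 w_ij) over all
# direct estimates, (b) the exponential-covariance GP for the observed
# prevalence field H(S), and (c) the priors
#   beta ~ N(0, 1e6 I), mu ~ N(0, 1e6), phi ~ Unif(0, 10),
#   1/tau^2 ~ Gamma(0.01, 0.01), 1/sigma^2 ~ Gamma(2, 1)   (shape, rate).
# Sampling is Metropolis-within-Gibbs: the regression block is conditionally
# conjugate and drawn exactly (beta jointly Gaussian, 1/tau^2 Gamma), while
# the GP parameters use componentwise adaptive Gaussian random-walk
# Metropolis -- sigma^2 on the log scale and phi on the logit-of-(phi/10)
# scale, with Jacobians, to improve mixing near the boundaries. (A random
# walk on beta itself mixes arbitrarily badly here: with log N far from
# zero, the intercept and the population slope are near-perfectly
# correlated a posteriori.) All training areas must have observed
# prevalence; areas with missing prevalence enter only at prediction time.

.prior_beta_sd <- 1e3     # beta, mu ~ N(0, 1e6)
.prior_tau_shape <- 0.01  # 1/tau^2 ~ Gamma(0.01, 0.01)
.prior_tau_rate <- 0.01
.prior_sig_shape <- 2     # 1/sigma^2 ~ Gamma(2, 1)
.prior_sig_rate <- 1
.phi_upper <- 10          # phi ~ Unif(0, 10)

.log_priors <- function(beta, tau2, mu, sigma2, phi) {
  if (tau2 <= 0 || sigma2 <= 0 || phi <= 0 || phi >= .phi_upper) return(-Inf)
  sum(dnorm(beta, 0, .prior_beta_sd, log = TRUE)) +
    dnorm(mu, 0, .prior_beta_sd, log = TRUE) -
    log(.phi_upper) +
    dgamma(1 / tau2, .prior_tau_shape, rate = .prior_tau_rate, log = TRUE) -
    2 * log(tau2) +   # Jacobian of precision -> variance
    dgamma(1 / sigma2, .prior_sig_shape, rate = .prior_sig_rate, log = TRUE) -
    2 * log(sigma2)
}

#' MCMC configuration
#'
#' @param n_iter total iterations (default 30000).
#' @param n_burn burn-in iterations discarded from the front (default 15000).
#' @param seed optional integer seed.
#' @param proposal_scales named numeric vector of initial random-walk
#'   standard deviations for `mu`, `lsigma2` (log sigma^2) and `lphi` (logit
#'   of phi/10); defaults are adapted away during burn-in when
#'   `adapt = TRUE`.
#' @param adapt adapt proposal scales toward a 44% acceptance rate during
#'   burn-in (scales are frozen afterwards, so retained draws target the
#'   exact posterior).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 30000L, n_burn = 15000L, seed = NULL,
                        proposal_scales = NULL, adapt = TRUE, thin = 1L) {
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  if (n_burn < 0L || n_burn >= n_iter) stop("need 0 <= n_burn < n_iter")
  sc <- c(mu = 0.5, lsigma2 = 0.5, lphi = 0.8)
  if (!is.null(proposal_scales)) {
    bad <- setdiff(names(proposal_scales), names(sc))
    if (length(bad)) stop("unknown proposal scale(s): ", paste(bad, collapse = ", "))
    sc[names(proposal_scales)] <- proposal_scales
  }
  structure(list(n_iter = n_iter, n_burn = n_burn, seed = seed,
                 proposal_scales = sc, adapt = isTRUE(adapt),
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

# extract regression pieces shared by log_posterior and run_mcmc
.regression_pieces <- function(observations, areas) {
  if (is.null(observations) || nrow(observations) == 0L)
    return(list(n = 0L))
  if (!all(c("area_id", "y", "w") %in% names(observations)))
    stop("observations need columns area_id, y, w")
  if (any(observations$w <= 0)) stop("weights w must be positive")
  idx <- match(observations$area_id, areas$area_id)
  if (anyNA(idx)) stop("observation references unknown area_id")
  tr <- areas[idx, , drop = FALSE]
  if (anyNA(tr$hiv_prev_pct))
    stop("training areas must have observed HIV prevalence")
  X <- cbind(1, log(tr$male_pop_18_29), tr$hiv_prev_pct)
  list(n = nrow(observations), y = observations$y, w = observations$w, X = X)
}

#' Joint log posterior density
#'
#' Evaluates the unnormalized log posterior of the hierarchical model at one
#' parameter state: the weighted-regression log likelihood over all direct
#' estimates, the GP log density of the observed prevalence field, and the
#' log priors. Returns `-Inf` outside the support (`tau2, sigma2 > 0`,
#' `0 < phi < 10`).
#'
#' @param state named list or numeric vector with elements `beta0`, `beta1`,
#'   `beta2`, `tau2`, `mu`, `sigma2`, `phi`.
#' @param observations regression observations (`area_id`, `y`, `w`), may be
#'   empty/NULL for a prior-only evaluation.
#' @param areas area table; rows with observed `hiv_prev_pct` form the GP
#'   term, and supply covariates for the observations.
#' @return Scalar log density.
#' @export
log_posterior <- function(state, observations, areas) {
  state <- as.list(state)
  beta <- c(state$beta0, state$beta1, state$beta2)
  lp <- .log_priors(beta, state$tau2, state$mu, state$sigma2, state$phi)
  if (!is.finite(lp)) return(-Inf)
  rp <- .regression_pieces(observations, areas)
  if (rp$n > 0L) {
    mu_y <- drop(rp$X %*% beta)
    lp <- lp + sum(dnorm(rp$y, mu_y, sqrt(state$tau2 * rp$w), log = TRUE))
  }
  if (!is.null(areas) && "hiv_prev_pct" %in% names(areas)) {
    obs <- areas[!is.na(areas$hiv_prev_pct), , drop = FALSE]
    if (nrow(obs) > 0L) {
      D <- .coord_dist(obs)
      lp <- lp + .gp_loglik(obs$hiv_prev_pct, D, state$mu, state$sigma2,
                            state$phi)
    }
  }
  lp
}

# effective sample size via Geyer's initial positive sequence
.ess <- function(x) {
  n <- length(x)
  s <- sd(x)
  if (n < 10L || !is.finite(s) || s == 0) return(n)
  lag_max <- min(n - 1L, 10L * floor(sqrt(n)))
  ac <- acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[-1]
  ac[!is.finite(ac)] <- 0
  s <- 0; k <- 1L
  while (k + 1L <= length(ac)) {
    g <- ac[k] + ac[k + 1L]
    if (g < 0) break
    s <- s + g
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' Sample the joint posterior by adaptive Metropolis-within-Gibbs
#'
#' The regression block is conditionally conjugate and is drawn exactly each
#' sweep: `beta` jointly from its Gaussian full conditional, and the
#' precision `1/tau2` from Gamma(0.01 + n/2, 0.01 + S/2) with S the weighted
#' residual sum of squares. The GP parameters `mu`, `sigma2`, `phi` use
#' componentwise Gaussian random-walk Metropolis with proposal scales
#' adapted during burn-in only. With no observations and no observed
#' prevalence the chain targets the prior exactly, which is useful for
#' validation.
#'
#' @param observations regression observations (`area_id`, `y`, `w`) from
#'   [prepare_regression_data]; may be NULL.
#' @param areas area table; all areas referenced by observations must have
#'   observed prevalence, and every observed prevalence value enters the GP
#'   term.
#' @param config an [mcmc_config].
#' @param fix named list of parameters to hold fixed (e.g.
#'   `list(beta0 = 2.6, phi = 7.7)`); fixed parameters are skipped by the
#'   sampler and reported as constant columns.
#' @return Object of class `kpsae_draws`: list with `draws` (data.frame of
#'   retained samples of `beta0`, `beta1`, `beta2`, `tau2`, `mu`, `sigma2`,
#'   `phi`), `acceptance`, `ess`, and the configuration. Warnings are issued
#'   for post-adaptation acceptance rates outside (0.05, 0.8) and effective
#'   sample sizes below 100.
#' @export
run_mcmc <- function(observations, areas, config = mcmc_config(),
                     fix = list()) {
  stopifnot(inherits(config, "mcmc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  rp <- .regression_pieces(observations, areas)
  n <- rp$n
  have_gp <- !is.null(areas) && "hiv_prev_pct" %in% names(areas) &&
    any(!is.na(areas$hiv_prev_pct))
  if (have_gp) {
    obs <- areas[!is.na(areas$hiv_prev_pct), , drop = FALSE]
    H <- obs$hiv_prev_pct
    D <- .coord_dist(obs)
    k <- length(H)
  } else k <- 0L

  bad_fix <- setdiff(names(fix),
                     c("beta0", "beta1", "beta2", "tau2", "mu", "sigma2", "phi"))
  if (length(bad_fix)) stop("unknown parameter(s) in fix: ",
                            paste(bad_fix, collapse = ", "))

  # initial state: weighted least squares for beta, moments for the GP part
  if (n > 0L) {
    f <- lm.wfit(rp$X, rp$y, w = 1 / rp$w)
    beta <- unname(f$coefficients)
    beta[is.na(beta)] <- 0
    tau2 <- max(sum(f$residuals^2 / rp$w) / max(n - 3, 1), 1e-3)
  } else {
    beta <- c(0, 0, 0); tau2 <- 1
  }
  if (k > 0L) {
    mu <- mean(H); sigma2 <- max(var(H), 1e-3); phi <- .phi_upper / 2
  } else {
    mu <- 0; sigma2 <- 1; phi <- .phi_upper / 2
  }
  if ("beta0" %in% names(fix)) beta[1] <- fix$beta0
  if ("beta1" %in% names(fix)) beta[2] <- fix$beta1
  if ("beta2" %in% names(fix)) beta[3] <- fix$beta2
  if ("tau2" %in% names(fix)) tau2 <- fix$tau2
  if ("mu" %in% names(fix)) mu <- fix$mu
  if ("sigma2" %in% names(fix)) sigma2 <- fix$sigma2
  if ("phi" %in% names(fix)) {
    phi <- fix$phi
    if (phi <= 0 || phi >= .phi_upper) stop("fixed phi outside (0, 10)")
  }

  # cached quantities
  if (n > 0L) {
    Xb <- drop(rp$X %*% beta)
    SS <- sum((rp$y - Xb)^2 / rp$w)
    const_w <- -0.5 * sum(log(2 * pi * rp$w))
  }
  if (k > 0L) {
    U <- .chol_corr(D, phi)
    ldetR <- 2 * sum(log(diag(U)))
    z <- backsolve(U, H - mu, transpose = TRUE)
    Q <- sum(z^2)
  }

  upd <- c("mu", "lsigma2", "lphi")
  fixed_rw <- c(mu = "mu", lsigma2 = "sigma2", lphi = "phi")
  upd <- upd[!fixed_rw[upd] %in% names(fix)]
  do_tau <- !"tau2" %in% names(fix)
  beta_free <- !(c("beta0", "beta1", "beta2") %in% names(fix))

  ls <- log(config$proposal_scales)          # adapted log proposal sds
  acc_batch <- setNames(numeric(length(upd)), upd)
  acc_post <- setNames(numeric(length(upd)), upd)
  n_post_prop <- 0L
  batch_len <- 50L

  n_keep <- (config$n_iter - config$n_burn) %/% config$thin
  draws <- matrix(NA_real_, n_keep, 7,
                  dimnames = list(NULL, c("beta0", "beta1", "beta2", "tau2",
                                          "mu", "sigma2", "phi")))
  keep_i <- 0L

  lp_beta <- function(b) dnorm(b, 0, .prior_beta_sd, log = TRUE)
  # sigma^2 target pieces on u = log sigma2: -a*u - b*exp(-u) (prior+Jacobian)
  lp_lsig <- function(u) -.prior_sig_shape * u - .prior_sig_rate * exp(-u)
  lp_lphi <- function(p) log(p) + log(.phi_upper - p)  # Unif + logit Jacobian

  for (it in seq_len(config$n_iter)) {
    # joint conjugate Gaussian draw for the free regression coefficients
    if (any(beta_free)) {
      A <- diag(3) / .prior_beta_sd^2
      bvec <- numeric(3)
      if (n > 0L) {
        Wi <- 1 / (tau2 * rp$w)
        A <- A + crossprod(rp$X, rp$X * Wi)
        bvec <- bvec + drop(crossprod(rp$X, rp$y * Wi))
      }
      if (all(beta_free)) {
        Ub <- chol(A)
        mb <- backsolve(Ub, backsolve(Ub, bvec, transpose = TRUE))
        beta <- drop(mb + backsolve(Ub, rnorm(3)))
      } else {
        uf <- which(beta_free); ff <- which(!beta_free)
        rhs <- bvec[uf] - drop(A[uf, ff, drop = FALSE] %*% beta[ff])
        Uu <- chol(A[uf, uf, drop = FALSE])
        mb <- backsolve(Uu, backsolve(Uu, rhs, transpose = TRUE))
        beta[uf] <- drop(mb + backsolve(Uu, rnorm(length(uf))))
      }
      if (n > 0L) {
        Xb <- drop(rp$X %*% beta)
        SS <- sum((rp$y - Xb)^2 / rp$w)
      }
    }

    for (pm in upd) {
      s <- exp(ls[[pm]])
      if (pm == "mu") {
        prop <- mu + s * rnorm(1)
        if (k > 0L) {
          z_p <- backsolve(U, H - prop, transpose = TRUE)
          Q_p <- sum(z_p^2)
          dll <- -(Q_p - Q) / (2 * sigma2)
        } else dll <- 0
        la <- dll + lp_beta(prop) - lp_beta(mu)
        if (log(runif(1)) < la) {
          mu <- prop
          if (k > 0L) Q <- Q_p
          acc_batch[[pm]] <- acc_batch[[pm]] + 1
          if (it > config$n_burn) acc_post[[pm]] <- acc_post[[pm]] + 1
        }
      } else if (pm == "lsigma2") {
        u <- log(sigma2)
        u_p <- u + s * rnorm(1)
        s2_p <- exp(u_p)
        dll <- if (k > 0L)
          (-0.5 * k * (u_p - u) - Q / (2 * s2_p) + Q / (2 * sigma2)) else 0
        la <- dll + lp_lsig(u_p) - lp_lsig(u)
        if (is.finite(la) && log(runif(1)) < la) {
          sigma2 <- s2_p
          acc_batch[[pm]] <- acc_batch[[pm]] + 1
          if (it > config$n_burn) acc_post[[pm]] <- acc_post[[pm]] + 1
        }
      } else { # lphi
        v <- log(phi / (.phi_upper - phi))
        v_p <- v + s * rnorm(1)
        phi_p <- .phi_upper / (1 + exp(-v_p))
        if (phi_p > 0 && phi_p < .phi_upper) {
          if (k > 0L) {
            U_p <- .chol_corr(D, phi_p)
            ldetR_p <- 2 * sum(log(diag(U_p)))
            z_p <- backsolve(U_p, H - mu, transpose = TRUE)
            Q_p <- sum(z_p^2)
            dll <- -0.5 * (ldetR_p - ldetR) - (Q_p - Q) / (2 * sigma2)
          } else dll <- 0
          la <- dll + lp_lphi(phi_p) - lp_lphi(phi)
          if (is.finite(la) && log(runif(1)) < la) {
            phi <- phi_p
            if (k > 0L) { U <- U_p; ldetR <- ldetR_p; Q <- Q_p }
            acc_batch[[pm]] <- acc_batch[[pm]] + 1
            if (it > config$n_burn) acc_post[[pm]] <- acc_post[[pm]] + 1
          }
        }
      }
    }

    if (do_tau) {
      S_part <- if (n > 0L) SS else 0
      prec <- rgamma(1, shape = .prior_tau_shape + n / 2,
                     rate = .prior_tau_rate + S_part / 2)
      tau2 <- 1 / prec
    }

    if (it > config$n_burn) n_post_prop <- n_post_prop + 1L

    # batch adaptation during burn-in only
    if (config$adapt && it <= config$n_burn && it %% batch_len == 0L) {
      for (pm in upd) {
        rate <- acc_batch[[pm]] / batch_len
        ls[[pm]] <- ls[[pm]] + ifelse(rate > 0.44, 0.05, -0.05)
      }
      acc_batch[] <- 0
    } else if (it %% batch_len == 0L) acc_batch[] <- 0

    if (it > config$n_burn &&
        (it - config$n_burn) %% config$thin == 0L) {
      keep_i <- keep_i + 1L
      draws[keep_i, ] <- c(beta, tau2, mu, sigma2, phi)
    }
  }

  acc_rate <- if (n_post_prop > 0L) acc_post / n_post_prop else acc_post
  low <- names(acc_rate)[acc_rate < 0.05 | acc_rate > 0.8]
  if (length(low))
    warning("post-adaptation acceptance rate outside (0.05, 0.8) for: ",
            paste(low, collapse = ", "))
  draws <- as.data.frame(draws[seq_len(keep_i), , drop = FALSE])
  ess <- vapply(draws, .ess, numeric(1))
  # fixed / conjugate columns are not meaningfully autocorrelated diagnostics
  check <- setdiff(names(ess), c(names(fix)))
  lowe <- check[ess[check] < 100]
  if (length(lowe))
    warning("effective sample size below 100 for: ",
            paste(lowe, collapse = ", "))
  structure(list(draws = draws, acceptance = acc_rate, ess = ess,
                 config = config, fix = fix),
            class = "kpsae_draws")
}

#' @export
print.kpsae_draws <- function(x, ...) {
  cat(sprintf("kpsae posterior draws: %d retained samples of %d parameters\n",
              nrow(x$draws), ncol(x$draws)))
  print(posterior_summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.kpsae_draws <- function(x, ...) x$draws

#' Posterior summaries
#'
#' Componentwise empirical median and central 95% credible interval
#' (quantile type 7).
#'
#' @param draws a `kpsae_draws` object or a data.frame of draws (at least
#'   100 rows).
#' @return data.frame: `parameter`, `median`, `q2.5`, `q97.5`.
#' @export
posterior_summary <- function(draws) {
  d <- if (inherits(draws, "kpsae_draws")) draws$draws else as.data.frame(draws)
  if (nrow(d) < 100L) stop("need at least 100 draws")
  qs <- t(vapply(d, quantile, numeric(3), probs = c(0.5, 0.025, 0.975),
                 type = 7, names = FALSE))
  data.frame(parameter = names(d), median = qs[, 1], q2.5 = qs[, 2],
             q97.5 = qs[, 3], row.names = NULL, stringsAsFactors = FALSE)
}
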