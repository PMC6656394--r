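# Independent oracles and small fixtures shared across tests. The oracles
# deliberately avoid the package's Cholesky-based code paths: densities use
# determinant() and solve() on dense matrices, conditioning uses the
# textbook partitioned-covariance formulas, and the hat matrix comes from an
# explicit QR decomposition.

# dense multivariate normal log density
mvn_logdens_oracle <- function(x, mean, Sigma) {
  k <- length(x)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  r <- x - mean
  -0.5 * (k * log(2 * pi) + ld + drop(t(r) %*% solve(Sigma) %*% r))
}

# conditional normal of target given observed under joint exponential GP
cond_mvn_oracle <- function(mu, sigma2, phi, obs_xy, obs_h, target_xy) {
  all_xy <- rbind(obs_xy, target_xy)
  D <- as.matrix(dist(all_xy))
  S <- sigma2 * exp(-phi * D)
  k <- nrow(obs_xy)
  t_idx <- k + seq_len(nrow(target_xy))
  S11 <- S[seq_len(k), seq_len(k), drop = FALSE]
  S21 <- S[t_idx, seq_len(k), drop = FALSE]
  S22 <- S[t_idx, t_idx, drop = FALSE]
  m <- mu + S21 %*% solve(S11, obs_h - mu)
  V <- S22 - S21 %*% solve(S11, t(S21))
  list(mean = unname(drop(m)), var = unname(diag(as.matrix(V))))
}

# hat-matrix diagonal via QR
hat_diag_oracle <- function(X) {
  Q <- qr.Q(qr(X))
  rowSums(Q^2)
}

# minimal handmade area table with observed prevalence everywhere
tiny_areas <- function(n = 5, seed = 11) {
  set.seed(seed)
  data.frame(area_id = sprintf("T%02d", seq_len(n)),
             name = sprintf("T%02d", seq_len(n)),
             lon = runif(n, 0, 2), lat = runif(n, 0, 2),
             male_pop_18_29 = round(exp(runif(n, 9, 12))),
             hiv_prev_pct = round(runif(n, 1, 4), 2),
             stringsAsFactors = FALSE)
}

# areas sampled from a known GP field over the unit square
gp_field_areas <- function(k, mu, sigma2, phi, seed, box = c(0, 1)) {
  set.seed(seed)
  lon <- runif(k, box[1], box[2])
  lat <- runif(k, box[1], box[2])
  D <- as.matrix(dist(cbind(lon, lat)))
  S <- sigma2 * exp(-phi * D) + diag(1e-10, k)
  H <- mu + drop(rnorm(k) %*% chol(S))
  data.frame(area_id = sprintf("G%03d", seq_len(k)),
             name = sprintf("G%03d", seq_len(k)),
             lon = lon, lat = lat,
             male_pop_18_29 = rep(10000L, k),
             hiv_prev_pct = H, stringsAsFactors = FALSE)
}
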