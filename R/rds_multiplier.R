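# Multiplier-method direct estimation from RDS survey data.
#
# An RDS survey reaches a hidden population through chain referral; sampled
# members are reached with probability roughly proportional to their personal
# network size (degree). The RDS-II (Volz--Heckathorn) estimator undoes that
# bias by inverse-degree weighting. Combined with a programme-log total count
# T of population members enrolled at some source (an NGO, a clinic, a social
# event, a unique-object distribution), the multiplier method estimates the
# population size as N = T / p-hat, where p-hat is the estimated proportion of
# the population covered by the source.

.rds_sources <- c("ngo", "service", "social_event", "unique_object")

.check_respondents <- function(respondents) {
  if (!is.data.frame(respondents)) stop("'respondents' must be a data.frame")
  if (!"degree" %in% names(respondents)) stop("missing 'degree' column")
  d <- respondents$degree
  if (nrow(respondents) && (any(!is.finite(d)) || any(d < 1) || any(d != round(d))))
    stop("degrees must be positive integers (zero-degree respondents are rejected, not imputed)")
  invisible(respondents)
}

.membership <- function(respondents, source_label) {
  b <- respondents[[source_label]]
  if (is.null(b))
    stop("source '", source_label, "' was not recorded in this survey")
  if (anyNA(b))
    stop("source '", source_label, "' has respondents with no recorded answer")
  if (!all(b %in% c(0, 1))) stop("membership indicators must be 0/1")
  b
}

#' RDS-II (Volz--Heckathorn) proportion estimator
#'
#' Estimates the proportion of a hidden population belonging to a source
#' (e.g. registered at an NGO) from an RDS sample, weighting each respondent
#' by the inverse of their reported network size:
#' \deqn{\hat p = \frac{\sum_i b_i / d_i}{\sum_i 1 / d_i}}
#' where \eqn{b_i} is the binary membership indicator and \eqn{d_i} the
#' degree. With equal degrees this reduces to the sample proportion. The
#' estimator is invariant to rescaling all degrees by a common constant.
#'
#' @param respondents data.frame with columns `degree` (positive integer) and
#'   one 0/1 column per source (`ngo`, `service`, `social_event`,
#'   `unique_object`); `NA` means the question was not asked.
#' @param source_label name of the membership column to estimate.
#' @return The estimated proportion, in (0, 1].
#' @examples
#' r <- data.frame(degree = c(1, 4), ngo = c(1, 0))
#' rds2_proportion(r, "ngo")  # (1/1) / (1/1 + 1/4) = 0.8
#' @seealso [multiplier_estimate], [rds2_proportion_ci]
#' @export
rds2_proportion <- function(respondents, source_label) {
  .check_respondents(respondents)
  if (nrow(respondents) == 0L) stop("empty respondent list")
  b <- .membership(respondents, source_label)
  if (all(b == 0))
    stop("all indicators are zero for source '", source_label,
         "': multiplier undefined (division by zero)")
  d <- respondents$degree
  sum(b / d) / sum(1 / d)
}

#' Bootstrap confidence interval for the RDS-II proportion
#'
#' Percentile bootstrap over respondents: resample rows with replacement,
#' recompute the RDS-II estimator, and take empirical quantiles. Resamples in
#' which every indicator is zero leave the multiplier undefined; they are
#' discarded (with a warning) and redrawn, up to ten times the requested
#' number of resamples. A recruitment-chain-aware bootstrap would need the
#' referral tree, which the downstream analysis never uses.
#'
#' @inheritParams rds2_proportion
#' @param n_boot number of bootstrap resamples (at least 200).
#' @param confidence interval coverage, default 0.95.
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector `c(low, high)`.
#' @export
rds2_proportion_ci <- function(respondents, source_label, n_boot = 1000L,
                               confidence = 0.95, seed = NULL) {
  if (n_boot < 200L) stop("n_boot must be at least 200")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0,1)")
  .check_respondents(respondents)
  if (nrow(respondents) == 0L) stop("empty respondent list")
  b <- .membership(respondents, source_label)
  d <- respondents$degree
  if (!is.null(seed)) set.seed(seed)
  n <- length(b)
  kept <- numeric(0)
  dropped <- 0L
  tries <- 0L
  while (length(kept) < n_boot) {
    m <- min(n_boot - length(kept), n_boot)
    idx <- matrix(sample.int(n, n * m, replace = TRUE), nrow = n)
    bb <- matrix(b[idx], nrow = n)
    dd <- matrix(d[idx], nrow = n)
    p <- colSums(bb / dd) / colSums(1 / dd)
    ok <- colSums(bb) > 0
    dropped <- dropped + sum(!ok)
    kept <- c(kept, p[ok])
    tries <- tries + m
    if (tries > 10L * n_boot)
      stop("bootstrap retry cap reached: too many degenerate (all-zero) resamples")
  }
  if (dropped > 0L)
    warning(dropped, " degenerate bootstrap resample(s) discarded")
  alpha <- (1 - confidence) / 2
  q <- unname(quantile(kept, c(alpha, 1 - alpha)))
  c(low = q[1], high = q[2])
}

#' Multiplier-method population size estimate
#'
#' Inverts the coverage identity T / N = p: the population size estimate is
#' N-hat = T / p-hat, and the confidence interval for the proportion maps to a
#' size interval with the bounds flipped (a larger covered proportion implies
#' a smaller population).
#'
#' @param total programme-log total count T of population members at the
#'   source (nonnegative).
#' @param p_hat estimated proportion covered, from [rds2_proportion].
#' @param p_ci length-2 proportion interval `c(low, high)` with
#'   `0 < low <= p_hat <= high <= 1`.
#' @param area_id,method_label identifiers carried into the output row.
#' @return One-row data.frame: `area_id`, `method_label`, `n_hat`, `ci_low`,
#'   `ci_high` (persons).
#' @examples
#' multiplier_estimate(100, 0.5, c(0.4, 0.8))  # n_hat 200, CI (125, 250)
#' @export
multiplier_estimate <- function(total, p_hat, p_ci,
                                area_id = NA_character_,
                                method_label = NA_character_) {
  if (length(total) != 1L || !is.finite(total) || total < 0)
    stop("'total' must be a single nonnegative count")
  if (p_hat <= 0) stop("p_hat = 0: multiplier undefined")
  if (length(p_ci) != 2L) stop("p_ci must be c(low, high)")
  lo <- p_ci[[1]]; hi <- p_ci[[2]]
  if (!(lo > 0 && lo <= p_hat && p_hat <= hi && hi <= 1))
    stop("p_ci must satisfy 0 < low <= p_hat <= high <= 1")
  if (total == 0) {
    warning("source total is 0: size estimate is 0")
    return(data.frame(area_id = area_id, method_label = method_label,
                      n_hat = 0, ci_low = 0, ci_high = 0,
                      stringsAsFactors = FALSE))
  }
  data.frame(area_id = area_id, method_label = method_label,
             n_hat = total / p_hat, ci_low = total / hi, ci_high = total / lo,
             stringsAsFactors = FALSE)
}

#' Direct estimates for every available source in an RDS survey
#'
#' Runs the RDS-II estimator, its bootstrap interval, and the multiplier
#' inversion for each source that has both a programme-log total and recorded
#' survey answers. Sources with no survey answers are skipped.
#'
#' @inheritParams rds2_proportion_ci
#' @param source_counts data.frame with columns `source_label` and `total`.
#' @param area_id identifier attached to the output rows.
#' @return data.frame of direct estimates, one row per usable source.
#' @export
direct_estimates_from_rds <- function(respondents, source_counts, area_id,
                                      n_boot = 1000L, confidence = 0.95,
                                      seed = NULL) {
  if (!all(c("source_label", "total") %in% names(source_counts)))
    stop("source_counts needs columns source_label, total")
  if (any(source_counts$total < 0)) stop("source totals must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nrow(source_counts)), function(i) {
    src <- source_counts$source_label[i]
    b <- respondents[[src]]
    if (is.null(b) || all(is.na(b))) return(NULL)
    asked <- respondents[!is.na(b), , drop = FALSE]
    p <- rds2_proportion(asked, src)
    ci <- rds2_proportion_ci(asked, src, n_boot = n_boot,
                             confidence = confidence)
    ci[1] <- min(ci[1], p); ci[2] <- max(ci[2], p)  # guard MC edge cases
    multiplier_estimate(source_counts$total[i], p, ci,
                        area_id = area_id, method_label = src)
  })
  do.call(rbind, out)
}

#' Packaged multiplier-method direct estimates for Cote d'Ivoire
#'
#' The 19 published multiplier-method size estimates (with 95% confidence
#' intervals) of MSM aged 18--29 in five departments of Cote d'Ivoire:
#' Abidjan (two NGO membership lists, service, social event, unique object),
#' Agboville, Bouake, Gagnoa, and Yamoussoukro. These are statistical
#' end-products of surveys whose raw records are not public; the exact
#' interval construction behind them is not documented, so they serve as an
#' input fixture for the extrapolation stages, not as a reference output.
#'
#' @return data.frame with columns `area_id`, `method_label`, `n_hat`,
#'   `ci_low`, `ci_high`.
#' @export
civ_direct_estimates <- function() {
  path <- system.file("extdata", "civ_direct_estimates.csv", package = "kpsae",
                      mustWork = TRUE)
  read_direct_estimates(path)
}
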