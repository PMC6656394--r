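# CSV readers/writers for every schema and the pipeline driver. Missing
# values are empty cells, never sentinel numbers.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read an area table
#'
#' Columns: `area_id`, `name`, `lon`, `lat`, `male_pop_18_29`,
#' `hiv_prev_pct` (empty cell = missing), plus any optional covariate
#' columns. Duplicate ids and nonpositive populations are errors naming the
#' offending row.
#'
#' @param path CSV path.
#' @return Validated area data.frame.
#' @export
read_area_table <- function(path) {
  df <- .need_cols(.read_csv(path),
                   c("area_id", "name", "lon", "lat", "male_pop_18_29",
                     "hiv_prev_pct"), "area table")
  df$hiv_prev_pct <- suppressWarnings(as.numeric(df$hiv_prev_pct))
  if (any(!is.na(df$hiv_prev_pct) & df$hiv_prev_pct < 0))
    stop("negative HIV prevalence")
  .check_area_table(df)
  df
}

#' @rdname read_area_table
#' @param areas area data.frame to write.
#' @export
write_area_table <- function(areas, path) {
  .check_area_table(areas)
  write.csv(areas, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write a direct-estimate table
#'
#' Columns: `area_id`, `method_label`, `n_hat`, `ci_low`, `ci_high`.
#' Enforces `0 < ci_low <= n_hat <= ci_high`.
#'
#' @param path CSV path.
#' @export
read_direct_estimates <- function(path) {
  df <- .need_cols(.read_csv(path),
                   c("area_id", "method_label", "n_hat", "ci_low", "ci_high"),
                   "direct-estimate table")
  bad <- which(!(df$ci_low > 0 & df$ci_low <= df$n_hat &
                   df$n_hat <= df$ci_high))
  if (length(bad))
    stop("invalid estimate interval in row(s) ", paste(bad, collapse = ", "),
         " (need 0 < ci_low <= n_hat <= ci_high)")
  df
}

#' @rdname read_direct_estimates
#' @param estimates direct-estimate data.frame.
#' @export
write_direct_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write regression observations
#'
#' Columns: `area_id`, `method_label`, `y`, `w` (w > 0).
#'
#' @param path CSV path.
#' @export
read_observations <- function(path) {
  df <- .need_cols(.read_csv(path), c("area_id", "method_label", "y", "w"),
                   "observation table")
  if (any(df$w <= 0)) stop("weights w must be positive")
  df
}

#' @rdname read_observations
#' @param observations observation data.frame.
#' @export
write_observations <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read or write posterior draws
#'
#' The draws CSV has one column per parameter and one row per retained draw;
#' a JSON sidecar (`<path stem>_meta.json`) records the seed, configuration,
#' acceptance rates and effective sample sizes.
#'
#' @param path CSV path for the draws.
#' @return For `read_draws`, a `kpsae_draws` object (metadata restored when
#'   the sidecar exists).
#' @export
read_draws <- function(path) {
  df <- .read_csv(path)
  need <- c("beta0", "beta1", "beta2", "tau2", "mu", "sigma2", "phi")
  .need_cols(df, need, "draws table")
  meta_path <- sub("\\.csv$", "_meta.json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  structure(list(draws = df[need],
                 acceptance = unlist(meta$acceptance),
                 ess = unlist(meta$ess),
                 config = meta$config, fix = meta$fix),
            class = "kpsae_draws")
}

#' @rdname read_draws
#' @param draws a `kpsae_draws` object.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "kpsae_draws"))
  write.csv(draws$draws, path, row.names = FALSE)
  meta_path <- sub("\\.csv$", "_meta.json", path)
  jsonlite::write_json(list(acceptance = as.list(draws$acceptance),
                            ess = as.list(draws$ess),
                            config = draws$config[c("n_iter", "n_burn",
                                                    "seed", "thin")],
                            fix = draws$fix),
                       meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read or write a prediction summary table
#'
#' The shape of the published prediction table: `area_id`, `name`,
#' `n_median`, `n_low`, `n_high`, `pct_median`, `relative_width`,
#' `hiv_was_imputed`, `leverage`.
#'
#' @param path CSV path.
#' @export
read_predictions <- function(path) {
  .need_cols(.read_csv(path),
             c("area_id", "n_median", "n_low", "n_high", "pct_median",
               "relative_width", "hiv_was_imputed"), "prediction table")
}

#' @rdname read_predictions
#' @param predictions prediction summary data.frame.
#' @export
write_predictions <- function(predictions, path) {
  write.csv(predictions, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML file whose keys mirror the [run_pipeline] configuration list
#' verbatim: `area_csv`, `estimates_csv`, `out_dir`, `seed`, `mcmc`
#' (`n_iter`, `n_burn`, `thin`), `truncation_q`, `ci_level`,
#' `joint_missing_draws`, `truncate_count_N`, `loocv_scale`.
#'
#' @param path YAML path.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.stage <- function(name, expr) {
  message("[", name, "] starting")
  out <- tryCatch(expr, error = function(e)
    stop("pipeline failed at stage [", name, "]: ", conditionMessage(e),
         call. = FALSE))
  message("[", name, "] done")
  out
}

#' Run the full estimation pipeline
#'
#' Reads the area and direct-estimate tables, builds the regression data,
#' samples the joint posterior, predicts every area by composition sampling,
#' and writes five artifacts to the output directory: `draws.csv` (with its
#' `draws_meta.json` sidecar), `posterior_summary.csv`, `predictions.csv`,
#' `imputation.csv`, and `manifest.json` (seed, configuration, versions).
#' Any stage error aborts with the stage name; artifacts written before the
#' failure are left in place.
#'
#' @param config configuration list (see [read_run_config]) or path to a
#'   YAML file. Required: `area_csv`, `estimates_csv`, `out_dir`. Optional:
#'   `seed` (default 1), `mcmc` (`n_iter` 30000, `n_burn` 15000, `thin` 1),
#'   `truncation_q` (0.10), `ci_level` (0.95), `joint_missing_draws`
#'   (FALSE), `truncate_count_N` (FALSE).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("area_csv", "estimates_csv", "out_dir"))
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mc <- config$mcmc
  cfg <- mcmc_config(n_iter = if (is.null(mc$n_iter)) 30000L else mc$n_iter,
                     n_burn = if (is.null(mc$n_burn)) 15000L else mc$n_burn,
                     thin = if (is.null(mc$thin)) 1L else mc$thin,
                     seed = seed)
  trunc_q <- if (is.null(config$truncation_q)) 0.10 else config$truncation_q
  level <- if (is.null(config$ci_level)) 0.95 else config$ci_level
  if (level <= 0 || level >= 1) stop("ci_level must be in (0, 1)")

  inputs <- .stage("read", list(
    estimates = read_direct_estimates(config$estimates_csv),
    areas = read_area_table(config$area_csv)))
  areas <- inputs$areas
  estimates <- inputs$estimates

  obs <- .stage("prepare", prepare_regression_data(estimates, areas))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- .stage("mcmc", run_mcmc(obs, areas, cfg))
  write_draws(draws, file.path(config$out_dir, "draws.csv"))
  write.csv(posterior_summary(draws),
            file.path(config$out_dir, "posterior_summary.csv"),
            row.names = FALSE)

  pred <- .stage("predict", {
    thr <- population_truncation_threshold(areas, trunc_q)
    predict_msm(areas, draws, threshold = thr, seed = seed + 1L,
                joint = isTRUE(config$joint_missing_draws),
                truncate_count_N = isTRUE(config$truncate_count_N))
  })
  tr_ids <- unique(obs$area_id)
  Xtr <- build_design(areas[match(tr_ids, areas$area_id), , drop = FALSE])
  Xtr <- Xtr[match(obs$area_id, tr_ids), , drop = FALSE]
  summ <- summarize_predictions(pred, training_design = Xtr, level = level)
  write_predictions(summ, file.path(config$out_dir, "predictions.csv"))

  .stage("imputation", {
    alpha <- (1 - level) / 2
    hq <- apply(pred$hiv, 2, quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    imp <- data.frame(area_id = areas$area_id,
                      hiv_prev_pct_imputed = colMeans(pred$hiv),
                      sd = apply(pred$hiv, 2, sd),
                      q2.5 = hq[1, ], q97.5 = hq[2, ],
                      was_observed = !is.na(areas$hiv_prev_pct))
    write.csv(imp, file.path(config$out_dir, "imputation.csv"),
              row.names = FALSE)
  })

  manifest <- list(seed = seed,
                   config = config[setdiff(names(config), "out_dir")],
                   package_version = as.character(utils::packageVersion("kpsae")),
                   r_version = R.version.string,
                   n_areas = nrow(areas), n_observations = nrow(obs),
                   acceptance = as.list(draws$acceptance),
                   ess = as.list(draws$ess),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
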