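#' Assemble and validate a full pipeline run configuration
#'
#' A run takes either the three input CSV paths (counts, sunshine, station
#' map) or a synthetic-data configuration — exactly one of the two. The
#' remaining fields control ingest filtering, the target and validation
#' periods, and the bootstrap.
#'
#' @param counts,sunshine,station_map Input CSV paths (see [read_counts()],
#'   [read_sunshine()], [read_station_map()]), or all `NULL` when running on
#'   synthetic data.
#' @param synthetic A [synthetic_config()], or a list of arguments for it;
#'   `NULL` when running on files.
#' @param year_min First year retained (and year-index origin).
#' @param winter_months Months excluded from the analysis window.
#' @param urban_min_attempts,urban_min_users,rural_min_attempts,rural_min_users,min_length_m
#'   Segment eligibility thresholds, see [filter_segments()].
#' @param target_period List `(year, months)` of the shock period whose
#'   effect is estimated.
#' @param validation_period List `(year, months)` of a shock-free period
#'   used to check that the counterfactuals return null effects; `NULL`
#'   skips validation.
#' @param n_boot Bootstrap replicates per effect estimate.
#' @param seed Master seed; every stochastic step derives its seed from it.
#' @param percent_diff_mode See [estimate_effect()].
#' @param out_dir Output directory for CSV tables and the run manifest;
#'   `NULL` returns results without writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts = NULL, sunshine = NULL, station_map = NULL,
                       synthetic = NULL,
                       year_min = 2012,
                       winter_months = c(12L, 1L, 2L),
                       urban_min_attempts = 1500, urban_min_users = 350,
                       rural_min_attempts = 600, rural_min_users = 200,
                       min_length_m = 500,
                       target_period = list(year = 2020, months = 3:6),
                       validation_period = list(year = 2019, months = 7:10),
                       n_boot = 10000, seed = 1L,
                       percent_diff_mode = "per_segment_median",
                       out_dir = NULL) {
  have_files <- !is.null(counts) || !is.null(sunshine) ||
    !is.null(station_map)
  if (have_files == !is.null(synthetic)) {
    rlang::abort(paste0("Provide exactly one input source: either the ",
                        "counts/sunshine/station_map paths or `synthetic`."))
  }
  if (have_files && (is.null(counts) || is.null(sunshine) ||
                       is.null(station_map))) {
    rlang::abort("File input needs `counts`, `sunshine` and `station_map`.")
  }
  cfg <- list(counts = counts, sunshine = sunshine,
              station_map = station_map, synthetic = synthetic,
              year_min = as.integer(year_min),
              winter_months = as.integer(winter_months),
              urban_min_attempts = urban_min_attempts,
              urban_min_users = urban_min_users,
              rural_min_attempts = rural_min_attempts,
              rural_min_users = rural_min_users,
              min_length_m = min_length_m,
              target_period = target_period,
              validation_period = validation_period,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              percent_diff_mode = percent_diff_mode,
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `synthetic` may be
#' a mapping of [synthetic_config()] arguments, and the periods are mappings
#' with `year` and `months`.
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Unknown config key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

period_label <- function(year, months) {
  if (length(months) == 1) {
    sprintf("%d-%02d", year, months)
  } else {
    sprintf("%d-%02d..%02d", year, min(months), max(months))
  }
}

#' Run the full counterfactual pipeline
#'
#' Executes ingest (deduplication, eligibility filtering, temporal window,
#' sunshine join), per-segment-month Poisson model fitting with AIC
#' selection, counterfactual prediction, and bootstrap effect estimation for
#' the target period and (if configured) the shock-free validation period.
#' Effects are estimated per stratum, both pooled over the period's months
#' and month by month. The run is deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `effects` (tibble of effect estimates),
#'   `selection` (model-selection tallies per period), `counterfactuals`
#'   (per period), `reports` (ingest errors, segment drops, unfit cells,
#'   per-stage row counts), and `manifest` (all parameters, seed, package
#'   version). With `out_dir` set, the tables and a YAML manifest are also
#'   written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$synthetic)) {
    scfg <- if (inherits(config$synthetic, "synthetic_config")) {
      config$synthetic
    } else {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      do.call(synthetic_config, args)
    }
    ds <- generate_dataset(scfg)
    observations <- ds$observations[, c("segment_id", "stratum", "year",
                                        "month", "count")]
    segments <- ds$segments
    sunshine <- ds$sunshine
    station_map <- ds$station_map
    read_errors <- tibble::tibble()
  } else {
    counts <- read_counts(config$counts)
    observations <- counts$observations
    segments <- counts$segments
    read_errors <- counts$errors
    sunshine <- read_sunshine(config$sunshine)
    station_map <- read_station_map(config$station_map)
  }

  stages <- list(input = nrow(observations))
  observations <- deduplicate(observations)
  stages$deduplicated <- nrow(observations)
  filt <- filter_segments(segments, observations,
                          urban_min_attempts = config$urban_min_attempts,
                          urban_min_users = config$urban_min_users,
                          rural_min_attempts = config$rural_min_attempts,
                          rural_min_users = config$rural_min_users,
                          min_length_m = config$min_length_m)
  stages$eligible <- nrow(filt$observations)
  observations <- apply_temporal_window(filt$observations,
                                        year_min = config$year_min,
                                        winter_months = config$winter_months)
  stages$in_window <- nrow(observations)
  joined <- join_sunshine(observations, sunshine, station_map)
  observations <- joined$observations
  stages$with_sunshine <- nrow(observations)

  periods <- list(target = config$target_period)
  if (!is.null(config$validation_period)) {
    periods$validation <- config$validation_period
  }

  effects <- list()
  selection <- list()
  counterfactuals <- list()
  unfit <- list()
  seed_offset <- 0L
  for (pname in names(periods)) {
    p <- periods[[pname]]
    training_years <- config$year_min:(p$year - 1L)
    cf <- run_counterfactuals(observations, p$year, p$months,
                              training_years, year_min = config$year_min)
    counterfactuals[[pname]] <- cf$counterfactuals
    selection[[pname]] <- dplyr::mutate(cf$selection_tally, period = pname)
    unfit[[pname]] <- cf$unfit
    for (stratum in intersect(c("urban", "rural"),
                              unique(cf$counterfactuals$stratum))) {
      pooled_months <- p$months
      for (months in c(list(pooled_months),
                       if (length(pooled_months) > 1) {
                         as.list(pooled_months)
                       })) {
        sub <- cf$counterfactuals[cf$counterfactuals$month %in% months, ,
                                  drop = FALSE]
        if (sum(sub$stratum == stratum) < 2) next
        seed_offset <- seed_offset + 1L
        effects[[length(effects) + 1L]] <- estimate_effect(
          sub, stratum,
          period_label = period_label(p$year, months),
          n_boot = config$n_boot,
          seed = config$seed + 1000L * seed_offset,
          percent_diff_mode = config$percent_diff_mode
        )
      }
    }
  }
  effects <- dplyr::bind_rows(effects)
  selection <- dplyr::bind_rows(selection)

  manifest <- list(
    package = "cycleshift",
    version = as.character(utils::packageVersion("cycleshift")),
    seed = config$seed,
    n_boot = config$n_boot,
    year_min = config$year_min,
    winter_months = config$winter_months,
    eligibility = list(urban_min_attempts = config$urban_min_attempts,
                       urban_min_users = config$urban_min_users,
                       rural_min_attempts = config$rural_min_attempts,
                       rural_min_users = config$rural_min_users,
                       min_length_m = config$min_length_m),
    target_period = config$target_period,
    validation_period = config$validation_period,
    percent_diff_mode = config$percent_diff_mode,
    input = if (is.null(config$synthetic)) {
      list(counts = config$counts, sunshine = config$sunshine,
           station_map = config$station_map)
    } else {
      c(list(source = "synthetic"),
        unclass(scfg)[setdiff(names(scfg), "shock_months")],
        list(shock_months = paste(scfg$shock_months$year,
                                  scfg$shock_months$month, sep = "-")))
    },
    row_counts = stages
  )

  result <- list(effects = effects,
                 selection = selection,
                 counterfactuals = counterfactuals,
                 reports = list(read_errors = read_errors,
                                segment_drops = filt$report,
                                sunshine_dropped = joined$dropped,
                                unfit = dplyr::bind_rows(unfit),
                                row_counts = tibble::tibble(
                                  stage = names(stages),
                                  rows = unlist(stages))),
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_effects(effects, file.path(config$out_dir, "effects.csv"))
    readr::write_csv(selection,
                     file.path(config$out_dir, "model_selection.csv"))
    readr::write_csv(result$reports$segment_drops,
                     file.path(config$out_dir, "segment_drops.csv"))
    readr::write_csv(result$reports$unfit,
                     file.path(config$out_dir, "unfit_cells.csv"))
    readr::write_csv(result$reports$row_counts,
                     file.path(config$out_dir, "row_counts.csv"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }
  invisible(result)
}

#' Quick internal consistency checks
#'
#' Runs a handful of fast, deterministic sanity checks of the statistical
#' core: closed-form Poisson MLEs, exact recovery of log-linear data, the
#' AIC identity, the reduction of the BCa interval to the percentile
#' interval in the symmetric case, and a small-sample bootstrap check
#' against exhaustive enumeration. Failures are reported, not raised.
#'
#' @return Tibble with columns `check` and `passed`; printed as a summary.
#' @export
selftest <- function() {
  checks <- list()
  add <- function(name, passed) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(check = name,
                                                     passed = isTRUE(passed))
  }

  f <- fit_poisson(matrix(1, 3, 1, dimnames = list(NULL, "intercept")),
                   c(3, 3, 3))
  add("intercept-only MLE equals log of the mean",
      f$converged && abs(f$coefficients[[1]] - log(3)) < 1e-8)

  d <- build_design(tibble::tibble(year = 2012:2015, count = c(1, 2, 4, 8)),
                    "A", year_min = 2012)
  f <- fit_poisson(d$X, d$y)
  add("exact log-linear counts recovered exactly",
      f$converged && abs(f$coefficients[["year"]] - log(2)) < 1e-6 &&
        abs(f$coefficients[["intercept"]]) < 1e-6)

  ll <- f$log_likelihood
  add("AIC identity 2k - 2logLik", abs(aic(ll, 2) - (4 - 2 * ll)) < 1e-12)

  boot_dist <- rep(1:10, each = 10)
  ci <- bca_interval(NULL, boot_dist, 5.5, jackknife = rep(2, 5))
  pct <- boot_quantile(boot_dist, c(0.025, 0.975))
  add("BCa reduces to percentile when z0 = a = 0",
      ci$components$z0 == 0 && ci$components$a == 0 &&
        ci$low == pct[1] && ci$high == pct[2])

  vals <- c(1, 2, 9)
  bd <- bootstrap_statistic(vals, stats::median, n_boot = 20000, seed = 42)
  p_hat <- mean(bd == 1)
  p_exact <- 7 / 27  # resamples whose median is the smallest value
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  add("bootstrap matches exhaustive enumeration (n = 3)",
      abs(p_hat - p_exact) < 3 * se)

  out <- dplyr::bind_rows(checks)
  n_bad <- sum(!out$passed)
  cat(sprintf("cycleshift selftest: %d/%d checks passed\n",
              nrow(out) - n_bad, nrow(out)))
  if (n_bad > 0) {
    cat("FAILED:", paste(out$check[!out$passed], collapse = "; "), "\n")
  }
  invisible(out)
}
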