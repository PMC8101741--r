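#' Configuration for the synthetic segment-count generator
#'
#' Builds and validates the generative parameters for [generate_dataset()].
#' The generator emulates the structure of crowdsourced fitness-app segment
#' leaderboards joined with weather-station sunshine hours: multi-year monthly
#' activity counts per trail segment with a multiplicative year trend (growing
#' user base), a log-linear sunshine effect, Poisson noise, an urban/rural
#' stratum, and an optional multiplicative shock in designated months.
#'
#' The expected count for segment \eqn{s} in year \eqn{t} (indexed from
#' `year_start`) and calendar month \eqn{m} is
#' \deqn{\mu = b_{stratum} \cdot g^{t} \cdot w_m \cdot
#'   \exp\{\beta_s (S - \bar S_m) + \beta_i t (S - \bar S_m)\} \cdot shock}
#' where \eqn{b} is `baseline_rate`, \eqn{g} is `growth_rate`, \eqn{w_m} is
#' `winter_damping` for winter months (1 otherwise), \eqn{S} the simulated
#' sunshine hours, \eqn{\bar S_m} the monthly climatological mean, and the
#' shock multiplier applies only in `shock_months`. Counts are drawn
#' Poisson(\eqn{\mu}) (or negative binomial if `dispersion` is set).
#'
#' @param n_urban_segments,n_rural_segments Number of eligible segments per
#'   stratum. Defaults mirror the study design (30 urban, 14 rural).
#' @param year_start,year_end First and last calendar year generated.
#' @param baseline_rate Named vector `c(urban = , rural = )` of expected
#'   counts per month in `year_start` for a non-winter month at mean sunshine.
#' @param growth_rate Multiplicative per-year factor on the expected count
#'   (> 0); 1.1 means 10\% annual growth of activity.
#' @param sunshine_coef Log-scale coefficient per sunshine hour (1/hour).
#' @param interaction_coef Log-scale year-by-sunshine interaction coefficient
#'   (1/(year*hour)); default 0.
#' @param sunshine_mean_by_month Length-12 vector of mean monthly sunshine
#'   hours (January first). Default follows a central-European climatology.
#' @param sunshine_sd Standard deviation of monthly sunshine hours around the
#'   monthly mean (hours); draws are truncated at 0.
#' @param winter_months Calendar months generated at a reduced baseline.
#' @param winter_damping Multiplicative factor on the baseline in winter
#'   months (the analysis is expected to exclude them; they are generated so
#'   the exclusion rule has something to act on).
#' @param shock_months Data frame with columns `year` and `month` naming the
#'   months that receive the shock multiplier.
#' @param shock_multiplier_urban,shock_multiplier_rural Multiplicative shock
#'   on the expected count in `shock_months` (>= 0); 1 encodes "no effect"
#'   exactly. Defaults emulate the study's shock period: a +55\% urban shift
#'   and no rural shift.
#' @param dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) draws pure Poisson counts, matching the fitted family.
#' @param segments_per_region Co-located segments sharing one weather
#'   station (the study sampled two segments per city or nature park).
#' @param n_decoy_segments Number of additional ineligible segments (failing
#'   the attempts/users/length filters) to generate, for testing the filters.
#' @param seed Integer RNG seed; the generator is deterministic given the
#'   full configuration.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [generate_dataset()], [write_dataset()]
#' @export
synthetic_config <- function(n_urban_segments = 30,
                             n_rural_segments = 14,
                             year_start = 2012,
                             year_end = 2020,
                             baseline_rate = c(urban = 100, rural = 30),
                             growth_rate = 1.1,
                             sunshine_coef = 0.002,
                             interaction_coef = 0,
                             sunshine_mean_by_month = c(45, 70, 120, 165, 210,
                                                        220, 225, 205, 155,
                                                        105, 55, 40),
                             sunshine_sd = 30,
                             winter_months = c(12L, 1L, 2L),
                             winter_damping = 0.4,
                             shock_months = data.frame(year = 2020L,
                                                       month = 3:6),
                             shock_multiplier_urban = 1.55,
                             shock_multiplier_rural = 1,
                             dispersion = NULL,
                             segments_per_region = 2,
                             n_decoy_segments = 0,
                             seed = 1L) {
  cfg <- list(
    n_urban_segments = as.integer(n_urban_segments),
    n_rural_segments = as.integer(n_rural_segments),
    year_start = as.integer(year_start),
    year_end = as.integer(year_end),
    baseline_rate = baseline_rate,
    growth_rate = growth_rate,
    sunshine_coef = sunshine_coef,
    interaction_coef = interaction_coef,
    sunshine_mean_by_month = sunshine_mean_by_month,
    sunshine_sd = sunshine_sd,
    winter_months = as.integer(winter_months),
    winter_damping = winter_damping,
    shock_months = tibble::as_tibble(shock_months),
    shock_multiplier_urban = shock_multiplier_urban,
    shock_multiplier_rural = shock_multiplier_rural,
    dispersion = dispersion,
    segments_per_region = as.integer(segments_per_region),
    n_decoy_segments = as.integer(n_decoy_segments),
    seed = as.integer(seed)
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$year_start >= cfg$year_end) {
    rlang::abort("`year_start` must be before `year_end`.")
  }
  if (!is.finite(cfg$growth_rate) || cfg$growth_rate <= 0) {
    rlang::abort("`growth_rate` must be a finite positive number.")
  }
  if (!all(c("urban", "rural") %in% names(cfg$baseline_rate))) {
    rlang::abort("`baseline_rate` needs named entries 'urban' and 'rural'.")
  }
  if (any(!is.finite(cfg$baseline_rate)) || any(cfg$baseline_rate <= 0)) {
    rlang::abort("`baseline_rate` entries must be finite and positive.")
  }
  if (length(cfg$sunshine_mean_by_month) != 12L) {
    rlang::abort("`sunshine_mean_by_month` must have 12 entries.")
  }
  if (cfg$shock_multiplier_urban < 0 || cfg$shock_multiplier_rural < 0) {
    rlang::abort("Shock multipliers must be >= 0.")
  }
  if (!all(c("year", "month") %in% names(cfg$shock_months))) {
    rlang::abort("`shock_months` needs columns `year` and `month`.")
  }
  if (cfg$n_urban_segments < 1 || cfg$n_rural_segments < 0) {
    rlang::abort("Need at least one urban segment and >= 0 rural segments.")
  }
  invisible(cfg)
}

# Metadata draws that guarantee eligibility under the default filters
# (urban: attempts > 1500 & users > 350; rural: attempts > 600 & users > 200;
# both: length >= 500 m). Decoys deliberately fail one criterion.
draw_segment_meta <- function(n, stratum, decoy = FALSE) {
  if (n == 0L) {
    return(tibble::tibble(segment_id = character(), stratum = character(),
                          attempts_total = integer(), users_total = integer(),
                          length_m = double()))
  }
  lo <- if (stratum == "urban") c(attempts = 1600L, users = 400L)
        else c(attempts = 700L, users = 250L)
  hi <- if (stratum == "urban") c(attempts = 20000L, users = 3000L)
        else c(attempts = 6000L, users = 1500L)
  meta <- tibble::tibble(
    stratum = stratum,
    attempts_total = sample(lo[["attempts"]]:hi[["attempts"]], n, TRUE),
    users_total = sample(lo[["users"]]:hi[["users"]], n, TRUE),
    length_m = round(stats::runif(n, 500, 5000), 0)
  )
  if (decoy) {
    fail <- rep_len(c("attempts", "users", "length"), n)
    meta$attempts_total[fail == "attempts"] <-
      if (stratum == "urban") 1500L else 600L
    meta$users_total[fail == "users"] <-
      if (stratum == "urban") 350L else 200L
    meta$length_m[fail == "length"] <- 400
  }
  meta
}

#' Generate a synthetic segment-count dataset
#'
#' Draws a complete dataset (segment metadata, monthly observations, monthly
#' station sunshine hours, segment-to-station map) under the generative model
#' described in [synthetic_config()]. Segments within one region share one
#' weather-station sunshine series, mirroring the closest-station join that
#' the real data acquisition performs. All twelve calendar months are
#' generated, including winter months at a damped baseline: excluding winter
#' is the ingest step's job, not the generator's.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `synthetic_dataset` with elements `segments`,
#'   `observations` (one row per segment-year-month, carrying the drawn
#'   `sunshine_hours`), `sunshine` (per station-year-month), `station_map`,
#'   and `truth` (the configuration used).
#' @examples
#' ds <- generate_dataset(synthetic_config(n_urban_segments = 4,
#'                                         n_rural_segments = 2,
#'                                         seed = 7))
#' head(ds$observations)
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  strata <- c(rep("urban", cfg$n_urban_segments),
              rep("rural", cfg$n_rural_segments))
  n_dec_u <- ceiling(cfg$n_decoy_segments / 2)
  n_dec_r <- cfg$n_decoy_segments - n_dec_u

  meta <- dplyr::bind_rows(
    draw_segment_meta(cfg$n_urban_segments, "urban"),
    draw_segment_meta(cfg$n_rural_segments, "rural"),
    draw_segment_meta(n_dec_u, "urban", decoy = TRUE),
    draw_segment_meta(n_dec_r, "rural", decoy = TRUE)
  )
  meta$segment_id <- sprintf("seg_%s_%03d", substr(meta$stratum, 1, 1),
                             seq_len(nrow(meta)))
  # regions group co-located segments (two per city / nature park by default)
  region_index <- stats::ave(seq_len(nrow(meta)), meta$stratum,
                             FUN = function(i) {
                               ceiling(seq_along(i) / cfg$segments_per_region)
                             })
  meta$region <- sprintf("%s_%02d",
                         ifelse(meta$stratum == "urban", "city", "park"),
                         region_index)
  segments <- meta[, c("segment_id", "stratum", "region", "attempts_total",
                       "users_total", "length_m")]
  station_map <- tibble::tibble(segment_id = segments$segment_id,
                                station_id = paste0("st_", segments$region))

  years <- cfg$year_start:cfg$year_end
  stations <- sort(unique(station_map$station_id))
  sunshine <- tidyr::expand_grid(station_id = stations, year = years,
                                 month = 1:12)
  sunshine$sunshine_hours <- pmax(
    0,
    round(stats::rnorm(nrow(sunshine),
                       mean = cfg$sunshine_mean_by_month[sunshine$month],
                       sd = cfg$sunshine_sd), 1)
  )

  obs <- tidyr::expand_grid(segment_id = segments$segment_id,
                            year = years, month = 1:12)
  obs <- dplyr::left_join(obs, segments[, c("segment_id", "stratum")],
                          by = "segment_id")
  obs <- dplyr::left_join(obs, station_map, by = "segment_id")
  obs <- dplyr::left_join(obs, sunshine,
                          by = c("station_id", "year", "month"))
  obs <- dplyr::arrange(obs, .data$segment_id, .data$year, .data$month)

  t_idx <- obs$year - cfg$year_start
  s_dev <- obs$sunshine_hours - cfg$sunshine_mean_by_month[obs$month]
  shock_key <- paste(cfg$shock_months$year, cfg$shock_months$month)
  in_shock <- paste(obs$year, obs$month) %in% shock_key
  shock <- ifelse(in_shock,
                  ifelse(obs$stratum == "urban",
                         cfg$shock_multiplier_urban,
                         cfg$shock_multiplier_rural),
                  1)
  mu <- cfg$baseline_rate[obs$stratum] *
    cfg$growth_rate^t_idx *
    ifelse(obs$month %in% cfg$winter_months, cfg$winter_damping, 1) *
    exp(cfg$sunshine_coef * s_dev + cfg$interaction_coef * t_idx * s_dev) *
    shock
  if (any(!is.finite(mu))) {
    rlang::abort("Configuration produces non-finite expected counts.")
  }
  if (any(mu > 1e9)) {
    rlang::abort("Expected counts exceed 1e9; reduce growth or baseline.")
  }
  obs$count <- if (is.null(cfg$dispersion)) {
    stats::rpois(nrow(obs), mu)
  } else {
    stats::rnbinom(nrow(obs), mu = mu, size = cfg$dispersion)
  }

  structure(
    list(segments = segments,
         observations = tibble::as_tibble(
           obs[, c("segment_id", "stratum", "year", "month", "count",
                   "station_id", "sunshine_hours")]
         ),
         sunshine = sunshine,
         station_map = station_map,
         truth = cfg),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset>\n")
  cat("  segments:    ", nrow(x$segments), " (",
      sum(x$segments$stratum == "urban"), " urban, ",
      sum(x$segments$stratum == "rural"), " rural)\n", sep = "")
  cat("  observations:", nrow(x$observations), "\n")
  cat("  years:       ", x$truth$year_start, "-", x$truth$year_end, "\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic dataset to the CSV dialect the ingest module reads
#'
#' Emits the counts table (one row per segment-year-month, with the segment
#' metadata denormalised onto every row), the station sunshine table, and
#' optionally the segment-to-station map. Winter months and any ineligible
#' decoy segments are written as-is: filtering is the ingest module's job,
#' and a round trip through [read_counts()], [deduplicate()],
#' [filter_segments()], [apply_temporal_window()] and [join_sunshine()]
#' reproduces the eligible, in-window observations exactly.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param counts_path,sunshine_path,station_map_path Output CSV paths;
#'   `station_map_path` may be `NULL` to skip the map.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, counts_path, sunshine_path,
                          station_map_path = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  counts <- dplyr::left_join(dataset$observations, dataset$segments,
                             by = c("segment_id", "stratum"))
  counts <- counts[, c("segment_id", "stratum", "region", "year", "month",
                       "count", "attempts_total", "users_total", "length_m")]
  readr::write_csv(counts, counts_path)
  readr::write_csv(dataset$sunshine[, c("station_id", "year", "month",
                                        "sunshine_hours")],
                   sunshine_path)
  paths <- c(counts = counts_path, sunshine = sunshine_path)
  if (!is.null(station_map_path)) {
    readr::write_csv(dataset$station_map, station_map_path)
    paths <- c(paths, station_map = station_map_path)
  }
  invisible(paths)
}
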