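#' Read a monthly segment-counts table
#'
#' Parses the counts CSV (columns `segment_id, stratum, region, year, month,
#' count, attempts_total, users_total, length_m`) into monthly observations
#' plus per-segment metadata. Malformed rows (non-integer counts, months
#' outside 1-12, unknown strata, ...) are collected into a row-level error
#' report rather than silently dropped; a missing required column is a hard
#' error.
#'
#' @param path Path to the counts CSV (UTF-8, header row, "." decimal).
#' @return A list with `observations` (tibble: segment_id, stratum, year,
#'   month, count), `segments` (tibble of distinct segment metadata), and
#'   `errors` (tibble: line, field, value, problem; `line` counts the header
#'   as line 1).
#' @export
read_counts <- function(path) {
  required <- c("segment_id", "stratum", "region", "year", "month", "count",
                "attempts_total", "users_total", "length_m")
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("Counts file is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }

  errors <- list()
  flag <- function(bad, field, value, problem) {
    if (any(bad)) {
      errors[[length(errors) + 1L]] <<- tibble::tibble(
        line = which(bad) + 1L, field = field,
        value = value[bad], problem = problem
      )
    }
    bad
  }

  bad <- flag(!check_integerish(raw$year), "year", raw$year,
              "not an integer year")
  bad <- bad | flag(!check_integerish(raw$month) |
                      suppressWarnings(as.numeric(raw$month)) < 1 |
                      suppressWarnings(as.numeric(raw$month)) > 12,
                    "month", raw$month, "month must be an integer in 1-12")
  bad <- bad | flag(!check_integerish(raw$count) |
                      suppressWarnings(as.numeric(raw$count)) < 0,
                    "count", raw$count,
                    "count must be a non-negative integer")
  bad <- bad | flag(!raw$stratum %in% c("urban", "rural"), "stratum",
                    raw$stratum, "stratum must be 'urban' or 'rural'")
  bad <- bad | flag(!check_integerish(raw$attempts_total), "attempts_total",
                    raw$attempts_total, "not an integer")
  bad <- bad | flag(!check_integerish(raw$users_total), "users_total",
                    raw$users_total, "not an integer")
  bad <- bad | flag(is.na(suppressWarnings(as.numeric(raw$length_m))),
                    "length_m", raw$length_m, "not a number")

  ok <- raw[!bad, , drop = FALSE]
  observations <- tibble::tibble(
    segment_id = ok$segment_id,
    stratum = ok$stratum,
    year = as.integer(ok$year),
    month = as.integer(ok$month),
    count = as.integer(ok$count)
  )
  segments <- dplyr::distinct(tibble::tibble(
    segment_id = ok$segment_id,
    stratum = ok$stratum,
    region = ok$region,
    attempts_total = as.integer(ok$attempts_total),
    users_total = as.integer(ok$users_total),
    length_m = as.numeric(ok$length_m)
  ))
  list(observations = observations,
       segments = segments,
       errors = if (length(errors)) dplyr::bind_rows(errors)
                else tibble::tibble(line = integer(), field = character(),
                                    value = character(),
                                    problem = character()))
}

check_integerish <- function(x) {
  suppressWarnings({
    num <- as.numeric(x)
    !is.na(num) & num == trunc(num) & !grepl("[.]", x)
  })
}

#' Read a monthly station sunshine-hours table
#'
#' @param path CSV with columns `station_id, year, month, sunshine_hours`.
#' @return Tibble with those columns, typed.
#' @export
read_sunshine <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    station_id = readr::col_character(),
    year = readr::col_integer(),
    month = readr::col_integer(),
    sunshine_hours = readr::col_double()
  ), progress = FALSE)
  if (any(tab$sunshine_hours < 0, na.rm = TRUE)) {
    rlang::abort("Sunshine hours must be non-negative.")
  }
  tab
}

#' Read a segment-to-station assignment map
#'
#' The closest-station assignment is an explicit input here (no geocoding is
#' performed); each segment must map to exactly one station.
#'
#' @param path CSV with columns `segment_id, station_id`.
#' @return Tibble with those columns.
#' @export
read_station_map <- function(path) {
  map <- readr::read_csv(path, col_types = readr::cols(
    segment_id = readr::col_character(),
    station_id = readr::col_character()
  ), progress = FALSE)
  dup <- unique(map$segment_id[duplicated(map$segment_id)])
  if (length(dup) > 0) {
    rlang::abort(paste0("Segments mapped to more than one station: ",
                        paste(utils::head(dup, 5), collapse = ", ")))
  }
  map
}

#' Collapse duplicated observation rows
#'
#' Exact duplicates of a (segment_id, year, month) key collapse to a single
#' record. Conflicting duplicates — same key, different counts — are an
#' error naming the offending keys: the acquisition rules give no rule for
#' combining them, so guessing is refused.
#'
#' @param observations Tibble of monthly observations.
#' @return Tibble with exactly one record per (segment_id, year, month).
#' @export
deduplicate <- function(observations) {
  out <- dplyr::distinct(observations)
  key <- paste(out$segment_id, out$year, out$month, sep = "/")
  clash <- unique(key[duplicated(key)])
  if (length(clash) > 0) {
    rlang::abort(paste0(
      "Conflicting duplicate observations (same segment/year/month, ",
      "different values): ",
      paste(utils::head(clash, 5), collapse = ", "),
      if (length(clash) > 5) sprintf(" (and %d more)", length(clash) - 5)
    ))
  }
  out
}

#' Filter segments by eligibility thresholds
#'
#' Keeps urban segments with more than `urban_min_attempts` attempts and more
#' than `urban_min_users` users, rural segments with more than
#' `rural_min_attempts` attempts and more than `rural_min_users` users, and —
#' in both strata — a length of at least `min_length_m` metres. "More than"
#' is a strict inequality; the length threshold is inclusive. Observations
#' belonging to dropped segments are removed too, and every drop is reported
#' with its reason.
#'
#' @param segments Tibble of segment metadata (see [read_counts()]).
#' @param observations Tibble of monthly observations.
#' @param urban_min_attempts,urban_min_users,rural_min_attempts,rural_min_users
#'   Strict lower bounds on total attempts / distinct users.
#' @param min_length_m Inclusive minimum segment length in metres.
#' @return List with filtered `segments`, filtered `observations`, and a
#'   `report` tibble (segment_id, stratum, reason) of drops.
#' @export
filter_segments <- function(segments, observations,
                            urban_min_attempts = 1500,
                            urban_min_users = 350,
                            rural_min_attempts = 600,
                            rural_min_users = 200,
                            min_length_m = 500) {
  stopifnot(all(segments$stratum %in% c("urban", "rural")))
  urban <- segments$stratum == "urban"
  min_attempts <- ifelse(urban, urban_min_attempts, rural_min_attempts)
  min_users <- ifelse(urban, urban_min_users, rural_min_users)

  reason <- rep(NA_character_, nrow(segments))
  reason[segments$length_m < min_length_m] <-
    sprintf("length below %g m", min_length_m)
  reason[segments$users_total <= min_users] <-
    sprintf("users <= %g", min_users)[segments$users_total <= min_users]
  reason[segments$attempts_total <= min_attempts] <-
    sprintf("attempts <= %g", min_attempts)[segments$attempts_total <=
                                              min_attempts]
  keep <- is.na(reason)

  report <- tibble::tibble(segment_id = segments$segment_id[!keep],
                           stratum = segments$stratum[!keep],
                           reason = reason[!keep])
  list(segments = segments[keep, , drop = FALSE],
       observations = observations[observations$segment_id %in%
                                     segments$segment_id[keep], ,
                                   drop = FALSE],
       report = report)
}

#' Restrict observations to the analysis window
#'
#' Drops observations before `year_min` (early years with too thin a user
#' base to support the trend models) and observations in the configured
#' winter months (infrequent activity). The winter set defaults to
#' meteorological winter: December, January, February.
#'
#' @param observations Tibble of monthly observations.
#' @param year_min First year retained.
#' @param winter_months Integer months removed.
#' @return Filtered tibble.
#' @export
apply_temporal_window <- function(observations, year_min = 2012,
                                  winter_months = c(12L, 1L, 2L)) {
  observations[observations$year >= year_min &
                 !observations$month %in% winter_months, , drop = FALSE]
}

#' Attach station sunshine hours to observations
#'
#' Joins each observation with the monthly sunshine hours of its assigned
#' weather station. A segment without a station assignment is a hard error;
#' an observation whose station lacks a sunshine record for that month is
#' dropped and reported.
#'
#' @param observations Tibble of monthly observations.
#' @param sunshine Tibble from [read_sunshine()].
#' @param station_map Tibble (segment_id, station_id).
#' @return List with `observations` (now carrying `sunshine_hours` and
#'   `station_id`) and `dropped` (observations lacking a sunshine record).
#' @export
join_sunshine <- function(observations, sunshine, station_map) {
  unmapped <- setdiff(unique(observations$segment_id),
                      station_map$segment_id)
  if (length(unmapped) > 0) {
    rlang::abort(paste0("Segments without a station assignment: ",
                        paste(utils::head(unmapped, 5), collapse = ", ")))
  }
  obs <- dplyr::left_join(observations, station_map, by = "segment_id")
  obs <- dplyr::left_join(obs, sunshine,
                          by = c("station_id", "year", "month"))
  missing <- is.na(obs$sunshine_hours)
  list(observations = obs[!missing, , drop = FALSE],
       dropped = obs[missing, , drop = FALSE])
}
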