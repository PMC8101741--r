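# In-code fixtures shared across test files.

# a small eligible dataset with both strata, fast to generate
small_dataset <- function(seed = 101, ...) {
  generate_dataset(synthetic_config(n_urban_segments = 6,
                                    n_rural_segments = 4,
                                    seed = seed, ...))
}

write_lines_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

counts_header <- paste("segment_id,stratum,region,year,month,count",
                       "attempts_total,users_total,length_m", sep = ",")

counts_row <- function(id = "s1", stratum = "urban", region = "city_01",
                       year = 2015, month = 6, count = 10,
                       attempts = 2000, users = 500, length_m = 900) {
  paste(id, stratum, region, year, month, count, attempts, users, length_m,
        sep = ",")
}

# one segment-month training set lying exactly on a log-linear curve
loglinear_cell <- function() {
  tibble::tibble(year = 2012:2015, count = c(1, 2, 4, 8),
                 sunshine_hours = c(150, 160, 170, 180))
}

# a random Poisson training cell with year trend and sunshine covariate
random_cell <- function(n_years = 8, base = 80, growth = 1.1,
                        sun_coef = 0) {
  t <- seq_len(n_years) - 1
  s <- stats::rnorm(n_years, 160, 30)
  mu <- base * growth^t * exp(sun_coef * (s - 160))
  tibble::tibble(year = 2012 + t, sunshine_hours = s,
                 count = stats::rpois(n_years, mu))
}
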