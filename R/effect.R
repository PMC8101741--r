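#' Per-segment observed-minus-expected differences
#'
#' Aggregates each segment's months within the period by summation before
#' differencing: `diff = sum(observed) - sum(expected)` and
#' `pct_diff = 100 * diff / sum(expected)`. Segments with non-positive
#' summed expectation are excluded with a report entry (this cannot occur
#' for converged Poisson fits, whose fitted means are strictly positive).
#'
#' @param counterfactuals Tibble from [run_counterfactuals()], already
#'   restricted to one stratum and period.
#' @return List with `differences` (tibble: segment_id, observed, expected,
#'   diff, pct_diff) and `excluded` (tibble of skipped segments).
#' @export
paired_differences <- function(counterfactuals) {
  agg <- dplyr::summarise(
    dplyr::group_by(counterfactuals, .data$segment_id),
    observed = sum(.data$observed_count),
    expected = sum(.data$expected_count),
    .groups = "drop"
  )
  bad <- agg$expected <= 0
  excluded <- agg[bad, , drop = FALSE]
  agg <- agg[!bad, , drop = FALSE]
  if (nrow(agg) < 2) {
    rlang::abort("Need at least 2 segments with observed and expected counts.")
  }
  agg$diff <- agg$observed - agg$expected
  agg$pct_diff <- 100 * agg$diff / agg$expected
  list(differences = agg, excluded = excluded)
}

#' Non-parametric bootstrap of a statistic over segments
#'
#' Resamples the values (one per segment, the exchangeable unit) with
#' replacement and evaluates the statistic on each resample. Deterministic
#' given the seed.
#'
#' @param values Numeric vector, one entry per segment (n >= 2).
#' @param statistic Function of a numeric vector; default [stats::median].
#' @param n_boot Number of bootstrap replicates (>= 1000 recommended for
#'   production intervals; smaller values are fine for quick checks).
#' @param seed Integer RNG seed.
#' @return Numeric vector of `n_boot` bootstrap statistics.
#' @export
bootstrap_statistic <- function(values, statistic = stats::median,
                                n_boot = 10000, seed = 1L) {
  n <- length(values)
  if (n < 2) {
    rlang::abort("Bootstrap needs at least 2 values.")
  }
  idx <- withr::with_seed(seed, {
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  })
  apply(matrix(values[idx], nrow = n), 2, statistic)
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Adjusts the bootstrap percentile interval for median bias and for
#' skewness of the statistic. The bias correction is
#' \eqn{z_0 = \Phi^{-1}(\#\{\theta^* < \hat\theta\}/B)} with ties counted
#' half (avoiding \eqn{\Phi^{-1}(0)} for degenerate distributions); the
#' acceleration \eqn{a} comes from the skewness of the leave-one-out
#' jackknife values,
#' \eqn{a = \sum(\bar\theta_{-} - \theta_{-i})^3 /
#'   (6 [\sum(\bar\theta_{-} - \theta_{-i})^2]^{3/2})}.
#' The adjusted levels are
#' \eqn{\alpha_j = \Phi(z_0 + (z_0 + z_j)/(1 - a (z_0 + z_j)))} for
#' \eqn{z_j = \pm\Phi^{-1}(1 - (1-level)/2)}, and the bounds are the
#' corresponding empirical quantiles of the bootstrap distribution.
#'
#' When every bootstrap value falls on one side of the point estimate the
#' bias correction is infinite; the interval then falls back to the plain
#' percentile interval and is flagged. A degenerate bootstrap distribution
#' collapses both bounds onto the point estimate.
#'
#' @param values Original per-segment values (for the jackknife), or `NULL`
#'   if `jackknife` is supplied directly.
#' @param boot_dist Bootstrap distribution of the statistic.
#' @param point_estimate The statistic on the original values.
#' @param level Nominal coverage (default 0.95).
#' @param statistic Statistic used for the jackknife (default median).
#' @param jackknife Optional precomputed leave-one-out statistic values;
#'   overrides `values`/`statistic`.
#' @return List with `low`, `high`, and `components` (z0, a, alpha_low,
#'   alpha_high, method — "bca", "percentile" fallback, or "degenerate").
#' @export
bca_interval <- function(values, boot_dist, point_estimate, level = 0.95,
                         statistic = stats::median, jackknife = NULL) {
  B <- length(boot_dist)
  alpha <- (1 - level) / 2
  comp <- list(z0 = NA_real_, a = NA_real_, alpha_low = alpha,
               alpha_high = 1 - alpha, method = "bca")

  if (max(boot_dist) == min(boot_dist)) {
    comp$z0 <- 0; comp$a <- 0; comp$method <- "degenerate"
    return(list(low = point_estimate, high = point_estimate,
                components = comp))
  }
  prop <- (sum(boot_dist < point_estimate) +
             0.5 * sum(boot_dist == point_estimate)) / B
  if (prop <= 0 || prop >= 1) {
    comp$method <- "percentile"
    q <- boot_quantile(boot_dist, c(alpha, 1 - alpha))
    return(list(low = q[1], high = q[2], components = comp))
  }
  z0 <- stats::qnorm(prop)

  if (is.null(jackknife)) {
    n <- length(values)
    jackknife <- vapply(seq_len(n),
                        function(i) statistic(values[-i]), numeric(1))
  }
  dev <- mean(jackknife) - jackknife
  denom <- sum(dev^2)^1.5
  a <- if (denom > 0) sum(dev^3) / (6 * denom) else 0

  zq <- stats::qnorm(1 - alpha)
  adj <- function(zj) {
    scale <- 1 - a * (z0 + zj)
    if (scale <= 0) {
      return(NA_real_)
    }
    stats::pnorm(z0 + (z0 + zj) / scale)
  }
  a_low <- adj(-zq)
  a_high <- adj(zq)
  if (is.na(a_low) || is.na(a_high) || a_low >= a_high) {
    comp$z0 <- z0; comp$a <- a; comp$method <- "percentile"
    q <- boot_quantile(boot_dist, c(alpha, 1 - alpha))
    return(list(low = q[1], high = q[2], components = comp))
  }
  comp$z0 <- z0; comp$a <- a
  comp$alpha_low <- a_low; comp$alpha_high <- a_high
  q <- boot_quantile(boot_dist, c(a_low, a_high))
  list(low = q[1], high = q[2], components = comp)
}

# empirical quantile on the (B+1)*p order-statistic convention
boot_quantile <- function(boot_dist, p) {
  unname(stats::quantile(boot_dist, probs = p, type = 6, names = FALSE))
}

#' Estimate the activity shift for one stratum and period
#'
#' Combines [paired_differences()], segment-level bootstrap resampling, and
#' [bca_interval()] into the effect summary the pipeline reports: the median
#' over segments of the observed-minus-expected difference (absolute scale)
#' and of the percent difference (relative scale), each with a BCa interval.
#' One set of resampled segment indices drives both statistics, so absolute
#' and relative intervals come from the same resamples.
#'
#' `percent_diff_mode` controls the relative statistic:
#' `"per_segment_median"` (default) takes the median over segments of each
#' segment's own percent difference; `"ratio_of_medians"` divides the median
#' absolute difference by the median expected count.
#'
#' @param counterfactuals Tibble from [run_counterfactuals()].
#' @param stratum `"urban"` or `"rural"`.
#' @param period_label Free-text label stored in the output (e.g.
#'   `"2020-03..06"`).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Integer RNG seed.
#' @param level Nominal interval coverage.
#' @param percent_diff_mode See Details.
#' @return One-row tibble: stratum, period_label, n_segments, median_diff,
#'   percent_diff, ci_low, ci_high (percent scale), ci_low_abs, ci_high_abs
#'   (count scale), n_boot, seed, significant (percent CI excludes 0). The
#'   BCa components of both intervals are attached as attribute `"bca"`.
#' @export
estimate_effect <- function(counterfactuals, stratum,
                            period_label = NA_character_,
                            n_boot = 10000, seed = 1L, level = 0.95,
                            percent_diff_mode = c("per_segment_median",
                                                  "ratio_of_medians")) {
  percent_diff_mode <- match.arg(percent_diff_mode)
  cf <- counterfactuals[counterfactuals$stratum == stratum, , drop = FALSE]
  pd <- paired_differences(cf)$differences
  n <- nrow(pd)

  stat_abs <- function(rows) stats::median(pd$diff[rows])
  stat_pct <- if (percent_diff_mode == "per_segment_median") {
    function(rows) stats::median(pd$pct_diff[rows])
  } else {
    function(rows) 100 * stats::median(pd$diff[rows]) /
      stats::median(pd$expected[rows])
  }

  point_abs <- stat_abs(seq_len(n))
  point_pct <- stat_pct(seq_len(n))

  idx <- withr::with_seed(seed, {
    matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  })
  boot_abs <- apply(idx, 2, stat_abs)
  boot_pct <- apply(idx, 2, stat_pct)
  jack_abs <- vapply(seq_len(n), function(i) stat_abs(setdiff(seq_len(n), i)),
                     numeric(1))
  jack_pct <- vapply(seq_len(n), function(i) stat_pct(setdiff(seq_len(n), i)),
                     numeric(1))

  ci_abs <- bca_interval(NULL, boot_abs, point_abs, level = level,
                         jackknife = jack_abs)
  ci_pct <- bca_interval(NULL, boot_pct, point_pct, level = level,
                         jackknife = jack_pct)

  out <- tibble::tibble(
    stratum = stratum,
    period_label = period_label,
    n_segments = n,
    median_diff = point_abs,
    percent_diff = point_pct,
    ci_low = ci_pct$low,
    ci_high = ci_pct$high,
    ci_low_abs = ci_abs$low,
    ci_high_abs = ci_abs$high,
    n_boot = as.integer(n_boot),
    seed = as.integer(seed),
    significant = ci_pct$low > 0 || ci_pct$high < 0
  )
  attr(out, "bca") <- list(percent = ci_pct$components,
                           absolute = ci_abs$components)
  out
}

#' Write an effect table to CSV
#'
#' @param effects Tibble of rows from [estimate_effect()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_effects <- function(effects, path) {
  readr::write_csv(effects, path)
  invisible(path)
}
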