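test_that("design matrices follow the form definitions", {
  cell <- random_cell(8)
  d_null <- build_design(cell, "D")
  expect_equal(dim(d_null$X), c(8, 1))
  expect_true(all(d_null$X == 1))

  d_full <- build_design(cell, "C")
  expect_equal(colnames(d_full$X),
               c("intercept", "year", "sunshine", "year:sunshine"))
  expect_equal(d_full$X[, 4], d_full$X[, 2] * d_full$X[, 3],
               ignore_attr = TRUE)
  expect_equal(d_full$X[, 2], cell$year - 2012, ignore_attr = TRUE)

  # identifiability guard: form B needs at least 4 training years
  expect_null(build_design(cell[1:2, ], "B"))
})

test_that("intercept-only fits recover the log of the mean", {
  X <- matrix(1, 3, 1, dimnames = list(NULL, "intercept"))
  f <- fit_poisson(X, c(3, 3, 3))
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), log(3), tolerance = 1e-8)

  f2 <- fit_poisson(X, c(2, 4, 6))
  expect_equal(unname(f2$coefficients), log(4), tolerance = 1e-8)
  # direct summation of the Poisson log-pmf at lambda = ybar = 4
  expect_equal(f2$log_likelihood, sum(dpois(c(2, 4, 6), 4, log = TRUE)),
               tolerance = 1e-9)
  expect_equal(round(f2$log_likelihood, 4), -5.8149)
})

test_that("exactly log-linear counts are fitted exactly", {
  d <- build_design(loglinear_cell(), "A")
  f <- fit_poisson(d$X, d$y)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients["year"]), log(2), tolerance = 1e-7)
  expect_equal(unname(f$coefficients["intercept"]), 0, tolerance = 1e-7)
})

test_that("fits agree with a brute-force Nelder-Mead oracle", {
  withr::with_seed(9, {
    t_idx <- 0:5
    y <- rpois(6, exp(1 + 0.3 * t_idx))
  })
  X <- cbind(intercept = 1, year = t_idx)
  nll <- function(b) -sum(y * (X %*% b) - exp(X %*% b) - lfactorial(y))
  oracle <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
  f <- fit_poisson(X, y)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), oracle$par, tolerance = 1e-5)
  expect_equal(f$log_likelihood, -oracle$value, tolerance = 1e-8)
})

test_that("the score equations hold at every converged fit", {
  withr::with_seed(21, {
    for (i in 1:10) {
      cell <- random_cell(8, sun_coef = 0.002)
      fits <- fit_candidates(cell)
      for (j in which(fits$converged)) {
        d <- build_design(cell, fits$label[j])
        beta <- fits$coefficients[[j]]
        mu <- exp(as.vector(d$X %*% beta))
        expect_lt(max(abs(crossprod(d$X, d$y - mu))), 1e-6)
      }
    }
  })
})

test_that("rank-deficient designs are flagged, not fitted", {
  X <- cbind(intercept = 1, year = rep(2, 6))  # constant column pair
  X <- cbind(X, dup = X[, 2])
  f <- fit_poisson(X, rpois(6, 10))
  expect_false(f$converged)
  expect_match(f$reason, "rank")
})

test_that("AIC is 2k minus twice the log-likelihood", {
  expect_equal(aic(-5.81492098075781, 1), 13.6298419615156,
               tolerance = 1e-9)
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-10, 2), 24)
})

test_that("stored AICs satisfy the identity and nested fits order by logLik", {
  withr::with_seed(33, {
    for (i in 1:20) {
      cell <- random_cell(8, sun_coef = 0.003)
      fits <- fit_candidates(cell)
      conv <- fits[fits$converged, ]
      expect_equal(conv$aic, 2 * conv$n_params - 2 * conv$log_likelihood,
                   tolerance = 1e-9)
      ll <- setNames(fits$log_likelihood, fits$label)
      if (all(fits$converged)) {
        expect_gte(ll["C"], ll["B"] - 1e-6)
        expect_gte(ll["B"], ll["D"] - 1e-6)
        expect_gte(ll["C"], ll["A"] - 1e-6)
        expect_gte(ll["A"], ll["D"] - 1e-6)
      }
    }
  })
})

test_that("model selection minimises AIC with ties toward parsimony", {
  fits <- tibble::tibble(label = c("A", "B", "C", "D"),
                         n_params = c(2L, 3L, 4L, 1L),
                         aic = c(10, 12, 13, 11),
                         converged = TRUE)
  expect_equal(select_model(fits)$label, "A")

  tie <- fits
  tie$aic <- c(10, 12, 13, 10)
  expect_equal(select_model(tie)$label, "D")

  only_c <- fits
  only_c$converged <- c(FALSE, FALSE, TRUE, FALSE)
  only_c$aic <- c(NA, NA, 99, NA)
  expect_equal(select_model(only_c)$label, "C")

  none <- fits
  none$converged <- FALSE
  expect_null(select_model(none))
})

test_that("predictions exponentiate the linear predictor", {
  fit_a <- tibble::tibble(
    label = "A", converged = TRUE,
    coefficients = list(c(intercept = log(100), year = log(1.1))))
  expect_equal(predict_expected(fit_a, 2020, year_min = 2012), 100 * 1.1^8)

  fit_d <- tibble::tibble(label = "D", converged = TRUE,
                          coefficients = list(c(intercept = log(50))))
  expect_equal(predict_expected(fit_d, 2030, year_min = 2012), 50)

  # nested-model consistency: B with a zero sunshine coefficient equals A
  fit_b <- tibble::tibble(
    label = "B", converged = TRUE,
    coefficients = list(c(intercept = log(100), year = log(1.1),
                          sunshine = 0)))
  expect_equal(predict_expected(fit_b, 2020, sunshine_hours = 210,
                                year_min = 2012),
               predict_expected(fit_a, 2020, year_min = 2012))
})

test_that("backcasting before the training window is refused", {
  fit_a <- tibble::tibble(
    label = "A", converged = TRUE,
    coefficients = list(c(intercept = log(100), year = log(1.1))))
  expect_error(predict_expected(fit_a, 2011, year_min = 2012,
                                train_year_min = 2012),
               "precedes the training window")
})

test_that("training years may not contain the target year", {
  ds <- small_dataset()
  expect_error(run_counterfactuals(ds$observations, 2020, 3:6, 2012:2020),
               "must not contain")
})

test_that("each cell trains on at most the available pre-target years", {
  ds <- small_dataset()
  cf <- run_counterfactuals(ds$observations, 2020, 3:6, 2012:2019)
  expect_true(all(cf$counterfactuals$n_train <= 8))
  expect_equal(nrow(cf$counterfactuals) + nrow(cf$unfit), 10 * 4)
  expect_true(all(cf$counterfactuals$expected_count > 0))
  expect_equal(sum(cf$selection_tally$share), 1)

  # validation windowing: 2019 targets trained on 2012-2018 only
  cfv <- run_counterfactuals(ds$observations, 2019, 7:10, 2012:2018)
  expect_true(all(cfv$counterfactuals$n_train <= 7))
})

test_that("the fast per-cell path matches the candidate-table route", {
  ds <- small_dataset(seed = 77)
  cf <- run_counterfactuals(ds$observations, 2020, 3:6, 2012:2019)
  obs <- ds$observations
  for (i in sample.int(nrow(cf$counterfactuals), 5)) {
    row <- cf$counterfactuals[i, ]
    train <- obs[obs$segment_id == row$segment_id &
                   obs$month == row$month & obs$year <= 2019, ]
    sel <- select_model(fit_candidates(train))
    expect_equal(sel$label, row$selected_form)
    target <- obs[obs$segment_id == row$segment_id &
                    obs$month == row$month & obs$year == 2020, ]
    expect_equal(predict_expected(sel, 2020, target$sunshine_hours),
                 row$expected_count, tolerance = 1e-10)
  }
})

test_that("fitted year trends recover the generative growth rate", {
  cfg <- synthetic_config(n_urban_segments = 60, n_rural_segments = 0,
                          sunshine_coef = 0, growth_rate = 1.1,
                          shock_multiplier_urban = 1,
                          shock_multiplier_rural = 1, seed = 55)
  ds <- generate_dataset(cfg)
  obs <- apply_temporal_window(ds$observations)
  obs <- obs[obs$year <= 2019, ]
  cells <- split(obs, paste(obs$segment_id, obs$month))
  slopes <- vapply(cells, function(cell) {
    d <- build_design(cell, "A")
    f <- fit_poisson(d$X, d$y)
    if (f$converged) unname(f$coefficients["year"]) else NA_real_
  }, numeric(1))
  expect_lt(abs(median(exp(slopes), na.rm = TRUE) - 1.1), 0.01)
})
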