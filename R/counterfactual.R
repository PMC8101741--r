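#' The four candidate model forms
#'
#' Per segment and calendar month, four Poisson GLM forms compete:
#' A `count ~ year`, B `count ~ year + sunshine`, C `count ~ year + sunshine
#' + year:sunshine`, and the intercept-only null model D. `n_params` counts
#' the intercept plus the listed terms (A: 2, B: 3, C: 4, D: 1).
#'
#' @return Tibble with columns `label`, `terms` (list column), `n_params`.
#' @export
model_forms <- function() {
  tibble::tibble(
    label = c("A", "B", "C", "D"),
    terms = list(c("year"),
                 c("year", "sunshine"),
                 c("year", "sunshine", "year:sunshine"),
                 character(0)),
    n_params = c(2L, 3L, 4L, 1L)
  )
}

#' Build the design matrix for one segment-month training set
#'
#' Columns are ordered `[intercept, year, sunshine, year:sunshine]`,
#' restricted to the form's terms. The year enters as a continuous index
#' centred at `year_min` (t = year - year_min); predictions are invariant to
#' this centring, which only conditions the intercept. A form is only
#' identifiable with at least `n_params + 1` training observations; smaller
#' training sets return `NULL` so the caller can flag the cell unfit.
#'
#' @param observations Tibble with columns `year`, `count`, and (for forms
#'   B/C) `sunshine_hours`, for a single segment and calendar month.
#' @param form One row of [model_forms()] (or its label).
#' @param year_min Centring origin for the year index.
#' @return List with `X` (design matrix), `y` (response), `form`; or `NULL`
#'   when there are fewer than `n_params + 1` rows.
#' @export
build_design <- function(observations, form, year_min = 2012) {
  if (is.character(form)) {
    forms <- model_forms()
    form <- forms[match(form, forms$label), ]
  }
  terms <- form$terms[[1]]
  if (nrow(observations) < form$n_params + 1L) {
    return(NULL)
  }
  t_idx <- observations$year - year_min
  cols <- list(intercept = rep(1, nrow(observations)))
  if ("year" %in% terms) cols$year <- t_idx
  if ("sunshine" %in% terms) cols$sunshine <- observations$sunshine_hours
  if ("year:sunshine" %in% terms) {
    cols$`year:sunshine` <- t_idx * observations$sunshine_hours
  }
  X <- do.call(cbind, cols)
  list(X = X, y = observations$count, form = form)
}

#' Fit a Poisson GLM with log link by maximum likelihood
#'
#' Maximises the Poisson log-likelihood
#' \eqn{\sum_i y_i x_i'\beta - \exp(x_i'\beta) - \log(y_i!)} via iteratively
#' reweighted least squares (`stats::glm.fit`, deviance tolerance 1e-12,
#' at most 100 iterations). A rank-deficient design or a fit that fails to
#' converge (separation-like divergence) is reported as non-converged rather
#' than raising.
#'
#' @param X Design matrix (first column the intercept).
#' @param y Non-negative integer response.
#' @return List with `coefficients` (named, log-link scale),
#'   `log_likelihood` (nats), `fitted` (means, strictly positive when
#'   converged), `converged`, and `reason` when not converged.
#' @export
fit_poisson <- function(X, y) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) {
    return(list(coefficients = NULL, log_likelihood = NA_real_,
                fitted = NULL, converged = FALSE,
                reason = "rank-deficient design"))
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      X, y, family = stats::poisson(),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100)
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients) ||
      any(!is.finite(fit$fitted.values)) || any(fit$fitted.values <= 0)) {
    return(list(coefficients = NULL, log_likelihood = NA_real_,
                fitted = NULL, converged = FALSE,
                reason = "IRLS did not converge"))
  }
  mu <- fit$fitted.values
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       log_likelihood = sum(stats::dpois(y, mu, log = TRUE)),
       fitted = mu,
       converged = TRUE,
       reason = NA_character_)
}

#' Akaike's Information Criterion
#'
#' @param log_likelihood Maximised log-likelihood (nats).
#' @param n_params Number of estimated parameters (intercept included).
#' @return `2 * n_params - 2 * log_likelihood`; smaller is better.
#' @export
aic <- function(log_likelihood, n_params) {
  2 * n_params - 2 * log_likelihood
}

#' Fit all candidate forms on one segment-month training set
#'
#' @param observations Training rows for one segment and calendar month.
#' @param year_min Centring origin for the year index.
#' @return Tibble with one row per form: `label`, `n_params`, `n_train`,
#'   `coefficients` (list), `log_likelihood`, `aic`, `converged`, `reason`.
#' @export
fit_candidates <- function(observations, year_min = 2012) {
  forms <- model_forms()
  rows <- lapply(seq_len(nrow(forms)), function(i) {
    form <- forms[i, ]
    d <- build_design(observations, form, year_min)
    if (is.null(d)) {
      return(tibble::tibble(label = form$label, n_params = form$n_params,
                            n_train = nrow(observations),
                            coefficients = list(NULL),
                            log_likelihood = NA_real_, aic = NA_real_,
                            converged = FALSE,
                            reason = "insufficient training years"))
    }
    f <- fit_poisson(d$X, d$y)
    tibble::tibble(label = form$label, n_params = form$n_params,
                   n_train = length(d$y),
                   coefficients = list(f$coefficients),
                   log_likelihood = f$log_likelihood,
                   aic = if (f$converged) {
                     aic(f$log_likelihood, form$n_params)
                   } else NA_real_,
                   converged = f$converged, reason = f$reason)
  })
  dplyr::bind_rows(rows)
}

#' Select the best candidate by AIC
#'
#' Returns the converged fit with minimal AIC; ties (|dAIC| < 1e-9) break
#' toward the form with fewer parameters. With no converged fit the cell is
#' unfit and `NULL` is returned.
#'
#' @param fits Tibble from [fit_candidates()].
#' @return One row of `fits`, or `NULL`.
#' @export
select_model <- function(fits) {
  conv <- fits[fits$converged, , drop = FALSE]
  if (nrow(conv) == 0) {
    return(NULL)
  }
  tied <- conv[conv$aic - min(conv$aic) < 1e-9, , drop = FALSE]
  tied[which.min(tied$n_params), , drop = FALSE]
}

#' Predict the expected (counterfactual) count
#'
#' Evaluates \eqn{\hat\mu = \exp(x'\beta)} for the selected form at a target
#' year and that month's observed sunshine hours. Forms A and D ignore the
#' sunshine input. Backcasting before the training window is refused.
#'
#' @param fit One row of [fit_candidates()] output (converged).
#' @param year Target calendar year.
#' @param sunshine_hours Observed sunshine hours in the target month.
#' @param year_min Centring origin used when the model was built.
#' @param train_year_min First year in the training window (for the
#'   no-backcasting guard); `NULL` skips the guard.
#' @return Positive expected count.
#' @export
predict_expected <- function(fit, year, sunshine_hours = NULL,
                             year_min = 2012, train_year_min = NULL) {
  stopifnot(nrow(fit) == 1, isTRUE(fit$converged))
  if (!is.null(train_year_min) && year < train_year_min) {
    rlang::abort("Prediction year precedes the training window.")
  }
  beta <- fit$coefficients[[1]]
  t_idx <- year - year_min
  x <- c(intercept = 1)
  if ("year" %in% names(beta)) x["year"] <- t_idx
  if ("sunshine" %in% names(beta)) {
    if (is.null(sunshine_hours)) {
      rlang::abort("This form needs `sunshine_hours` for prediction.")
    }
    x["sunshine"] <- sunshine_hours
  }
  if ("year:sunshine" %in% names(beta)) {
    x["year:sunshine"] <- t_idx * sunshine_hours
  }
  unname(exp(sum(x[names(beta)] * beta)))
}

#' Fit, select and predict counterfactuals for a target period
#'
#' For every segment and every target (year, month) cell: trains the four
#' candidate Poisson GLMs on that calendar month's observations in
#' `training_years`, selects by AIC, and predicts the expected count at the
#' target month's observed sunshine hours. The target year must be disjoint
#' from the training years (no leakage). Cells with no converged fit (or too
#' few training years for every form) are reported as unfit.
#'
#' @param observations Analysis-ready tibble (post-ingest) with columns
#'   `segment_id, stratum, year, month, count, sunshine_hours`.
#' @param target_year Calendar year of the target period.
#' @param target_months Integer months of the target period.
#' @param training_years Years used for training (same calendar month).
#' @param year_min Centring origin for the year index.
#' @return List with `counterfactuals` (tibble: segment_id, stratum, year,
#'   month, observed_count, expected_count, selected_form, n_train),
#'   `selection_tally` (share of cells won by each form), and `unfit`
#'   (tibble of skipped cells with reasons).
#' @export
run_counterfactuals <- function(observations, target_year, target_months,
                                training_years, year_min = 2012) {
  if (target_year %in% training_years) {
    rlang::abort("`training_years` must not contain `target_year`.")
  }
  needed <- c("segment_id", "stratum", "year", "month", "count",
              "sunshine_hours")
  stopifnot(all(needed %in% names(observations)))

  obs <- as.data.frame(observations[, needed])
  targets <- obs[obs$year == target_year & obs$month %in% target_months, ,
                 drop = FALSE]
  train_all <- obs[obs$year %in% training_years &
                     obs$month %in% target_months, , drop = FALSE]
  train_split <- split(train_all,
                       paste(train_all$segment_id, train_all$month))

  n_t <- nrow(targets)
  expected <- rep(NA_real_, n_t)
  form_sel <- rep(NA_character_, n_t)
  n_train <- rep(NA_integer_, n_t)
  unfit_reason <- rep(NA_character_, n_t)
  for (i in seq_len(n_t)) {
    train <- train_split[[paste(targets$segment_id[i], targets$month[i])]]
    if (is.null(train) || nrow(train) < 2) {
      unfit_reason[i] <- "insufficient training years"
      next
    }
    sel <- fit_and_select_cell(train$year, train$sunshine_hours,
                               train$count, year_min)
    if (is.null(sel)) {
      unfit_reason[i] <- "no converged candidate fit"
      next
    }
    if (targets$year[i] < min(train$year)) {
      rlang::abort("Prediction year precedes the training window.")
    }
    beta <- sel$coefficients
    t_idx <- targets$year[i] - year_min
    s <- targets$sunshine_hours[i]
    x <- c(intercept = 1, year = t_idx, sunshine = s,
           "year:sunshine" = t_idx * s)
    expected[i] <- exp(sum(x[names(beta)] * beta))
    form_sel[i] <- sel$label
    n_train[i] <- sel$n_train
  }

  fitted <- is.na(unfit_reason)
  counterfactuals <- tibble::tibble(
    segment_id = targets$segment_id[fitted],
    stratum = targets$stratum[fitted],
    year = targets$year[fitted],
    month = targets$month[fitted],
    observed_count = targets$count[fitted],
    expected_count = expected[fitted],
    selected_form = form_sel[fitted],
    n_train = n_train[fitted]
  )
  unfit <- tibble::tibble(segment_id = targets$segment_id[!fitted],
                          month = targets$month[!fitted],
                          reason = unfit_reason[!fitted])
  tally <- if (nrow(counterfactuals) > 0) {
    dplyr::mutate(
      dplyr::count(counterfactuals, .data$selected_form, name = "n_cells"),
      share = .data$n_cells / sum(.data$n_cells)
    )
  } else {
    tibble::tibble(selected_form = character(), n_cells = integer(),
                   share = double())
  }
  list(counterfactuals = counterfactuals,
       selection_tally = tally,
       unfit = unfit)
}

# Fast per-cell fit/select path used by run_counterfactuals(); follows the
# same rules as fit_candidates() + select_model() without per-form tibbles.
fit_and_select_cell <- function(train_year, train_sunshine, train_count,
                                year_min) {
  n <- length(train_count)
  t_idx <- train_year - year_min
  X <- cbind(intercept = 1, year = t_idx, sunshine = train_sunshine,
             "year:sunshine" = t_idx * train_sunshine)
  labels <- c("A", "B", "C", "D")
  columns <- list(1:2, 1:3, 1:4, 1L)
  k <- c(2L, 3L, 4L, 1L)
  fits <- vector("list", 4L)
  for (j in 1:4) {
    if (n < k[j] + 1L) next
    f <- fit_poisson(X[, columns[[j]], drop = FALSE], train_count)
    if (!f$converged) next
    f$label <- labels[j]
    f$n_params <- k[j]
    f$n_train <- n
    f$aic <- aic(f$log_likelihood, k[j])
    fits[[j]] <- f
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    return(NULL)
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ks <- vapply(fits, `[[`, integer(1), "n_params")
  tied <- aics - min(aics) < 1e-9
  fits[tied][[which.min(ks[tied])]]
}
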