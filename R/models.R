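#' Feature-vector specifications
#'
#' The two fixed predictor sets used in the regression experiments. The
#' `temporal` vector has 6 components: the hourly activity changes at 2, 3
#' and 4 AM, the last-seen shifts at the 4 AM and 5 AM cutoffs, and the
#' short video-platform interval change. The `semantic` vector has 9: the
#' work, money, death and authentic-hook changes from the search stream; the
#' anxiety, sadness, friends and tone-hook changes from the video stream;
#' and the adult category change.
#'
#' @param name `"temporal"`, `"semantic"`, or `"custom"` (supply
#'   `components`).
#' @param components For `"custom"`: a tibble with `feature_name` and
#'   `parameter`.
#' @return A tibble of class `feature_vector_spec` with attributes `name`
#'   and `dimensionality`.
#' @export
feature_vector_spec <- function(name = c("temporal", "semantic", "custom"),
                                components = NULL) {
  name <- match.arg(name)
  components <- switch(name,
    temporal = tibble(
      feature_name = c("hourly_change", "hourly_change", "hourly_change",
                       "last_seen_shift", "last_seen_shift", "sei_change"),
      parameter = c("2", "3", "4", "4", "5", "youtube")
    ),
    semantic = tibble(
      feature_name = c(rep("lexicon_search", 4), rep("lexicon_video", 4),
                       "category_change"),
      parameter = c("work", "money", "death", "authentic",
                    "anxiety", "sadness", "friends", "tone", "adult")
    ),
    custom = {
      if (is.null(components)) abort("custom spec needs `components`")
      as_tibble(components)[c("feature_name", "parameter")]
    }
  )
  structure(components,
    class = c("feature_vector_spec", class(components)),
    name = name, dimensionality = nrow(components)
  )
}

#' Assemble the design matrix for a feature-vector spec
#'
#' Pivots the tidy feature table into a participants-by-components matrix in
#' spec order. Sporadic missing entries (for example strict-policy hourly
#' changes with a zero baseline) are imputed with the cohort median of the
#' column, with the imputation count reported; a component missing for every
#' participant, or present for fewer than `min_coverage` of them, is an
#' error.
#'
#' @param features Tidy feature table.
#' @param spec A [feature_vector_spec()].
#' @param min_coverage Minimum fraction of participants with an observed
#'   value per component.
#' @param quiet Suppress the imputation message.
#' @return A numeric matrix with participant ids as rownames and
#'   `feature_parameter` column names; the number of imputed cells is
#'   attached as attribute `n_imputed`.
#' @export
build_feature_matrix <- function(features, spec, min_coverage = 0.2,
                                 quiet = FALSE) {
  stopifnot(inherits(spec, "feature_vector_spec"))
  keys <- paste(spec$feature_name, spec$parameter, sep = "_")
  wide <- features_wide(features)
  miss <- setdiff(keys, names(wide))
  if (length(miss)) abort(paste("spec components absent from features:", paste(miss, collapse = ", ")))
  X <- as.matrix(wide[keys])
  rownames(X) <- wide$participant_id
  coverage <- colMeans(is.finite(X))
  dead <- keys[coverage == 0]
  if (length(dead)) abort(paste("component observed for no participant:", paste(dead, collapse = ", ")))
  thin <- keys[coverage < min_coverage]
  if (length(thin)) {
    warn(paste("components observed for under", min_coverage * 100,
               "% of participants:", paste(thin, collapse = ", ")))
  }
  n_imputed <- sum(!is.finite(X))
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- median(X[!bad, j])
  }
  if (n_imputed > 0 && !quiet) {
    inform(sprintf("build_feature_matrix: imputed %d missing cells with column medians",
                   n_imputed))
  }
  attr(X, "n_imputed") <- n_imputed
  X
}

#' Model configuration for the regression evaluation
#'
#' @param model `"ols"` or `"lasso"`.
#' @param alpha L1 penalty weight on the `1/(2n) * RSS + alpha * ||b||_1`
#'   scale (default 1e-4).
#' @param alpha_grid Optional penalty grid for inner leave-one-out tuning;
#'   when supplied with `tune = TRUE`, each outer training fold picks its own
#'   alpha. The default behavior fixes alpha for reproducibility.
#' @param tune Enable inner-loop tuning over `alpha_grid`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(model = c("ols", "lasso"), alpha = 1e-4,
                         alpha_grid = NULL, tune = FALSE) {
  model <- match.arg(model)
  if (alpha < 0) abort("`alpha` must be nonnegative")
  if (tune && (is.null(alpha_grid) || length(alpha_grid) == 0)) {
    abort("tuning requires a nonempty `alpha_grid`")
  }
  structure(list(model = model, alpha = alpha, alpha_grid = alpha_grid, tune = tune),
            class = "model_config")
}

#' L1-penalized least squares
#'
#' Minimizes `1/(2n) * sum((y - b0 - X b)^2) + alpha * sum(|b|)` with an
#' unpenalized intercept, by coordinate descent (via glmnet). At `alpha = 0`
#' the unpenalized least-squares solution is returned. Predictors are used
#' as given (standardize upstream if desired); the fit is deterministic in
#' the data.
#'
#' @param X Numeric predictor matrix.
#' @param y Response vector.
#' @param alpha Nonnegative L1 penalty.
#' @return List with `coefficients` (named), `intercept`, `alpha`.
#' @export
fit_l1 <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (alpha < 0) abort("`alpha` must be nonnegative")
  if (alpha == 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    if (any(is.na(fit$coefficients))) {
      abort("singular design for unpenalized least squares; use lasso or drop features")
    }
    return(list(coefficients = setNames(fit$coefficients[-1], colnames(X)),
                intercept = unname(fit$coefficients[1]), alpha = 0))
  }
  if (sd(y) == 0) {
    # constant response: the penalized optimum is the intercept-only fit
    return(list(coefficients = setNames(rep(0, ncol(X)), colnames(X)),
                intercept = y[1], alpha = alpha))
  }
  fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1, lambda = alpha,
                        standardize = FALSE, intercept = TRUE, thresh = 1e-12)
  beta <- as.numeric(fit$beta)
  list(coefficients = setNames(beta, colnames(X)),
       intercept = unname(fit$a0), alpha = alpha)
}

standardize_train <- function(X_train) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, sd)
  sdv[sdv == 0] <- 1 # constant training column carries no information
  list(mu = mu, sd = sdv,
       apply = function(M) sweep(sweep(M, 2, mu), 2, sdv, "/"))
}

fit_predict <- function(X_train, y_train, X_test, model, alpha) {
  sc <- standardize_train(X_train)
  Xs <- sc$apply(X_train)
  f <- if (model == "ols") fit_l1(Xs, y_train, 0) else fit_l1(Xs, y_train, alpha)
  drop(sc$apply(X_test) %*% f$coefficients + f$intercept)
}

#' Leave-one-out evaluation of a regression model
#'
#' The small-cohort evaluation protocol: `n` outer splits each train on
#' `n - 1` participants and predict the held-out one. Predictors are
#' standardized with training-fold statistics only, so no held-out point
#' leaks into its own fold. With `tune = TRUE` in the config, each outer
#' fold selects its penalty by a complete inner leave-one-out over
#' `alpha_grid` on its training samples.
#'
#' Reported metrics: the per-split squared errors and their mean (MSE), and
#' the pooled-prediction R-squared `1 - PRESS/SST` computed over all held-out
#' predictions. A per-split R-squared on a single test point is undefined,
#' so the pooled form is the well-defined analogue of an averaged one.
#' Coefficients come from one full-data fit (standardized predictors).
#'
#' @param X Design matrix (see [build_feature_matrix()]).
#' @param y Response (score deltas), length `nrow(X)` and at least 5.
#' @param config A [model_config()].
#' @param target Optional response label stored in the report.
#' @return An object of class `loo_report`.
#' @export
loo_evaluate <- function(X, y, config = model_config(), target = NULL) {
  stopifnot(inherits(config, "model_config"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) abort("`y` must match rows of `X`")
  if (n < 5) abort("leave-one-out evaluation needs n >= 5")

  pick_alpha <- function(idx_train) {
    if (!config$tune || config$model != "lasso") return(config$alpha)
    inner_mse <- vapply(config$alpha_grid, function(a) {
      errs <- vapply(seq_along(idx_train), function(j) {
        tr <- idx_train[-j]; te <- idx_train[j]
        (fit_predict(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE],
                     config$model, a) - y[te])^2
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    config$alpha_grid[which.min(inner_mse)]
  }

  preds <- vapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    a <- pick_alpha(tr)
    fit_predict(X[tr, , drop = FALSE], y[tr], X[i, , drop = FALSE],
                config$model, a)
  }, numeric(1))
  errors <- (preds - y)^2
  sst <- sum((y - mean(y))^2)

  sc <- standardize_train(X)
  full <- fit_l1(sc$apply(X), y, if (config$model == "ols") 0 else config$alpha)

  structure(list(
    per_split_errors = errors,
    predictions = preds,
    mse = mean(errors),
    r2 = 1 - sum(errors) / sst,
    coefficients = full$coefficients,
    intercept = full$intercept,
    config = config, n = n, target = target
  ), class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat("<loo_report>", x$config$model,
      if (x$config$model == "lasso") sprintf("(alpha = %g)", x$config$alpha),
      if (!is.null(x$target)) paste("->", x$target), "\n")
  cat(sprintf("  n = %d leave-one-out splits; MSE = %.4g; pooled R^2 = %.4g\n",
              x$n, x$mse, x$r2))
  invisible(x)
}

#' @rdname loo_evaluate
#' @param x,object A `loo_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.loo_report <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname loo_evaluate
#' @exportS3Method generics::glance
glance.loo_report <- function(x, ...) {
  tibble(model = x$config$model, alpha = x$config$alpha, n = x$n,
         mse = x$mse, r2 = x$r2, target = x$target %||% NA_character_)
}

#' Full-data coefficient table for a feature-vector spec
#'
#' Mirrors the coefficient tables of the modeling experiments: one full-data
#' penalized fit on standardized predictors, reported component by
#' component in spec order.
#'
#' @param X Design matrix from [build_feature_matrix()].
#' @param y Response vector.
#' @param spec The [feature_vector_spec()] used to build `X`.
#' @param config A [model_config()] (the penalty fit uses `config$alpha`).
#' @return A tibble `(feature_name, parameter, coefficient)`.
#' @export
coefficient_report <- function(X, y, spec, config = model_config("lasso")) {
  sc <- standardize_train(as.matrix(X))
  fit <- fit_l1(sc$apply(as.matrix(X)), y,
                if (config$model == "ols") 0 else config$alpha)
  tibble(
    feature_name = spec$feature_name,
    parameter = spec$parameter,
    coefficient = unname(fit$coefficients)
  )
}
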