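test_that("fixed feature-vector specs have the documented dimensionality", {
  tm <- feature_vector_spec("temporal")
  expect_equal(attr(tm, "dimensionality"), 6)
  expect_equal(sum(tm$feature_name == "hourly_change"), 3)
  sm <- feature_vector_spec("semantic")
  expect_equal(attr(sm, "dimensionality"), 9)
  expect_error(feature_vector_spec("custom"), "components")
})

test_that("feature matrix is participant-aligned with median imputation", {
  withr::with_seed(3, {
    feats <- tidyr::expand_grid(
      participant_id = sprintf("p%02d", 1:12),
      feature_name = "hourly_change", parameter = as.character(c(2, 3, 4))
    ) |> dplyr::mutate(value = rnorm(dplyr::n()))
  })
  feats <- dplyr::bind_rows(
    feats,
    tidyr::expand_grid(participant_id = sprintf("p%02d", 1:12),
                       feature_name = "last_seen_shift", parameter = c("4", "5")) |>
      dplyr::mutate(value = rnorm(dplyr::n())),
    tibble::tibble(participant_id = sprintf("p%02d", 1:12),
                   feature_name = "sei_change", parameter = "youtube",
                   value = rnorm(12))
  )
  # knock one cell out; it must come back as that column's median
  feats$value[feats$participant_id == "p03" & feats$parameter == "3"] <- NA
  X <- build_feature_matrix(feats, feature_vector_spec("temporal"), quiet = TRUE)
  expect_equal(dim(X), c(12, 6))
  col <- feats$value[feats$parameter == "3" & feats$feature_name == "hourly_change"]
  expect_equal(X["p03", "hourly_change_3"], median(col, na.rm = TRUE))
  expect_equal(attr(X, "n_imputed"), 1)

  feats$value[feats$feature_name == "sei_change"] <- NA
  expect_error(build_feature_matrix(feats, feature_vector_spec("temporal")),
               "no participant")
})

test_that("fit_l1 at alpha 0 equals least squares; huge alpha zeroes all weights", {
  withr::with_seed(4, {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- 1 + X %*% c(0.5, -1, 0) + rnorm(20, 0, 0.1)
  })
  f0 <- fit_l1(X, y, 0)
  ls <- coef(lm(y ~ X))
  expect_equal(unname(f0$coefficients), unname(ls[-1]), tolerance = 1e-6)
  expect_equal(f0$intercept, unname(ls[1]), tolerance = 1e-6)

  fbig <- fit_l1(X, y, 1e6)
  expect_equal(unname(fbig$coefficients), c(0, 0, 0))
  expect_equal(fbig$intercept, mean(y), tolerance = 1e-6)
})

test_that("fit_l1 satisfies the lasso KKT conditions (independent check)", {
  withr::with_seed(7, {
    n <- 40
    X <- scale(matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c"))))
    y <- X %*% c(1, 0.5, 0) + rnorm(n, 0, 0.3)
  })
  alpha <- 0.1
  f <- fit_l1(X, y, alpha)
  r <- y - f$intercept - X %*% f$coefficients
  g <- drop(crossprod(X, r)) / n # subgradient of the smooth part
  for (j in seq_along(f$coefficients)) {
    if (abs(f$coefficients[j]) > 1e-10) {
      expect_equal(g[j], alpha * sign(f$coefficients[j]), tolerance = 1e-4)
    } else {
      expect_lte(abs(g[j]), alpha * (1 + 1e-4))
    }
  }
})

test_that("lasso L1 norm shrinks monotonically as alpha grows", {
  withr::with_seed(8, {
    X <- scale(matrix(rnorm(200), 40, 5))
    y <- X %*% c(1, -0.5, 0.3, 0, 0) + rnorm(40, 0, 0.2)
  })
  norms <- vapply(c(0.01, 0.05, 0.1, 0.3, 1),
                  function(a) sum(abs(fit_l1(X, y, a)$coefficients)), numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("noiseless linear targets give zero LOO error and R^2 of one", {
  withr::with_seed(9, {
    X <- matrix(rnorm(100), 25, 4, dimnames = list(sprintf("p%02d", 1:25), letters[1:4]))
    y <- drop(2 + X %*% c(1, -2, 0.5, 0))
  })
  rep_ <- loo_evaluate(X, y, model_config("ols"))
  expect_lte(rep_$mse, 1e-12)
  expect_gte(rep_$r2, 0.999999)
  expect_equal(length(rep_$per_split_errors), 25)
  expect_equal(rep_$mse, mean(rep_$per_split_errors))
})

test_that("OLS LOO mean squared error matches the closed-form PRESS oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(80), 20, 4)
      y <- drop(X %*% rnorm(4) + rnorm(20))
    })
    got <- loo_evaluate(X, y, model_config("ols"))$mse
    expect_equal(got, oracle_loo_mse_ols(X, y), tolerance = 1e-8)
  }
})

test_that("pure-noise targets usually give non-positive pooled R^2", {
  r2s <- vapply(1:10, function(seed) {
    withr::with_seed(seed, {
      X <- matrix(rnorm(100), 25, 4)
      y <- rnorm(25)
    })
    loo_evaluate(X, y, model_config("ols"))$r2
  }, numeric(1))
  expect_gte(mean(r2s <= 0), 0.8)
})

test_that("singular designs error for OLS with a pointer to the lasso", {
  X <- cbind(a = rnorm(10), b = 1:10, c = 2 * (1:10))
  y <- rnorm(10)
  expect_error(loo_evaluate(X, y, model_config("ols")), "lasso")
})

test_that("inner-loop tuning picks a penalty from the grid per fold", {
  withr::with_seed(10, {
    X <- scale(matrix(rnorm(60), 15, 4))
    y <- drop(X %*% c(1, 0, 0, 0) + rnorm(15, 0, 0.5))
  })
  cfg <- model_config("lasso", alpha_grid = c(0.001, 0.1, 1), tune = TRUE)
  rep_ <- loo_evaluate(X, y, cfg)
  expect_equal(length(rep_$per_split_errors), 15)
  expect_true(is.finite(rep_$mse))
})

test_that("coefficient report zeroes a feature that carries no signal", {
  withr::with_seed(11, {
    n <- 49
    X <- matrix(rnorm(n * 4), n, 4)
    spec <- feature_vector_spec("custom", components = tibble::tibble(
      feature_name = c("sig", "sig", "sig", "null"), parameter = as.character(1:4)
    ))
    colnames(X) <- paste(spec$feature_name, spec$parameter, sep = "_")
    y <- drop(X[, 1:3] %*% c(1, 0.6, 0.4)) # no noise, null feature orthogonal-ish
  })
  out <- coefficient_report(X, y, spec, model_config("lasso", alpha = 1e-4))
  expect_equal(nrow(out), 4)
  expect_equal(out$coefficient[out$feature_name == "null"], 0)
  expect_gt(out$coefficient[out$parameter == "1"], 0.5)
})

test_that("duplicated signal features split or concentrate their weight", {
  withr::with_seed(12, {
    n <- 49
    x <- rnorm(n)
    X <- cbind(s1 = x, s2 = x + rnorm(n, 0, 1e-6), z = rnorm(n))
    y <- 2 * x
  })
  single <- fit_l1(scale(X[, c(1, 3)]), y, 0.01)$coefficients[["s1"]]
  pair <- fit_l1(scale(X), y, 0.01)$coefficients
  expect_equal(pair[["s1"]] + pair[["s2"]], single, tolerance = 0.05)

  zero_y <- fit_l1(scale(X), rep(0, n), 0.01)
  expect_equal(unname(zero_y$coefficients), c(0, 0, 0))
})
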