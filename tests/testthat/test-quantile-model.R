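test_that("the check loss and calibration penalty match hand arithmetic", {
  expect_equal(quantile_loss(c(3, 4), c(3, 4), c(1, 1), 0.95), 0)
  expect_equal(quantile_loss(c(10, 5), c(8, 6), c(2, 1), 0.95),
               (0.95 * 2 * 2 + 0.05 * 1 * 1) / 3)
  y <- runif(20, 2, 8); q <- runif(20, 2, 8); a <- runif(20, 1, 5)
  expect_equal(quantile_loss(y, q, a * 10, 0.9), quantile_loss(y, q, a, 0.9),
               tolerance = 1e-12)
  expect_error(quantile_loss(y, q, rep(0, 20)), "no harvested area")

  y <- c(1, 2, 3, 4)
  expect_equal(lambda_penalty(y, rep(2.5, 4), rep(1, 4), 0.95, sd(y)),
               sd(y) * 4 * abs(0.5 - 0.95))
  expect_equal(lambda_penalty(y, rep(2.5, 4), rep(1, 4), 0.95, sd(y)),
               2.3238, tolerance = 1e-4)
  # surface below all data: under-surface share 0
  expect_equal(lambda_penalty(y, rep(0, 4), rep(1, 4), 0.95, 2),
               2 * 4 * 0.95)
  # share exactly tau
  y2 <- c(rep(1, 19), 5)
  expect_equal(lambda_penalty(y2, rep(3, 20), rep(1, 20), 0.95, 1), 0)
})

test_that("design matrices evaluate term products on z-scores", {
  df <- data.frame(gdd = c(1000, 2000, 3000), map = c(100, 300, 500))
  f <- normalization_factors(df, c("gdd", "map"))
  X <- build_design(df, model_spec(c("GDD", "MAP", "GDD:MAP", "GDD^2")), f)
  z <- apply_zscore(df, f)
  expect_equal(X[, "1"], rep(1, 3))
  expect_equal(X[, "GDD:MAP"], z$gdd * z$map)
  expect_equal(X[, "GDD^2"], z$gdd^2)

  Xz <- build_design(data.frame(gdd = 1, map = 2), model_spec("GDD:MAP"))
  expect_equal(unname(Xz[, "GDD:MAP"]), 2)

  expect_true(all(c("VF", "VF:GDD", "VF:MAP") %in% base_spec("wheat")$terms))
  expect_false(any(grepl("VF", base_spec("maize")$terms)))
  expect_error(build_design(df, model_spec("PCI"), f), "pci")
})

test_that("intercept-only fits equal the area-weighted 95th percentile", {
  set.seed(21)
  for (i in 1:5) {
    y <- rnorm(150, 6); a <- rlnorm(150, 0, 1)
    fit <- rq_fit_ip(matrix(1, 150, 1), y, 0.95, a)
    oracle <- weighted_quantile_area(y, a, 0.95)
    expect_lt(quantile_loss(y, rep(fit$coefficients, 150), a, 0.95),
              quantile_loss(y, rep(oracle, 150), a, 0.95) + 1e-8)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-7)
  }
})

test_that("the LP fit matches the grid-search oracle on tiny instances", {
  set.seed(22)
  for (i in 1:6) {
    n <- sample(4:6, 1)
    X <- cbind(1, runif(n, -1, 1))
    colnames(X) <- c("1", "A")
    y <- drop(X %*% runif(2, -2, 2)) + rnorm(n, 0, 0.5)
    a <- runif(n, 0.5, 2)
    tau <- sample(c(0.5, 0.8, 0.95), 1)
    lp <- rq_fit_ip(X, y, tau, a)
    lp_loss <- quantile_loss(y, drop(X %*% lp$coefficients), a, tau)
    oracle <- grid_qr_oracle(X, y, a, tau)
    expect_lte(lp_loss, oracle$loss + 1e-8)
    expect_lt(oracle$loss - lp_loss, 0.05)
  }
})

test_that("noiseless surfaces are recovered exactly", {
  fx <- exact_surface_fixture(31)
  fit <- rq_fit_ip(fx$X, fx$y, 0.95, fx$a, tol = 1e-12)
  expect_lt(max(abs(fit$coefficients - fx$beta)), 1e-6)
})

test_that("unregularized optima satisfy the LP calibration band", {
  set.seed(23)
  for (i in 1:5) {
    n <- 300
    X <- cbind(1, rnorm(n)); colnames(X) <- c("1", "A")
    y <- drop(X %*% c(4, 1)) * runif(n, 0.4, 1.05)
    a <- rlnorm(n, 0, 1)
    fit <- rq_fit_ip(X, y, 0.95, a)
    q <- drop(X %*% fit$coefficients)
    frac <- sum(a[y <= q]) / sum(a)
    expect_lt(abs(frac - 0.95), max(a) / sum(a) + 1e-6)
  }
})

test_that("adding a constant to y only shifts the intercept", {
  set.seed(24)
  n <- 200
  X <- cbind(1, runif(n, -1, 1)); colnames(X) <- c("1", "A")
  y <- 3 + 0.5 * X[, 2] + rnorm(n)
  a <- runif(n, 0.5, 2)
  f1 <- rq_fit_ip(X, y, 0.95, a, tol = 1e-12)
  f2 <- rq_fit_ip(X, y + 2.5, 0.95, a, tol = 1e-12)
  expect_equal(f2$coefficients[1] - f1$coefficients[1], 2.5,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-6)
})

test_that("regularization calibrates the under-surface area share", {
  panel <- generate_panel(scenario_config(n_units = 1200, seed = 25))
  rec <- panel$records[panel$records$year == 1995, ]
  spec <- model_spec(default_beta_terms(panel))
  ser <- fit_annual_series(rec, spec, years = 1995)
  fit <- ser$fits[["1995"]]
  expect_lt(abs(fit$fraction_below - 0.95), 0.01)
  # regularized objective never exceeds the unregularized one
  ser0 <- fit_annual_series(rec, spec, years = 1995, regularized = FALSE)
  expect_lte(fit$objective, ser0$fits[["1995"]]$objective + 1e-10)
})

test_that("rank-deficient designs and degenerate weights are refused", {
  X <- cbind(1, c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(rq_fit_ip(X, rnorm(4), 0.5), "rank deficient")
  expect_error(rq_fit_ip(matrix(1, 3, 1), rnorm(3), 0.5, weights = rep(0, 3)),
               "no harvested area")
})

test_that("annual series fit one surface per year and reject time terms", {
  panel <- generate_panel(scenario_config(n_units = 150, years = 1999:2001,
                                          seed = 26))
  spec <- model_spec(default_beta_terms(panel))
  ser <- fit_annual_series(panel$records, spec)
  expect_named(ser$fits, c("1999", "2000", "2001"))
  expect_equal(ser$fits[["2000"]]$year, 2000)
  expect_error(fit_annual_series(panel$records, model_spec(c("GDD", "t"))),
               "without time terms")
  expect_error(
    suppressWarnings(fit_annual_series(panel$records[1:20, ], spec,
                                       years = 1999)),
    "records per coefficient")
  # a thin year is skipped with a warning while full years still fit
  thin <- rbind(panel$records[panel$records$year == 2000, ],
                panel$records[panel$records$year == 1999, ][1:10, ])
  expect_warning(ser2 <- fit_annual_series(thin, spec), "skipped")
  expect_named(ser2$fits, "2000")
})

test_that("prediction reproduces a noiseless generating ceiling", {
  set.seed(27)
  n <- 400
  rec <- data.frame(unit_id = sprintf("u%d", seq_len(n)), crop = "maize",
                    year = 2000, area_ha = 1, area_fraction = 1,
                    gdd = runif(n, 1000, 9000), map = runif(n, 200, 3200))
  f <- normalization_factors(rec, c("gdd", "map"))
  z <- apply_zscore(rec[c("gdd", "map")], f)
  ceiling_true <- 6 + 1.2 * z$gdd + 0.8 * z$map
  eps <- -runif(n, 0.2, 2)
  eps[sample(n, 32)] <- 0                      # 8% of points on the surface
  rec$yield_t_ha <- ceiling_true + eps
  spec <- model_spec(c("GDD", "MAP"))
  ser <- fit_annual_series(rec, spec, years = 2000, regularized = FALSE)
  pred <- predict_attainable(ser, rec, 2000)
  expect_equal(pred, ceiling_true, tolerance = 1e-6)

  # all-zero z covariates give the de-normalized intercept
  yf <- ser$factors[ser$factors$var == "yield_t_ha", ]
  mid <- as.data.frame(as.list(setNames(
    ser$factors$mean[ser$factors$var != "yield_t_ha"],
    ser$factors$var[ser$factors$var != "yield_t_ha"])))
  expect_equal(suppressWarnings(predict_attainable(ser, mid, 2000)),
               unname(ser$fits[["2000"]]$coefficients[1] * yf$sd + yf$mean),
               tolerance = 1e-10)
})

test_that("negative raw predictions are floored at zero with a warning", {
  set.seed(28)
  gdd <- runif(60, 1000, 9000)
  rec <- data.frame(unit_id = sprintf("u%d", 1:60), crop = "maize",
                    year = 2000,
                    yield_t_ha = 5 - 4.5 * (gdd - 1000) / 8000 +
                      runif(60, 0, 0.2),
                    area_ha = 1, area_fraction = 1, gdd = gdd)
  ser <- fit_annual_series(rec, model_spec("GDD"), years = 2000)
  w <- capture_warnings(p <- predict_attainable(ser,
                                                data.frame(gdd = 30000),
                                                2000))
  expect_true(any(grepl("floored", w)))
  expect_true(any(grepl("support", w)))
  expect_identical(p, 0)
})
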