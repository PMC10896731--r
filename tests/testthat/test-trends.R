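test_that("gap tables conserve gap + actual = attainable", {
  panel <- generate_panel(scenario_config(n_units = 80, years = 1999:2001,
                                          seed = 71))
  spec <- model_spec(default_beta_terms(panel))
  ser <- fit_annual_series(panel$records, spec)
  ens <- list("2000" = bootstrap_fit(panel$records, spec, 2000, B = 4,
                                     seed = 1, factors = ser$factors))
  gt <- gap_table(panel$records, ser, ens, years = 2000)
  expect_setequal(unique(gt$rep), 1:4)
  expect_equal(gt$gap + gt$actual, gt$attainable, tolerance = 1e-12)
  gt0 <- gap_table(panel$records, ser)
  expect_true(all(gt0$rep == 0))
  expect_equal(nrow(gt0), sum(panel$records$year %in% 1999:2001))
})

test_that("windowed values are area-weighted over +/-2 years", {
  df <- data.frame(year = 2008:2012, gap = 1:5, area = 1)
  expect_equal(windowed_value(df, 2010), 3)
  expect_equal(windowed_value(df, 2012), 4)    # edge: only 3 window years
  df$area <- c(1, 1, 1, 1, 6)
  expect_equal(windowed_value(df, 2010), (1 + 2 + 3 + 4 + 30) / 10)
  expect_equal(windowed_value(data.frame(year = 2000, gap = 7, area = 2),
                              2010), NA_real_)
  const <- data.frame(year = 1998:2012, gap = 2.5, area = runif(15, 1, 9))
  expect_equal(windowed_value(const, 2005), 2.5)
})

test_that("windowed values are invariant to splitting a unit in two", {
  set.seed(72)
  one <- data.frame(year = rep(1998:2002, each = 1), gap = runif(5),
                    area = runif(5, 2, 4))
  halves <- rbind(transform(one, area = area * 0.3),
                  transform(one, area = area * 0.7))
  expect_equal(windowed_value(halves, 2000), windowed_value(one, 2000),
               tolerance = 1e-12)
})

test_that("exactly linear gaps recover their slope and closure time", {
  years <- 1998:2012
  gt <- make_gap_table(years, list(a = 12 - 1 * (years - 1998),
                                   b = 4 - 0.2 * (years - 1998)))
  tr <- unit_trends(gt, "gap", years = years)
  expect_equal(tr$x1, c(-1, -0.2), tolerance = 1e-12)
  expect_equal(tr$x0, c(12, 4), tolerance = 1e-9)
  tc <- time_to_closure(tr)
  expect_equal(tc$t_close, c(-12 / -1 - 12, -4 / -0.2 - 12),
               tolerance = 1e-9)
  expect_equal(tc$t_close, c(0, 8), tolerance = 1e-9)
  expect_true(all(tc$category == "years"))
})

test_that("closure categories follow the slope sign calls", {
  years <- 1998:2012
  set.seed(73)
  # ensemble with slope bounds straddling zero -> no_trend
  reps <- lapply(1:40, function(b) {
    sl <- runif(1, -0.3, 0.1)
    data.frame(unit_id = "u", year = years, rep = b,
               actual = 5, attainable = 5 + 3 + sl * (years - 1998),
               gap = 3 + sl * (years - 1998), area = 1,
               stringsAsFactors = FALSE)
  })
  tr <- unit_trends(do.call(rbind, reps), "gap", years = years)
  expect_equal(time_to_closure(tr)$category, "no_trend")
  # significantly widening gap -> widen
  reps2 <- lapply(1:40, function(b) {
    sl <- runif(1, 0.2, 0.4)
    data.frame(unit_id = "u", year = years, rep = b,
               actual = 5, attainable = 5 + 3 + sl * (years - 1998),
               gap = 3 + sl * (years - 1998), area = 1,
               stringsAsFactors = FALSE)
  })
  tr2 <- unit_trends(do.call(rbind, reps2), "gap", years = years)
  expect_equal(time_to_closure(tr2)$category, "widen")
  # identical realizations -> zero-width slope interval
  reps3 <- do.call(rbind, lapply(1:5, function(b)
    transform(make_gap_table(years, list(u = 6 - 0.3 * (years - 1998))),
              rep = b)))
  tr3 <- unit_trends(reps3, "gap", years = years)
  expect_equal(tr3$lo, tr3$hi, tolerance = 1e-12)
})

test_that("white-noise gaps are rarely called significant", {
  set.seed(74)
  years <- 1998:2012
  gaps <- lapply(1:100, function(i) rnorm(15, 3, 0.5))
  names(gaps) <- sprintf("u%03d", 1:100)
  tr <- unit_trends(make_gap_table(years, gaps), "gap", years = years)
  expect_gte(mean(tr$sig == "none"), 0.85)
})

test_that("area shares of significant change respect the ground truth", {
  cfg <- scenario_config(n_units = 250, seed = 75,
                         scenario = c(steady_growth = 0.3,
                                      ceiling_pressure_flatceiling = 0.7))
  panel <- generate_panel(cfg)
  gt <- gap_table_truth(panel)
  us <- attr(panel, "unit_slopes")
  truth_share <- 100 * sum(us$area_ha[us$scenario == "steady_growth"]) /
    sum(us$area_ha)
  got <- area_fraction_significant(gt, "attainable", "positive",
                                   period = c(1975, 2010), ref_year = 2000)
  expect_lt(abs(as.numeric(got) - truth_share), 5)
  up <- area_fraction_significant(gt, "gap", "positive",
                                  period = c(1975, 2010), ref_year = 2000)
  dn <- area_fraction_significant(gt, "gap", "negative",
                                  period = c(1975, 2010), ref_year = 2000)
  expect_lte(as.numeric(up) + as.numeric(dn), 100)
})

test_that("degenerate area shares hit 0 and 100", {
  years <- 1998:2012
  growing <- make_gap_table(years, list(a = 1 + 0.5 * (years - 1998),
                                        b = 2 + 0.3 * (years - 1998)))
  expect_equal(as.numeric(
    area_fraction_significant(growing, "gap", "positive",
                              period = c(1998, 2012), ref_year = 2000)), 100)
  expect_equal(as.numeric(
    area_fraction_significant(growing, "gap", "negative",
                              period = c(1998, 2012), ref_year = 2000)), 0)
})

test_that("global average change normalizes by the base-year value", {
  years <- 1975:2010
  base <- 4
  gt <- make_gap_table(years, list(u = base + 0.01 * base * (years - 2000)))
  out <- global_average_change(gt, "gap", period = c(1975, 2010),
                               base_year = 2000)
  expect_equal(out$rate, 1, tolerance = 1e-9)
  expect_equal(out$lo, out$hi)
  const <- make_gap_table(years, list(u = rep(2, length(years))))
  out2 <- global_average_change(const, "gap", period = c(1975, 2010))
  expect_equal(out2$rate, 0, tolerance = 1e-12)
  expect_equal(out2$hi - out2$lo, 0)
})

test_that("near-zero base realizations are rejected from global rates", {
  years <- 1975:2010
  mk <- function(b, gapv) data.frame(unit_id = "u", year = years, rep = b,
                                     actual = 1, attainable = 1 + gapv,
                                     gap = gapv, area = 1,
                                     stringsAsFactors = FALSE)
  df <- rbind(mk(1, 4 + 0.04 * (years - 2000)),
              mk(2, 4.1 + 0.04 * (years - 2000)),
              mk(3, rep(0, length(years))))       # zero base gap
  out <- global_average_change(df, "gap", period = c(1975, 2010))
  expect_equal(out$n_used, 2)
  expect_gte(out$n_rejected, 1)
})

test_that("the fixed-area counterfactual isolates expansion effects", {
  years <- 2000:2010
  # constant areas: factual equals counterfactual
  df <- make_gap_table(years, list(a = rep(2, 11), b = rep(1, 11)),
                       area_by_unit = c(a = 3, b = 5))
  cf <- fixed_area_counterfactual(df, 2000)
  expect_equal(cf$gap_factual, cf$gap_fixed, tolerance = 1e-12)
  expect_equal(cf$attainable_factual, cf$attainable_fixed, tolerance = 1e-12)

  # expansion concentrated in a low-ceiling unit drags the factual
  # global ceiling below the frozen-weight counterfactual
  hi <- data.frame(unit_id = "hi", year = years, rep = 0L, actual = 5,
                   attainable = 10, gap = 5, area = 10)
  lo <- data.frame(unit_id = "lo", year = years, rep = 0L, actual = 2,
                   attainable = 4, gap = 2,
                   area = 1 + 3 * (years - 2000))
  cf2 <- fixed_area_counterfactual(rbind(hi, lo), 2000)
  expect_true(all(cf2$attainable_factual[-1] < cf2$attainable_fixed[-1]))

  single <- fixed_area_counterfactual(hi, 2000)
  expect_equal(single$gap_factual, single$gap_fixed)
})
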