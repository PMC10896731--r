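test_that("the piecewise detector recovers noiseless broken-stick slopes", {
  yrs <- 1986:2012
  y <- 1 + 0.05 * (yrs - 1986) - 0.05 * pmax(yrs - 2000, 0)
  r <- suppressWarnings(piecewise_stagnation(yrs, y))
  expect_equal(r$pre_slope, 0.05, tolerance = 1e-10)
  expect_equal(r$post_slope, 0, tolerance = 1e-10)
  expect_false(r$indeterminate)
})

test_that("rising, plateauing and flat series are labelled correctly", {
  yrs <- 1986:2012
  set.seed(81)
  rising <- piecewise_stagnation(yrs, 2 + 0.05 * (yrs - 1986) +
                                   rnorm(27, 0, 0.05))
  expect_false(rising$stagnant)

  hits <- 0; false_pos <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    plateau <- ifelse(yrs <= 2000, 2 * (1 + 0.02 * (yrs - 1986)),
                      2 * (1 + 0.02 * 14)) * exp(rnorm(27, 0, 0.02))
    flat <- rep(2.5, 27) * exp(rnorm(27, 0, 0.02))
    hits <- hits + isTRUE(piecewise_stagnation(yrs, plateau)$stagnant)
    false_pos <- false_pos + isTRUE(piecewise_stagnation(yrs, flat)$stagnant)
  }
  expect_gte(hits / 20, 0.9)
  expect_lte(false_pos / 20, 0.1)

  short <- piecewise_stagnation(1996:2012, rnorm(17, 3))
  expect_true(short$indeterminate)
})

test_that("the typology cascade is exhaustive and matches its archetypes", {
  # ceiling up, floor up, gap not closing -> steady growth
  expect_equal(classify_typology("positive", "positive", "positive"),
               "steady_growth")
  expect_equal(classify_typology("positive", "positive", "none"),
               "steady_growth")
  # ceiling up, floor flat -> stalled floor
  expect_equal(classify_typology("positive", "none", "positive"),
               "stalled_floor")
  # gap significantly closing -> ceiling pressure even when both rise
  expect_equal(classify_typology("positive", "positive", "negative"),
               "ceiling_pressure")
  # stagnating ceiling -> ceiling pressure
  expect_equal(classify_typology("none", "positive", "positive"),
               "ceiling_pressure")

  sigs <- c("positive", "negative", "none")
  grid <- expand.grid(c = sigs, f = sigs, g = sigs,
                      stringsAsFactors = FALSE)
  lab <- classify_typology(grid$c, grid$f, grid$g)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% c("steady_growth", "stalled_floor",
                             "ceiling_pressure")))
  expect_true(anyNA(classify_typology(NA_character_, "none", "none")))
})

test_that("typology area shares always list three labels summing to 100", {
  lab <- data.frame(label = rep("steady_growth", 4), area = c(1, 2, 3, 4))
  tab <- typology_area_table(lab)
  expect_equal(tab$share_pct, c(100, 0, 0))
  expect_equal(tab$label, c("steady_growth", "stalled_floor",
                            "ceiling_pressure"))
  lab2 <- data.frame(label = c("steady_growth", "ceiling_pressure", NA),
                     area = c(3, 1, 7))
  tab2 <- typology_area_table(lab2)
  expect_equal(sum(tab2$share_pct), 100)
  expect_equal(attr(tab2, "unlabeled_area"), 7)
})

test_that("scenario-labelled panels are classified back to their scenario", {
  cfg <- scenario_config(n_units = 300, seed = 82,
                         scenario = c(steady_growth = 0.5, stalled_floor = 0.2,
                                      ceiling_pressure_gapclose = 0.15,
                                      ceiling_pressure_flatceiling = 0.15))
  panel <- generate_panel(cfg)
  lab <- typology_labels(gap_table_truth(panel), years = 1998:2012)
  m <- merge(lab, attr(panel, "unit_slopes"), by = "unit_id")
  expected <- ifelse(m$scenario == "steady_growth", "steady_growth",
                     ifelse(m$scenario == "stalled_floor", "stalled_floor",
                            "ceiling_pressure"))
  ok <- !is.na(m$label) & m$label == expected
  expect_gte(sum(m$area_ha[ok]) / sum(m$area_ha), 0.8)
})

test_that("risk ratios separate causal from null stagnation worlds", {
  set.seed(83)
  n <- 400
  closing <- runif(n) < 0.3
  # closure mechanically raises the stagnation probability
  causal <- data.frame(closing = closing,
                       stagnant = runif(n) < ifelse(closing, 0.6, 0.2),
                       growth = rnorm(n))
  rr <- stagnation_risk_ratio(causal)
  expect_gt(rr$ratio, 1)
  expect_equal(sum(rr$counts), n)

  # null worlds: the ratio concentrates around 1 across repeated draws
  in_band <- 0
  for (s in 1:20) {
    set.seed(900 + s)
    cl <- runif(1000) < 0.3
    null <- data.frame(closing = cl, stagnant = runif(1000) < 0.35)
    r0 <- stagnation_risk_ratio(null)$ratio
    in_band <- in_band + (r0 >= 0.8 && r0 <= 1.25)
  }
  expect_gte(in_band / 20, 0.9)

  none <- data.frame(closing = closing, stagnant = rep(FALSE, n))
  expect_warning(rr_none <- stagnation_risk_ratio(none), "no stagnant")
  expect_equal(rr_none$ratio, 0)
})

test_that("risk ratios survive end-to-end on a constructed closure world", {
  # units whose gaps close 1986-2000 then plateau 2000-2012; controls grow
  set.seed(84)
  yrs <- 1986:2012
  units <- list()
  truth_closing <- logical(60)
  stag <- logical(60)
  for (i in 1:60) {
    closing <- i <= 30
    truth_closing[i] <- closing
    if (closing) {
      yield <- ifelse(yrs <= 2000, 3 + 0.08 * (yrs - 1986), 3 + 0.08 * 14)
      att <- 5 + 0.01 * (yrs - 1986)
    } else {
      yield <- 2 + 0.03 * (yrs - 1986)
      att <- 6 + 0.05 * (yrs - 1986)
    }
    yield <- yield * exp(rnorm(27, 0, 0.015))
    units[[i]] <- data.frame(unit_id = sprintf("u%02d", i), year = yrs,
                             rep = 0L, actual = yield, attainable = att,
                             gap = att - yield, area = 1,
                             stringsAsFactors = FALSE)
    stag[i] <- isTRUE(piecewise_stagnation(yrs, yield)$stagnant)
  }
  df <- do.call(rbind, units)
  tr86 <- unit_trends(df, "gap", years = 1986:2000, origin = 1986)
  tclose <- -tr86$x0 / tr86$x1 - 14
  closing_call <- tr86$sig == "negative" & is.finite(tclose) & tclose <= 30
  expect_gte(mean(closing_call == truth_closing), 0.9)
  rr <- stagnation_risk_ratio(data.frame(closing = closing_call,
                                         stagnant = stag))
  expect_gt(rr$ratio, 1)
})
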