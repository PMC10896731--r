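# Yield-gap series, windowed averages, linear trends, time to closure,
# area-with-significant-change tables, global average changes and the
# fixed-area counterfactual.
#
# The common currency is a long "gap table": one row per
# (unit, year, realization) with columns unit_id, year, rep, actual,
# attainable, gap and area.  rep = 0 denotes a single point estimate;
# bootstrap realizations are numbered from 1.

#' Assemble a gap table from fitted surfaces
#'
#' Evaluates the fitted (and optionally bootstrap-resampled) attainable
#' surfaces on the census records and returns the long gap table.  Gaps are
#' attainable minus actual and may be negative per realization; the
#' conservation `gap + actual = attainable` holds exactly.
#'
#' @param records census records.
#' @param series a `yg_annual_series` from [fit_annual_series()].
#' @param ensembles optional named list (by year) of `yg_ensemble`s; each
#'   bootstrap realization becomes one `rep`.
#' @param years years to include (default: the fitted years).
#' @return long `data.frame` gap table.
#' @export
gap_table <- function(records, series, ensembles = NULL, years = NULL) {
  stopifnot(inherits(series, "yg_annual_series"))
  years <- years %||% as.integer(names(series$fits))
  yf <- series$factors[series$factors$var == "yield_t_ha", ]
  out <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    fit <- series$fits[[as.character(yr)]]
    if (is.null(fit)) next
    sub <- records[records$year == yr, , drop = FALSE]
    X <- build_design(sub, series$spec, series$factors)
    mk <- function(beta, rep_id) {
      att <- pmax(drop(X %*% beta) * yf$sd + yf$mean, 0)
      data.frame(unit_id = sub$unit_id, year = yr, rep = rep_id,
                 actual = sub$yield_t_ha, attainable = att,
                 gap = att - sub$yield_t_ha, area = sub$area_ha,
                 stringsAsFactors = FALSE)
    }
    ens <- ensembles[[as.character(yr)]]
    if (is.null(ens)) {
      out[[k]] <- mk(fit$coefficients, 0L)
    } else {
      reps <- lapply(seq_len(nrow(ens$coefficients)), function(b)
        mk(ens$coefficients[b, ], b))
      out[[k]] <- do.call(rbind, reps)
    }
  }
  do.call(rbind, out)
}

#' Gap table from generator ground truth
#'
#' Builds the same long gap table directly from a synthetic panel's true
#' attainable yields (a single realization, `rep = 0`), for validating the
#' trend machinery against known trajectories.
#'
#' @param panel a `yg_panel`.
#' @return long gap table.
#' @export
gap_table_truth <- function(panel) {
  stopifnot(inherits(panel, "yg_panel"))
  m <- merge(panel$records[c("unit_id", "year", "yield_t_ha", "area_ha")],
             panel$truth[c("unit_id", "year", "attainable")],
             by = c("unit_id", "year"), sort = FALSE)
  data.frame(unit_id = m$unit_id, year = m$year, rep = 0L,
             actual = m$yield_t_ha, attainable = m$attainable,
             gap = m$attainable - m$yield_t_ha, area = m$area_ha,
             stringsAsFactors = FALSE)
}

#' Windowed area-weighted value
#'
#' Area-weighted mean of a quantity over the years `year +/- half_width`,
#' with each year weighted by its reported harvested area.  Missing years
#' simply drop out of the window; an empty window yields `NA`.
#'
#' @param df `data.frame` with columns `year`, the value column and `area`.
#' @param year centre year.
#' @param value value column name.
#' @param half_width window half-width.
#' @return scalar windowed value.
#' @export
windowed_value <- function(df, year, value = "gap", half_width = 2) {
  win <- df[abs(df$year - year) <= half_width, , drop = FALSE]
  if (!nrow(win) || sum(win$area) <= 0) return(NA_real_)
  weighted_mean_area(win[[value]], win$area)
}

# per-row OLS of a units x years value matrix; origin fixes the intercept's
# reference year.  Returns slope and fitted value at the origin; rows with
# fewer than min_years finite values get NA.
row_ols <- function(V, years, origin, min_years) {
  t(apply(V, 1, function(v) {
    ok <- is.finite(v)
    if (sum(ok) < min_years) return(c(NA_real_, NA_real_, NA_real_, sum(ok)))
    x <- years[ok] - origin
    y <- v[ok]
    xm <- mean(x); ym <- mean(y)
    ssx <- sum((x - xm)^2)
    b <- sum((x - xm) * (y - ym)) / ssx
    a <- ym - b * xm
    n <- length(x)
    se <- if (n > 2) sqrt(sum((y - a - b * x)^2) / (n - 2) / ssx) else NA_real_
    c(a, b, se, n)
  }))
}

#' Per-unit linear trends of a gap-table quantity
#'
#' Ordinary least squares of the chosen quantity on year, per unit and per
#' realization, with the intercept referenced to `origin`.  Significance of
#' the slope comes from the percentile bounds of the per-realization slopes;
#' with a single realization it falls back to the OLS t-interval.
#'
#' @param df long gap table.
#' @param value quantity: `"gap"`, `"attainable"` or `"actual"`.
#' @param years regression window (default 1998-2012).
#' @param origin intercept reference year (default `min(years)`).
#' @param level confidence level.
#' @param min_years minimum years required per unit (default 8).
#' @return object of class `yg_trends`: `data.frame` with per-unit `x0`
#'   (fitted value at origin), `x1` (slope, median over realizations),
#'   `lo`/`hi` slope bounds, `sig`, `n_years`; slope and intercept
#'   realization matrices are kept as attributes for closure-time work.
#' @export
unit_trends <- function(df, value = "gap", years = 1998:2012,
                        origin = min(years), level = 0.95, min_years = 8) {
  df <- df[df$year %in% years, , drop = FALSE]
  units <- sort(unique(df$unit_id))
  reps <- sort(unique(df$rep))
  x0 <- x1 <- matrix(NA_real_, length(units), length(reps),
                     dimnames = list(units, reps))
  se1 <- nyr <- NULL
  for (j in seq_along(reps)) {
    sub <- df[df$rep == reps[j], , drop = FALSE]
    V <- matrix(NA_real_, length(units), length(years),
                dimnames = list(units, years))
    V[cbind(match(sub$unit_id, units), match(sub$year, years))] <- sub[[value]]
    res <- row_ols(V, years, origin, min_years)
    x0[, j] <- res[, 1]
    x1[, j] <- res[, 2]
    if (j == 1L) { se1 <- res[, 3]; nyr <- res[, 4] }
  }
  single <- length(reps) == 1L
  sig <- character(length(units))
  lo <- hi <- numeric(length(units))
  for (i in seq_along(units)) {
    s <- x1[i, ]
    s <- s[is.finite(s)]
    if (!length(s)) {
      sig[i] <- NA_character_; lo[i] <- hi[i] <- NA_real_
      next
    }
    if (single) {
      if (!is.finite(se1[i])) {
        sig[i] <- NA_character_; lo[i] <- hi[i] <- NA_real_
        next
      }
      tq <- stats::qt(1 - (1 - level) / 2, df = nyr[i] - 2)
      lo[i] <- s - tq * se1[i]
      hi[i] <- s + tq * se1[i]
    } else {
      ci <- percentile_ci(s, level)
      lo[i] <- ci[1]; hi[i] <- ci[2]
    }
    sig[i] <- if (lo[i] > 0 && hi[i] > 0) "positive"
    else if (lo[i] < 0 && hi[i] < 0) "negative" else "none"
  }
  out <- data.frame(unit_id = units,
                    x0 = apply(x0, 1, stats::median, na.rm = TRUE),
                    x1 = apply(x1, 1, stats::median, na.rm = TRUE),
                    lo = lo, hi = hi, sig = sig,
                    n_years = if (single) nyr else length(years),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("yg_trends", "data.frame"),
            x0_mat = x0, x1_mat = x1, origin = origin, level = level,
            value = value, years = years)
}

#' Time to yield-gap closure
#'
#' From per-unit gap trends over 1998-2012 (origin 1998): each realization's
#' closure time relative to 2010 is `-x0/x1 - 12` (the zero crossing of the
#' fitted line, shifted from the 1998 origin to 2010).  Units whose slope
#' percentile bounds differ in sign get `"no_trend"` (no closure within the
#' confidence bounds); units with significantly diverging gaps (crossing in
#' the past) get `"widen"`; otherwise the median closure time across
#' realizations is reported in years relative to 2010.  Realizations with a
#' zero slope are excluded from the median.
#'
#' @param trends a `yg_trends` object for the gap.
#' @param reference reference year of the closure clock.
#' @return `data.frame` with `unit_id`, `category`
#'   (`"years"`, `"no_trend"`, `"widen"`) and `t_close`.
#' @export
time_to_closure <- function(trends, reference = 2010) {
  stopifnot(inherits(trends, "yg_trends"))
  offset <- reference - attr(trends, "origin")
  x0m <- attr(trends, "x0_mat")
  x1m <- attr(trends, "x1_mat")
  n <- nrow(trends)
  category <- character(n)
  t_close <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- trends$sig[i]
    if (is.na(s)) { category[i] <- NA_character_; next }
    if (s == "none") { category[i] <- "no_trend"; next }
    if (s == "positive") { category[i] <- "widen"; next }
    x0 <- x0m[i, ]; x1 <- x1m[i, ]
    ok <- is.finite(x0) & is.finite(x1) & x1 != 0
    tc <- -x0[ok] / x1[ok] - offset
    category[i] <- "years"
    t_close[i] <- stats::median(tc)
  }
  data.frame(unit_id = trends$unit_id, category = category,
             t_close = t_close, stringsAsFactors = FALSE)
}

#' Share of harvested area with a significant change
#'
#' Percentage of reference-year harvested area belonging to units whose
#' change in the chosen quantity over a period is significantly of the
#' requested sign.  By default the change is the endpoint difference of
#' +/-2-year windowed values computed per realization and sign-tested via
#' percentile bounds; `mode = "slope"` uses the regression-slope sign calls
#' of [unit_trends()] instead.
#'
#' @param df long gap table.
#' @param value quantity (`"attainable"` or `"gap"`).
#' @param direction `"positive"` (growth) or `"negative"` (decrease).
#' @param period `c(start_year, end_year)`.
#' @param ref_year year whose harvested areas weight the shares.
#' @param level confidence level.
#' @param mode `"endpoint"` or `"slope"`.
#' @return percentage (0-100) of reference-year area, with unit-level detail
#'   in the `"units"` attribute.
#' @export
area_fraction_significant <- function(df, value = "attainable",
                                      direction = "positive",
                                      period = c(1975, 2010),
                                      ref_year = 2000, level = 0.95,
                                      mode = c("endpoint", "slope")) {
  mode <- match.arg(mode)
  units <- sort(unique(df$unit_id))
  base <- df[df$rep == df$rep[1L] & df$year == ref_year, , drop = FALSE]
  ref_area <- base$area[match(units, base$unit_id)]
  if (anyNA(ref_area)) {
    warn_yg("%d unit(s) lack a reference-year area and are excluded",
            sum(is.na(ref_area)))
  }
  if (mode == "slope") {
    tr <- unit_trends(df, value = value, years = period[1]:period[2],
                      level = level)
    sig <- tr$sig[match(units, tr$unit_id)]
  } else {
    reps <- sort(unique(df$rep))
    d <- matrix(NA_real_, length(units), length(reps))
    for (j in seq_along(reps)) {
      sub <- df[df$rep == reps[j], , drop = FALSE]
      for (i in seq_along(units)) {
        u <- sub[sub$unit_id == units[i], , drop = FALSE]
        d[i, j] <- windowed_value(u, period[2], value) -
          windowed_value(u, period[1], value)
      }
    }
    sig <- apply(d, 1, function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) return(NA_character_)
      if (length(v) == 1L) return(if (v > 0) "positive"
                                  else if (v < 0) "negative" else "none")
      significant_sign(v, level)
    })
  }
  keep <- !is.na(ref_area) & !is.na(sig)
  share <- 100 * sum(ref_area[keep & sig == direction]) / sum(ref_area[keep])
  structure(share, units = data.frame(unit_id = units, sig = sig,
                                      ref_area = ref_area,
                                      stringsAsFactors = FALSE))
}

#' Globally averaged annual change of a quantity
#'
#' Per realization, forms the global area-weighted annual series of the
#' quantity, fits a linear trend over the period, and expresses the slope as
#' a percentage of the windowed base-year value.  Realizations with a
#' non-positive base value are rejected (near-zero gaps produce unbounded
#' relative rates); realizations outside `mean +/- 4 s.d.` of the surviving
#' rate distribution are rejected as outliers (`one_sided = TRUE` applies
#' the literal `mean + 4 s.d.` screen only).  The confidence interval comes
#' from the surviving realizations.
#'
#' @param df long gap table.
#' @param value quantity column.
#' @param period `c(start_year, end_year)` of the trend.
#' @param base_year year whose windowed value normalizes the slope.
#' @param level confidence level.
#' @param one_sided use the one-sided outlier screen.
#' @return list with `rate` (% per year, mean over realizations), `lo`,
#'   `hi`, `n_used`, `n_rejected`.
#' @export
global_average_change <- function(df, value = "gap", period = c(1975, 2010),
                                  base_year = 2000, level = 0.95,
                                  one_sided = FALSE) {
  reps <- sort(unique(df$rep))
  yrs <- period[1]:period[2]
  rates <- rep(NA_real_, length(reps))
  for (j in seq_along(reps)) {
    sub <- df[df$rep == reps[j], , drop = FALSE]
    glob <- global_series(sub, value)
    fitw <- glob[glob$year %in% yrs, , drop = FALSE]
    if (nrow(fitw) < 3) next
    b <- stats::coef(stats::lm(v ~ year, data = fitw))[2L]
    base <- windowed_value(data.frame(year = glob$year, gap = glob$v,
                                      area = glob$area), base_year, "gap")
    if (!is.finite(base) || base <= 0) next
    rates[j] <- 100 * b / base
  }
  ok <- is.finite(rates)
  r <- rates[ok]
  if (!length(r)) stop_yg("no usable realizations")
  m <- mean(r); s <- stats::sd(r)
  keep <- if (length(r) > 1 && is.finite(s) && s > 0) {
    if (one_sided) r <= m + 4 * s else abs(r - m) <= 4 * s
  } else rep(TRUE, length(r))
  r <- r[keep]
  list(rate = mean(r),
       lo = if (length(r) > 1) percentile_ci(r, level)[1] else mean(r),
       hi = if (length(r) > 1) percentile_ci(r, level)[2] else mean(r),
       n_used = length(r),
       n_rejected = sum(!ok) + sum(!keep))
}

# global area-weighted annual series of a gap-table quantity
global_series <- function(df, value = "gap") {
  f <- factor(df$year)
  sa <- drop(rowsum(df$area, f))
  v <- drop(rowsum(df[[value]] * df$area, f)) / sa
  data.frame(year = as.integer(levels(f)), v = v, area = sa,
             row.names = NULL)
}

#' Fixed-area counterfactual of the global series
#'
#' Recomputes the global attainable-yield and gap series holding every
#' unit's weight at its baseline-year harvested area, next to the factual
#' series with yearly weights.  Units without a baseline-year record are
#' excluded from both arms (paired comparison).
#'
#' @param df long gap table (single realization).
#' @param baseline_year year whose areas are frozen.
#' @return `data.frame` per year: factual and fixed-weight global attainable
#'   and gap.
#' @export
fixed_area_counterfactual <- function(df, baseline_year = 2000) {
  df <- df[df$rep == df$rep[1L], , drop = FALSE]
  base <- df[df$year == baseline_year, c("unit_id", "area")]
  df <- df[df$unit_id %in% base$unit_id, , drop = FALSE]
  frozen <- base$area[match(df$unit_id, base$unit_id)]
  fa <- global_series(df, "attainable")
  fg <- global_series(df, "gap")
  df2 <- df; df2$area <- frozen
  ca <- global_series(df2, "attainable")
  cg <- global_series(df2, "gap")
  data.frame(year = fa$year,
             attainable_factual = fa$v, attainable_fixed = ca$v,
             gap_factual = fg$v, gap_fixed = cg$v,
             row.names = NULL)
}
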