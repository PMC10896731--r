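# Three-category typology of yield-gap trajectories, piecewise stagnation
# detection and the gap-closure -> stagnation risk ratio.

#' Piecewise (broken-stick) stagnation detection
#'
#' Fits the value-continuous piecewise regression
#' `y = b0 + b1 (t - 1986) + b2 max(t - 2000, 0)` over 1986-2012 (slope
#' discontinuity only, fixed at the break year).  The pre-break slope is
#' `b1`, the post-break slope `b1 + b2`, with ordinary-least-squares
#' t-intervals.  A series stagnates when the pre-break interval is entirely
#' positive (prior growth) and the lower post-break limit is negative (the
#' slope is no longer significantly positive) - a plateau after a period of
#' growth.
#'
#' @param years observation years.
#' @param values yield (or other) series.
#' @param break_year slope break (default 2000).
#' @param start_year series start anchoring `b1` (default 1986).
#' @param end_year last year considered (default 2012).
#' @param level confidence level of the slope intervals.
#' @param min_side minimum years required on each side of the break.
#' @return object of class `yg_stagnation`: pre/post slopes with intervals,
#'   `stagnant` flag and `indeterminate` flag.
#' @export
piecewise_stagnation <- function(years, values, break_year = 2000,
                                 start_year = 1986, end_year = 2012,
                                 level = 0.95, min_side = 10) {
  keep <- is.finite(values) & years >= start_year & years <= end_year
  years <- years[keep]; values <- values[keep]
  res <- structure(list(pre_slope = NA_real_, pre_ci = c(NA_real_, NA_real_),
                        post_slope = NA_real_, post_ci = c(NA_real_, NA_real_),
                        stagnant = NA, indeterminate = TRUE, level = level),
                   class = "yg_stagnation")
  if (sum(years <= break_year) < min_side ||
      sum(years >= break_year) < min_side) return(res)
  t1 <- years - start_year
  t2 <- pmax(years - break_year, 0)
  fit <- stats::lm(values ~ t1 + t2)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$df.residual)
  pre <- cf[["t1"]]
  pre_se <- sqrt(V["t1", "t1"])
  post <- cf[["t1"]] + cf[["t2"]]
  post_se <- sqrt(V["t1", "t1"] + V["t2", "t2"] + 2 * V["t1", "t2"])
  res$pre_slope <- pre
  res$pre_ci <- pre + c(-1, 1) * tq * pre_se
  res$post_slope <- post
  res$post_ci <- post + c(-1, 1) * tq * post_se
  res$indeterminate <- FALSE
  res$stagnant <- res$pre_ci[1] > 0 && res$post_ci[1] < 0
  res
}

#' @export
print.yg_stagnation <- function(x, ...) {
  if (x$indeterminate) {
    cat("Stagnation test: indeterminate (insufficient years)\n")
  } else {
    cat(sprintf("Stagnation test: pre-break slope %.4f [%.4f, %.4f], post-break %.4f [%.4f, %.4f] -> %s\n",
                x$pre_slope, x$pre_ci[1], x$pre_ci[2],
                x$post_slope, x$post_ci[1], x$post_ci[2],
                if (isTRUE(x$stagnant)) "STAGNANT" else "not stagnant"))
  }
  invisible(x)
}

#' Classify units into yield-gap typologies
#'
#' Decision cascade over the significance calls of the ceiling (attainable),
#' floor (actual) and gap trends of each unit: `ceiling_pressure` when the
#' gap is significantly decreasing or the ceiling is not significantly
#' increasing; otherwise `stalled_floor` when the floor is not significantly
#' increasing; otherwise `steady_growth`.  The cascade is exhaustive and
#' mutually exclusive over units with determinate trends; units with any
#' indeterminate call are excluded (label `NA`).
#'
#' @param ceiling_sig,floor_sig,gap_sig significance calls
#'   (`"positive"`/`"negative"`/`"none"`, `NA` = indeterminate), vectorized
#'   over units.
#' @return character vector of labels.
#' @export
classify_typology <- function(ceiling_sig, floor_sig, gap_sig) {
  n <- length(gap_sig)
  stopifnot(length(ceiling_sig) == n, length(floor_sig) == n)
  out <- rep(NA_character_, n)
  det <- !is.na(ceiling_sig) & !is.na(floor_sig) & !is.na(gap_sig)
  cp <- det & (gap_sig == "negative" | ceiling_sig != "positive")
  sf <- det & !cp & floor_sig != "positive"
  sg <- det & !cp & !sf
  out[cp] <- "ceiling_pressure"
  out[sf] <- "stalled_floor"
  out[sg] <- "steady_growth"
  out
}

#' Per-unit typology labels from a gap table
#'
#' Computes ceiling, floor and gap trends over the analysis window and
#' applies [classify_typology()].
#'
#' @param df long gap table.
#' @param years analysis window (default 1998-2012).
#' @param level confidence level.
#' @return `data.frame` with per-unit label and the three significance
#'   calls.
#' @export
typology_labels <- function(df, years = 1998:2012, level = 0.95) {
  trc <- unit_trends(df, "attainable", years = years, level = level)
  trf <- unit_trends(df, "actual", years = years, level = level)
  trg <- unit_trends(df, "gap", years = years, level = level)
  stopifnot(identical(trc$unit_id, trf$unit_id),
            identical(trc$unit_id, trg$unit_id))
  data.frame(unit_id = trc$unit_id,
             label = classify_typology(trc$sig, trf$sig, trg$sig),
             ceiling_sig = trc$sig, floor_sig = trf$sig, gap_sig = trg$sig,
             stringsAsFactors = FALSE)
}

#' Harvested-area shares per typology
#'
#' Allocates circa-reference-year harvested area to the three typology
#' labels; shares sum to 100% over labeled units.  Units with `NA` labels
#' are counted separately.
#'
#' @param labels `data.frame` from [typology_labels()] plus an `area`
#'   column (reference-year harvested area per unit).
#' @return `data.frame` with one row per label (all three always present),
#'   `area`, `share_pct`, plus an `unlabeled_area` attribute.
#' @export
typology_area_table <- function(labels) {
  if (!all(c("label", "area") %in% names(labels)))
    stop_yg("labels need 'label' and 'area' columns")
  lv <- c("steady_growth", "stalled_floor", "ceiling_pressure")
  lab <- factor(labels$label, levels = lv)
  tot <- tapply(labels$area, lab, sum, default = 0)
  tot[is.na(tot)] <- 0
  labeled <- sum(tot)
  share <- if (labeled > 0) 100 * tot / labeled else rep(0, length(lv))
  structure(data.frame(label = lv, area = as.numeric(tot),
                       share_pct = as.numeric(share),
                       stringsAsFactors = FALSE, row.names = NULL),
            unlabeled_area = sum(labels$area[is.na(labels$label)]))
}

#' Gap-closure to stagnation risk ratio
#'
#' Ratio of the stagnation probability among units whose yield gap was
#' significantly closing (with projected closure within the horizon) during
#' the conditioning window, to the stagnation probability among all other
#' units.  Also reports the reversion-to-the-mean controls restricted to the
#' third and top quartiles of prior yield growth.
#'
#' @param units `data.frame` with logical columns `closing` (significant
#'   gap closure projected within the horizon over the conditioning window)
#'   and `stagnant` (outcome-window stagnation flag) and numeric `growth`
#'   (prior yield growth rate used for the quartile control).
#' @return list with `ratio`, `counts` (2 x 2 table), `p_closing`,
#'   `p_other`, and quartile-restricted ratios `ratio_q3`, `ratio_top`.
#' @export
stagnation_risk_ratio <- function(units) {
  need <- c("closing", "stagnant")
  if (!all(need %in% names(units))) stop_yg("need closing and stagnant columns")
  u <- units[stats::complete.cases(units[need]), , drop = FALSE]
  counts <- table(closing = factor(u$closing, c(FALSE, TRUE)),
                  stagnant = factor(u$stagnant, c(FALSE, TRUE)))
  ratio_of <- function(d) {
    if (!nrow(d) || !any(d$closing) || !any(!d$closing)) return(NA_real_)
    p1 <- mean(d$stagnant[d$closing])
    p0 <- mean(d$stagnant[!d$closing])
    if (p0 == 0) {
      if (p1 == 0) return(0)
      return(Inf)
    }
    p1 / p0
  }
  ratio <- ratio_of(u)
  if (!is.na(ratio) && ratio == 0 && !any(u$stagnant))
    warn_yg("no stagnant units; ratio is 0")
  out <- list(ratio = ratio, counts = counts,
              p_closing = if (any(u$closing)) mean(u$stagnant[u$closing]) else NA_real_,
              p_other = if (any(!u$closing)) mean(u$stagnant[!u$closing]) else NA_real_,
              ratio_q3 = NA_real_, ratio_top = NA_real_)
  if ("growth" %in% names(units)) {
    g <- units$growth
    qs <- stats::quantile(g, c(0.5, 0.75), na.rm = TRUE)
    q3 <- u[!is.na(u$growth) & u$growth >= qs[1] & u$growth < qs[2], , drop = FALSE]
    top <- u[!is.na(u$growth) & u$growth >= qs[2], , drop = FALSE]
    out$ratio_q3 <- ratio_of(q3)
    out$ratio_top <- ratio_of(top)
  }
  out
}
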