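# Reading, validation, quality filtering and normalization of census-style
# yield tables.  One row = one (administrative unit, crop, year) observation
# of yield (t per harvested ha), harvested area (ha) and biophysical
# covariates.

#' Read a census yield table
#'
#' Reads the delimited-text census schema (comma separated, header row,
#' UTF-8): `unit_id, crop, year, yield_t_ha, area_ha, area_fraction` plus the
#' covariate columns `gdd, map, pci, irr, awc, soc, ph, slope30, vf`.
#' Covariates may instead live in a second table keyed by `unit_id`.
#'
#' @param path path to the census table.
#' @param covariate_path optional path to a covariate table keyed by
#'   `unit_id`; joined onto the records.
#' @return a validated `data.frame` of census records.
#' @export
read_census_table <- function(path, covariate_path = NULL) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(covariate_path)) {
    cov <- utils::read.csv(covariate_path, stringsAsFactors = FALSE)
    if (!"unit_id" %in% names(cov)) stop_yg("covariate table lacks unit_id")
    records <- merge(records, cov, by = "unit_id", sort = FALSE)
  }
  validate_census(records)
}

#' Validate a census record table
#'
#' Checks schema, non-negativity of yields and areas, covariate range
#' invariants and uniqueness of (unit_id, crop, year).
#'
#' @param records census record `data.frame`.
#' @return the validated records (invisibly unchanged).
#' @export
validate_census <- function(records) {
  missing <- setdiff(CENSUS_COLS, names(records))
  if (length(missing))
    stop_yg("census table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(records$yield_t_ha < 0, na.rm = TRUE)) stop_yg("negative yields")
  if (any(records$area_ha < 0, na.rm = TRUE)) stop_yg("negative harvested areas")
  key <- paste(records$unit_id, records$crop, records$year)
  if (anyDuplicated(key))
    stop_yg("duplicated (unit_id, crop, year) keys")
  if ("irr" %in% names(records) &&
      any(records$irr < 0 | records$irr > 1, na.rm = TRUE))
    stop_yg("irr outside [0, 1]")
  if ("slope30" %in% names(records) &&
      any(records$slope30 < 0 | records$slope30 > 1, na.rm = TRUE))
    stop_yg("slope30 outside [0, 1]")
  if ("vf" %in% names(records) && !all(records$vf %in% c(0, 1)))
    stop_yg("vf must be binary")
  records
}

#' Quality-filter census records
#'
#' Applies, within each (crop, year) group, the two census quality rules:
#' records whose harvested-area fraction exceeds 3 (multicropping index above
#' 300%) are rejected, and records whose yield exceeds the area-weighted
#' 97.5th-percentile yield of the group plus twice the (unweighted) sample
#' standard deviation of the group's yields are rejected.  The percentile uses
#' the left-continuous weighted empirical CDF with ties broken by yield then
#' `unit_id`.
#'
#'
#' @param records census record `data.frame` (validated schema).
#' @param max_multicropping rejection threshold on `area_fraction`.
#' @param pctl percentile of the yield screen.
#' @param sd_mult multiplier of the yield standard deviation.
#' @return list with `kept` (records plus `qc_flag`/`qc_reason` columns,
#'   rejected rows removed) and `rejected` (the rejection log).
#' @export
qc_filter <- function(records, max_multicropping = 3,
                      pctl = 0.975, sd_mult = 2) {
  validate_census(records)
  if (any(is.na(records$area_ha))) stop_yg("missing area weights")
  grp <- interaction(records$crop, records$year, drop = TRUE)
  reason <- rep(NA_character_, nrow(records))

  mc_bad <- !is.na(records$area_fraction) &
    records$area_fraction > max_multicropping
  reason[mc_bad] <- sprintf("multicropping > %g", max_multicropping)

  for (g in levels(grp)) {
    idx <- which(grp == g & !mc_bad)
    if (!length(idx)) {
      warn_yg("empty crop-year group after multicropping screen: %s", g)
      next
    }
    yv <- records$yield_t_ha[idx]
    av <- records$area_ha[idx]
    if (sum(av) <= 0) stop_yg("missing area weights in group %s", g)
    thr <- weighted_quantile_area(yv, av, pctl, id = records$unit_id[idx]) +
      sd_mult * (if (length(yv) > 1) stats::sd(yv) else 0)
    out <- idx[yv > thr]
    reason[out] <- sprintf("yield > weighted %g pctl + %g sd", pctl, sd_mult)
  }

  bad <- !is.na(reason)
  kept <- records[!bad, , drop = FALSE]
  kept$qc_flag <- rep("pass", nrow(kept))
  kept$qc_reason <- rep("", nrow(kept))
  rejected <- records[bad, , drop = FALSE]
  rejected$qc_flag <- rep("reject", nrow(rejected))
  rejected$qc_reason <- reason[bad]
  list(kept = kept, rejected = rejected)
}

#' Aggregate sub-records to one unit record
#'
#' Collapses sub-elements (e.g. grid cells or nested reports) into a single
#' per-unit row: every numeric field becomes the harvested-area-weighted mean
#' of the sub-elements, and the total harvested area is their sum.
#'
#' @param sub `data.frame` of sub-elements including `area_ha`.
#' @param value_cols columns to average; defaults to all numeric columns
#'   except the area itself.
#' @return one-row `data.frame`.
#' @export
aggregate_to_unit <- function(sub, value_cols = NULL) {
  if (!"area_ha" %in% names(sub)) stop_yg("sub-records need area_ha")
  w <- sub$area_ha
  if (any(w < 0)) stop_yg("negative weights")
  if (sum(w) <= 0) stop_yg("no harvested area")
  if (is.null(value_cols)) {
    value_cols <- names(sub)[vapply(sub, is.numeric, logical(1))]
    value_cols <- setdiff(value_cols, "area_ha")
  }
  out <- sub[1, , drop = FALSE]
  for (v in value_cols) out[[v]] <- weighted_mean_area(sub[[v]], w)
  out$area_ha <- sum(w)
  rownames(out) <- NULL
  out
}

#' Compute normalization factors for z-scoring
#'
#' Means and population standard deviations (denominator `n`) of the given
#' columns, pooled over all rows.  One factor set per crop keeps annual
#' coefficient trajectories comparable across years.
#'
#' @param data `data.frame` of quality-passed records.
#' @param vars columns to normalize.
#' @return `data.frame` with columns `var`, `mean`, `sd`
#'   (class `yg_factors`).
#' @export
normalization_factors <- function(data, vars) {
  missing <- setdiff(vars, names(data))
  if (length(missing))
    stop_yg("missing covariate column(s): %s", paste(missing, collapse = ", "))
  mu <- vapply(vars, function(v) mean(data[[v]]), numeric(1))
  n <- nrow(data)
  sdv <- vapply(vars, function(v) {
    sqrt(sum((data[[v]] - mean(data[[v]]))^2) / n)
  }, numeric(1))
  zero <- vars[sdv <= 0]
  if (length(zero))
    stop_yg("zero-variance covariate(s): %s", paste(zero, collapse = ", "))
  structure(data.frame(var = vars, mean = mu, sd = sdv,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("yg_factors", "data.frame"))
}

#' Apply (or invert) z-score normalization
#'
#' @param data `data.frame` containing the factor columns.
#' @param factors a [normalization_factors()] table.
#' @param invert if `TRUE`, map z-scores back to physical units.
#' @return `data.frame` with transformed columns.
#' @export
apply_zscore <- function(data, factors, invert = FALSE) {
  for (i in seq_len(nrow(factors))) {
    v <- factors$var[i]
    if (!v %in% names(data)) stop_yg("missing covariate column: %s", v)
    data[[v]] <- if (invert) data[[v]] * factors$sd[i] + factors$mean[i]
    else (data[[v]] - factors$mean[i]) / factors$sd[i]
  }
  data
}

#' @export
print.yg_factors <- function(x, ...) {
  cat("Normalization factors (", nrow(x), " variables)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
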