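# Derivation of biophysical covariates from monthly climate and irrigation
# inputs: growing degree days (GDD), mean annual precipitation (MAP),
# precipitation concentration index (PCI), binary vernalization factor (VF)
# and the time-scaled irrigated fraction (IRR).

#' Growing degree days from monthly mean temperatures
#'
#' `GDD = sum_m max(Tbar_m, 0) * days_m` with base temperature 0 degC,
#' computed from a monthly climatology (no daily interpolation).
#'
#' @param tmean twelve monthly mean temperatures (degC).
#' @param days days per month (default: climatological non-leap year).
#' @return degree-days (degC day), non-negative.
#' @export
compute_gdd <- function(tmean, days = DAYS_PER_MONTH) {
  if (length(tmean) != 12L || anyNA(tmean)) stop_yg("need 12 monthly temperatures")
  if (length(days) != 12L) stop_yg("need 12 month lengths")
  sum(pmax(tmean, 0) * days)
}

#' Precipitation concentration index
#'
#' Oliver's annual index `PCI = 100 * sum(p^2) / (sum p)^2`, bounded between
#' 100/12 (uniform rainfall) and 100 (all rain in one month).
#'
#' @param precip twelve monthly precipitation totals (mm), non-negative.
#' @return index in `[100/12, 100]`.
#' @export
compute_pci <- function(precip) {
  if (length(precip) != 12L || anyNA(precip)) stop_yg("need 12 monthly totals")
  if (any(precip < 0)) stop_yg("negative precipitation")
  tot <- sum(precip)
  if (tot <= 0) stop_yg("PCI undefined: all-zero precipitation")
  100 * sum(precip^2) / tot^2
}

#' Binary vernalization factor
#'
#' Indicator of winter chill used for wheat.  Two conventions are offered:
#' `"interval"` (default) scores 1 when the coldest monthly mean lies in the
#' closed interval `[-8, 5]` degC; `"lte8"` scores 1 when the coldest monthly
#' mean is at most 8 degC.
#'
#' @param tmean twelve monthly mean temperatures (degC).
#' @param convention `"interval"` or `"lte8"`.
#' @return 0 or 1.
#' @export
compute_vf <- function(tmean, convention = c("interval", "lte8")) {
  if (length(tmean) != 12L || anyNA(tmean)) stop_yg("need 12 monthly temperatures")
  convention <- match.arg(convention)
  coldest <- min(tmean)
  if (convention == "interval") as.integer(coldest >= -8 && coldest <= 5)
  else as.integer(coldest <= 8)
}

#' Time-scaled irrigated fraction
#'
#' Scales a base-year irrigated fraction by the ratio of area equipped for
#' irrigation (AEI): `IRR(year) = clamp(IRR0 * AEI(year) / AEI(base), 0, 1)`.
#' Years between AEI observations are linearly interpolated; years past the
#' last observation are linearly extrapolated from the last two observations
#' (years before the first, from the first two).
#'
#' @param irr0 base-year irrigated fraction in `[0, 1]`.
#' @param aei_years years with AEI observations (sorted or not).
#' @param aei_values AEI values (>= 0), same length as `aei_years`.
#' @param base_year year to which `irr0` refers; must have an AEI value.
#' @param year target year(s).
#' @return irrigated fraction(s) in `[0, 1]`.
#' @export
scale_irrigation <- function(irr0, aei_years, aei_values, base_year, year) {
  if (irr0 < 0 || irr0 > 1) stop_yg("irr0 outside [0, 1]")
  if (length(aei_years) != length(aei_values)) stop_yg("AEI length mismatch")
  if (any(aei_values < 0)) stop_yg("negative AEI")
  ord <- order(aei_years)
  ay <- aei_years[ord]; av <- aei_values[ord]
  if (!base_year %in% ay) stop_yg("no AEI observation for the base year")
  base <- av[match(base_year, ay)]
  if (base == 0) {
    if (irr0 > 0) stop_yg("AEI(base) = 0 with positive irr0")
    return(rep(0, length(year)))
  }
  aei_at <- function(yr) {
    if (length(ay) == 1L) return(av)
    if (yr <= ay[1L]) {
      slope <- (av[2L] - av[1L]) / (ay[2L] - ay[1L])
      return(av[1L] + slope * (yr - ay[1L]))
    }
    k <- length(ay)
    if (yr >= ay[k]) {
      slope <- (av[k] - av[k - 1L]) / (ay[k] - ay[k - 1L])
      return(av[k] + slope * (yr - ay[k]))
    }
    stats::approx(ay, av, xout = yr)$y
  }
  out <- vapply(year, function(yr) irr0 * aei_at(yr) / base, numeric(1))
  pmin(pmax(out, 0), 1)
}

#' Derive climate covariates for a table of units
#'
#' Expands a monthly climate table (columns `unit_id`, `t01..t12`,
#' `p01..p12`) into the model covariates `gdd`, `map`, `pci` and `vf`.
#'
#' @param climate monthly climate `data.frame`.
#' @param vf_convention passed to [compute_vf()].
#' @return `data.frame` with `unit_id, gdd, map, pci, vf`.
#' @export
derive_climate_covariates <- function(climate,
                                      vf_convention = c("interval", "lte8")) {
  vf_convention <- match.arg(vf_convention)
  tcols <- sprintf("t%02d", 1:12)
  pcols <- sprintf("p%02d", 1:12)
  missing <- setdiff(c("unit_id", tcols, pcols), names(climate))
  if (length(missing))
    stop_yg("climate table lacks column(s): %s", paste(missing, collapse = ", "))
  tm <- as.matrix(climate[tcols])
  pm <- as.matrix(climate[pcols])
  data.frame(
    unit_id = climate$unit_id,
    gdd = apply(tm, 1, compute_gdd),
    map = rowSums(pm),
    pci = apply(pm, 1, compute_pci),
    vf = apply(tm, 1, compute_vf, convention = vf_convention),
    stringsAsFactors = FALSE
  )
}
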