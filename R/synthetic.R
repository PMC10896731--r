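# Synthetic census-panel generator with known ground truth.  Emulates the
# statistical geometry the attainable-yield model assumes: covariate-driven
# yield ceilings, attainment fractions placing about 5% of harvested area
# strictly above the ceiling, heavy-tailed harvested areas, and
# scenario-controlled ceiling/floor trajectories per unit.

SCENARIOS <- c("steady_growth", "stalled_floor",
               "ceiling_pressure_gapclose", "ceiling_pressure_flatceiling")

#' Configure a synthetic census scenario
#'
#' Defaults describe the study conditions the pipeline is validated under:
#' a 1973-2012 panel, ceilings growing about 1% per year of their year-2000
#' level, a 5% exceeder mechanism so the area-weighted 95th percentile of
#' yield equals the ceiling, log-normal (heavy-tailed) harvested areas, and
#' per-unit attainment fractions drawn from a Beta distribution.
#'
#' @param n_units number of administrative units (>= 1).
#' @param years inclusive year range of the panel.
#' @param seed master integer seed; identical seed and config give
#'   byte-identical output.
#' @param crop crop archetype name (`"wheat"` draws a vernalization factor).
#' @param scenario either a single scenario name applied to all units, a
#'   named vector of mixing proportions over
#'   `steady_growth`, `stalled_floor`, `ceiling_pressure_gapclose`,
#'   `ceiling_pressure_flatceiling`, or a length-`n_units` label vector.
#' @param beta named true coefficient vector of the ceiling surface on
#'   z-scored covariates (units t/ha); names are model terms.
#' @param growth_rate per-year ceiling growth as a fraction of the year-2000
#'   level.
#' @param p_exceed probability a record lies strictly above the ceiling.
#' @param exceed_max upper bound of the exceeder multiplier
#'   (`Uniform(1, exceed_max)`).
#' @param attain_shape `c(alpha, beta)` of the per-unit attainment Beta
#'   distribution; a non-positive `beta` degenerates to full attainment.
#' @param noise_sd log-scale s.d. of the multiplicative year-to-year
#'   attainment noise.
#' @param area_meanlog,area_sdlog log-normal parameters of harvested areas
#'   (ha).
#' @param floor_min smallest admissible ceiling (t/ha).
#' @param gapclose_target attainment level approached by gap-closing units.
#' @return object of class `yg_scenario_config`.
#' @export
scenario_config <- function(n_units = 500, years = 1973:2012, seed = 1,
                            crop = "maize", scenario = "steady_growth",
                            beta = c("1" = 6, GDD = 1.2, MAP = 0.8,
                                     IRR = 0.9, "IRR:MAP" = 0.3),
                            growth_rate = 0.01, p_exceed = 0.05,
                            exceed_max = 1.1, attain_shape = c(4, 1.6),
                            noise_sd = 0.03, area_meanlog = 7,
                            area_sdlog = 1.5, floor_min = 0.1,
                            gapclose_target = 0.92) {
  if (n_units < 1) stop_yg("n_units must be >= 1")
  if (p_exceed < 0 || p_exceed >= 1) stop_yg("p_exceed outside [0, 1)")
  if (is.null(names(beta)) || !"1" %in% names(beta))
    stop_yg("beta must be named and include the intercept '1'")
  if (length(scenario) == 1L && is.null(names(scenario))) {
    if (!scenario %in% SCENARIOS) stop_yg("unknown scenario '%s'", scenario)
  } else if (!is.null(names(scenario))) {
    if (!all(names(scenario) %in% SCENARIOS)) stop_yg("unknown scenario name")
    if (any(scenario < 0) || sum(scenario) <= 0) stop_yg("infeasible scenario mix")
  } else if (length(scenario) != n_units || !all(scenario %in% SCENARIOS)) {
    stop_yg("scenario must name proportions or label every unit")
  }
  structure(list(n_units = as.integer(n_units), years = as.integer(years),
                 seed = as.integer(seed), crop = crop, scenario = scenario,
                 beta = beta, growth_rate = growth_rate, p_exceed = p_exceed,
                 exceed_max = exceed_max, attain_shape = attain_shape,
                 noise_sd = noise_sd, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, floor_min = floor_min,
                 gapclose_target = gapclose_target),
            class = "yg_scenario_config")
}

assign_scenarios <- function(config) {
  n <- config$n_units
  sc <- config$scenario
  if (length(sc) == n && is.null(names(sc)) && n > 1) return(sc)
  if (length(sc) == 1L && is.null(names(sc))) return(rep(sc, n))
  prop <- sc / sum(sc)
  counts <- floor(prop * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- prop * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  labels <- rep(names(sc), counts)
  labels[sample.int(n)]  # deterministic under the generator's seed
}

#' Generate a synthetic census panel
#'
#' Draws per-unit biophysical covariates from documented ranges, builds the
#' true attainable-yield ceiling as the design matrix times the true
#' coefficient trajectory (floored at a small positive value), and produces
#' actual yields as ceiling times a per-unit attainment path controlled by
#' the unit's scenario, with multiplicative noise capped at the ceiling and a
#' Bernoulli exceeder mechanism lifting about `p_exceed` of the area strictly
#' above the ceiling.  Harvested areas are log-normal and static per unit.
#'
#' Scenario trajectories: `steady_growth` keeps attainment constant while
#' the ceiling grows (ceiling, floor and gap all grow); `stalled_floor`
#' freezes the floor at its first-year level under a growing ceiling;
#' `ceiling_pressure_gapclose` ramps attainment towards `gapclose_target`
#' (gap closes); `ceiling_pressure_flatceiling` holds the ceiling flat.
#'
#' @param config a [scenario_config()].
#' @return object of class `yg_panel`: list with `records` (full ingest
#'   schema plus covariates), `covariates` (per-unit table), and `truth`
#'   (per unit-year true attainable, attainment, exceeder flag and scenario),
#'   with attributes `beta_z` (true per-year coefficients, z-covariate/raw
#'   response space, valid for units without flat-ceiling modifier),
#'   `factors` (the generator's covariate normalization factors) and
#'   `unit_slopes` (per-unit true ceiling/floor/gap slopes in t/ha per
#'   year).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "yg_scenario_config"))
  set.seed(derive_seed(config$seed, "panel"))
  n <- config$n_units
  years <- config$years
  ny <- length(years)

  cov <- data.frame(
    unit_id = sprintf("U%05d", seq_len(n)),
    gdd = stats::runif(n, 1000, 9000),
    map = stats::runif(n, 200, 3200),
    pci = stats::runif(n, 9, 70),
    irr = stats::rbeta(n, 0.8, 2.5),
    awc = stats::runif(n, 5, 25),
    soc = stats::runif(n, 1, 12),
    ph = stats::runif(n, 4.5, 8.5),
    slope30 = stats::rbeta(n, 0.5, 8),
    vf = if (identical(tolower(config$crop), "wheat"))
      stats::rbinom(n, 1, 0.4) else rep(0L, n),
    stringsAsFactors = FALSE
  )

  spec <- model_spec(names(config$beta))
  vars <- tolower(term_vars(spec$terms))
  # internal z-scoring tolerates degenerate draws (e.g. a single unit):
  # a constant covariate contributes z = 0, so the ceiling falls back to
  # the intercept
  mu <- vapply(vars, function(v) mean(cov[[v]]), numeric(1))
  sdv <- vapply(vars, function(v) {
    s <- sqrt(sum((cov[[v]] - mean(cov[[v]]))^2) / nrow(cov))
    if (s > 0) s else 1
  }, numeric(1))
  factors <- structure(data.frame(var = vars, mean = mu, sd = sdv,
                                  stringsAsFactors = FALSE,
                                  row.names = NULL),
                       class = c("yg_factors", "data.frame"))
  X <- build_design(cov, spec, factors)
  base <- pmax(drop(X %*% config$beta[spec$terms]), config$floor_min)

  scen <- assign_scenarios(config)
  flat <- scen == "ceiling_pressure_flatceiling"
  g <- 1 + config$growth_rate * (years - 2000)        # ceiling time factor
  if (any(g <= 0)) stop_yg("infeasible growth rate for the year range")

  # attain_shape[2] <= 0 degenerates to full attainment (actual == ceiling
  # when noise and exceedance are switched off)
  att0 <- if (config$attain_shape[2] <= 0) rep(1, n)
  else stats::rbeta(n, config$attain_shape[1], config$attain_shape[2])
  gc <- scen == "ceiling_pressure_gapclose"
  att0[gc] <- 0.35 + 0.3 * att0[gc]                    # start below target
  area <- stats::rlnorm(n, config$area_meanlog, config$area_sdlog)
  area_frac <- stats::runif(n, 0.1, 1.5)

  ceiling <- outer(base, rep(1, ny))
  ceiling[!flat, ] <- base[!flat] %o% g
  ceiling <- pmax(ceiling, config$floor_min)

  ramp <- (years - years[1]) / max(ny - 1, 1)
  att_path <- matrix(att0, n, ny)
  att_path[gc, ] <- att0[gc] %o% (1 - ramp) +
    rep(config$gapclose_target, sum(gc)) %o% ramp
  sf <- scen == "stalled_floor"
  # stalled floor: actual frozen at its first-year level
  att_path[sf, ] <- (att0[sf] * ceiling[sf, 1]) / ceiling[sf, , drop = FALSE]

  noise <- matrix(exp(stats::rnorm(n * ny, 0, config$noise_sd)), n, ny)
  att_real <- pmin(att_path * noise, 1)
  # exceedance is a unit property: "frontier" units run at or above the
  # ceiling, so each year's cross-section has ~p_exceed of area strictly
  # above the surface without injecting spikes into unit time series
  exceed_unit <- stats::runif(n) < config$p_exceed
  mult <- matrix(stats::runif(n * ny, 1, config$exceed_max), n, ny)
  att_real[exceed_unit, ] <- mult[exceed_unit, , drop = FALSE]
  exceed <- matrix(exceed_unit, n, ny)
  actual <- att_real * ceiling

  records <- data.frame(
    unit_id = rep(cov$unit_id, ny),
    crop = config$crop,
    year = rep(years, each = n),
    yield_t_ha = as.vector(actual),
    area_ha = rep(area, ny),
    area_fraction = rep(area_frac, ny),
    stringsAsFactors = FALSE
  )
  records <- cbind(records, cov[rep(seq_len(n), ny), -1, drop = FALSE])
  rownames(records) <- NULL

  truth <- data.frame(
    unit_id = rep(cov$unit_id, ny),
    year = rep(years, each = n),
    attainable = as.vector(ceiling),
    attainment = as.vector(att_real),
    exceeder = as.vector(exceed),
    scenario = rep(scen, ny),
    stringsAsFactors = FALSE
  )

  span <- max(ny - 1, 1)
  ceil_slope <- (ceiling[, ny] - ceiling[, 1]) / span
  floor_true <- att_path * ceiling
  floor_slope <- (floor_true[, ny] - floor_true[, 1]) / span
  gap_slope <- ceil_slope - floor_slope
  unit_slopes <- data.frame(unit_id = cov$unit_id, scenario = scen,
                            area_ha = area,
                            ceiling_slope = ceil_slope,
                            floor_slope = floor_slope,
                            gap_slope = gap_slope,
                            stringsAsFactors = FALSE)

  beta_z <- outer(config$beta[spec$terms], g)
  rownames(beta_z) <- spec$terms
  colnames(beta_z) <- years

  structure(list(records = records, covariates = cov, truth = truth),
            class = "yg_panel",
            beta_z = beta_z, factors = factors, spec = spec,
            unit_slopes = unit_slopes, config = config)
}

#' @export
print.yg_panel <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Synthetic census panel: %d units x %d years (%s), crop %s\n",
              cfg$n_units, length(cfg$years), paste(range(cfg$years),
                                                    collapse = "-"),
              cfg$crop))
  cat("  scenarios:", paste(names(table(attr(x, "unit_slopes")$scenario)),
                            table(attr(x, "unit_slopes")$scenario),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Inject a decoy covariate
#'
#' Adds a standard-normal covariate statistically independent of yield (true
#' coefficient zero) to a generated panel, as a test surface for model
#' selection.
#'
#' @param panel a `yg_panel`.
#' @param seed integer seed for the decoy draw.
#' @param name column name of the decoy (model term is its upper-case).
#' @return the panel with the decoy column added to `records` and
#'   `covariates` and a `decoy` attribute recording the zero true effect.
#' @export
inject_decoy_covariate <- function(panel, seed = 1, name = "decoy") {
  stopifnot(inherits(panel, "yg_panel"))
  if (name %in% names(panel$covariates)) stop_yg("column '%s' exists", name)
  set.seed(derive_seed(seed, "decoy", name))
  vals <- stats::rnorm(nrow(panel$covariates))
  panel$covariates[[name]] <- vals
  panel$records[[name]] <- vals[match(panel$records$unit_id,
                                      panel$covariates$unit_id)]
  attr(panel, "decoy") <- list(name = name, beta = 0)
  panel
}
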