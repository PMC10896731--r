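# Model specification, design construction, the area-weighted check loss and
# its calibration penalty, per-year fitting and prediction of attainable
# yields.

# canonical covariate symbols usable in model terms, mapped to table columns
term_symbols <- function(extra = character()) {
  c("GDD", "MAP", "PCI", "IRR", "AWC", "SOC", "PH", "SLOPE30", "VF", "t",
    extra)
}

parse_term <- function(term) {
  if (term == "1") return(list())
  parts <- strsplit(term, ":", fixed = TRUE)[[1L]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Za-z][A-Za-z0-9_]*)(\\^([0-9]+))?$", p))[[1L]]
    if (!length(m)) stop_yg("cannot parse model term '%s'", term)
    list(var = m[2L], power = if (nzchar(m[4L])) as.integer(m[4L]) else 1L)
  })
}

term_vars <- function(terms) {
  unique(unlist(lapply(terms, function(tm)
    vapply(parse_term(tm), `[[`, character(1), "var"))))
}

#' Construct a model specification
#'
#' A `yg_spec` is an ordered set of regression terms, each a product of
#' (powers of) covariates, e.g. `"GDD"`, `"GDD^2"`, `"GDD:MAP"`, `"t"`,
#' `"t^2"`.  The intercept `"1"` is always present (prepended if missing).
#' Protected terms are never removed by pruning or model selection.
#'
#' @param terms character vector of term labels.
#' @param protected terms protected from removal (besides the intercept).
#' @return object of class `yg_spec`.
#' @export
model_spec <- function(terms, protected = c("IRR", "IRR:MAP")) {
  terms <- as.character(terms)
  if (!"1" %in% terms) terms <- c("1", terms)
  if (anyDuplicated(terms)) stop_yg("duplicate model terms")
  lapply(terms, parse_term)  # validates syntax
  structure(list(terms = terms,
                 protected = intersect(protected, terms)),
            class = "yg_spec")
}

#' Starting model specification for a crop archetype
#'
#' The physically motivated starting term set: quadratic climate response in
#' degree days and precipitation with their interaction, precipitation
#' concentration and its precipitation cross term, irrigation and its
#' precipitation and concentration cross terms, and the soil terms.  The
#' wheat archetype adds the vernalization factor and its climate cross
#' terms.  Optionally appends linear and quadratic time terms (used during
#' model selection and stripped before annual fitting).
#'
#' @param crop crop name; `"wheat"` selects the vernalization variant.
#' @param time_terms append `"t"` and `"t^2"`.
#' @return a [model_spec()].
#' @export
base_spec <- function(crop = "maize", time_terms = FALSE) {
  terms <- c("GDD", "MAP", "GDD^2", "MAP^2", "GDD:MAP",
             "PCI", "PCI:MAP", "IRR", "IRR:MAP", "IRR:PCI",
             "AWC", "SOC", "SLOPE30", "PH")
  if (identical(tolower(crop), "wheat"))
    terms <- c(terms, "VF", "VF:GDD", "VF:MAP")
  protected <- c("IRR", "IRR:MAP")
  if (time_terms) {
    terms <- c(terms, "t", "t^2")
    protected <- c(protected, "t", "t^2")
  }
  model_spec(terms, protected = protected)
}

#' Remove time terms from a specification
#'
#' Drops `t` and `t^2` (any pure power of `t`), preserving the order of all
#' other terms.  Applied after temporal model selection, before per-year
#' coefficient fitting.
#'
#' @param spec a [model_spec()].
#' @return a [model_spec()] without time terms.
#' @export
strip_time_terms <- function(spec) {
  stopifnot(inherits(spec, "yg_spec"))
  is_time <- vapply(spec$terms, function(tm) {
    p <- parse_term(tm)
    length(p) > 0 && all(vapply(p, `[[`, character(1), "var") == "t")
  }, logical(1))
  model_spec(spec$terms[!is_time],
             protected = setdiff(spec$protected, spec$terms[is_time]))
}

#' @export
print.yg_spec <- function(x, ...) {
  cat("Quantile-surface model: Y ~", paste(x$terms, collapse = " + "), "\n")
  if (length(x$protected))
    cat("  protected:", paste(x$protected, collapse = ", "), "\n")
  invisible(x)
}

#' Build a design matrix of model terms
#'
#' Evaluates each term of `spec` on z-scored covariates.  Covariate columns
#' are looked up in `data` by the lower-cased term symbol (`GDD` -> `gdd`,
#' `t` -> `t`); products and powers are computed after z-scoring.
#'
#' @param data `data.frame` of records in physical units.
#' @param spec a [model_spec()].
#' @param factors [normalization_factors()] for every covariate used by
#'   `spec`; if `NULL` the data are assumed already z-scored.
#' @return numeric matrix, one column per term, in spec order.
#' @export
build_design <- function(data, spec, factors = NULL) {
  stopifnot(inherits(spec, "yg_spec"))
  vars <- term_vars(spec$terms)
  cols <- tolower(vars)
  missing <- cols[!cols %in% names(data)]
  if (length(missing))
    stop_yg("missing covariate column(s): %s", paste(missing, collapse = ", "))
  z <- data[cols]
  names(z) <- cols
  if (!is.null(factors)) {
    fsub <- factors[factors$var %in% cols, , drop = FALSE]
    lost <- setdiff(cols, fsub$var)
    if (length(lost))
      stop_yg("no normalization factors for: %s", paste(lost, collapse = ", "))
    z <- apply_zscore(z, fsub)
  }
  n <- nrow(data)
  out <- matrix(NA_real_, n, length(spec$terms),
                dimnames = list(NULL, spec$terms))
  for (j in seq_along(spec$terms)) {
    parts <- parse_term(spec$terms[j])
    col <- rep(1, n)
    for (p in parts) col <- col * z[[tolower(p$var)]]^p$power
    out[, j] <- col
  }
  out
}

#' Area-weighted check (pinball) loss
#'
#' `LF = sum_i w_i |y_i - q_i| a_i / sum_i a_i` with `w_i = tau` where the
#' observation lies above the surface (`y_i > q_i`) and `1 - tau` on or below
#' it.  Scale-invariant in the areas.
#'
#' @param y observed yields.
#' @param q surface predictions.
#' @param a harvested-area weights; `sum(a) > 0`.
#' @param tau quantile level.
#' @return non-negative scalar loss.
#' @export
quantile_loss <- function(y, q, a, tau = 0.95) {
  if (length(y) != length(q) || length(y) != length(a))
    stop_yg("y, q, a must have equal length")
  if (sum(a) <= 0) stop_yg("no harvested area")
  w <- ifelse(y > q, tau, 1 - tau)
  sum(w * abs(y - q) * a) / sum(a)
}

#' Calibration penalty on the under-surface area share
#'
#' `lambda = sd_y * sum_i(a_i) * | sum_j(a_j)/sum(a) - tau |`, where `j`
#' indexes records strictly below the surface (`q_j > y_j`).  Zero exactly
#' when the area-weighted under-surface share equals `tau`.
#'
#' @param y observed yields.
#' @param q surface predictions.
#' @param a harvested-area weights; `sum(a) > 0`.
#' @param tau quantile level.
#' @param sd_y standard deviation of the response (sample s.d. of the
#'   fit-year yields).
#' @return non-negative penalty (scales with total area).
#' @export
lambda_penalty <- function(y, q, a, tau = 0.95, sd_y) {
  if (length(y) != length(q) || length(y) != length(a))
    stop_yg("y, q, a must have equal length")
  sa <- sum(a)
  if (sa <= 0) stop_yg("no harvested area")
  frac_under <- sum(a[q > y]) / sa
  sd_y * sa * abs(frac_under - tau)
}

# area-weighted share of records on or below the surface (ties count below)
fraction_below <- function(y, q, a) sum(a[y <= q]) / sum(a)

#' Fit the attainable-yield quantile surface for one data slice
#'
#' Minimizes the area-weighted check loss exactly by linear programming
#' (interior point).  On the regularized path the intercept is then
#' recalibrated so that the area-weighted share of records on or below the
#' surface is as close as possible to `tau` (the share is a non-decreasing
#' step function of the intercept, so the optimum is the weighted
#' `tau`-quantile of the residuals); the recalibrated solution is kept only
#' if it does not worsen the combined loss-plus-penalty objective.
#'
#' @param X design matrix from [build_design()]; must contain the intercept
#'   column `"1"` for the regularized path.
#' @param y response vector (same space as the design, typically z-scored).
#' @param a harvested-area weights.
#' @param tau quantile level.
#' @param regularized apply the calibration step.
#' @param sd_y response standard deviation used in the penalty; defaults to
#'   the sample s.d. of `y`.
#' @return object of class `yg_fit` with elements `coefficients`, `tau`,
#'   `loss` (check loss), `lambda`, `objective`, `fraction_below`
#'   (area-weighted share on/below the surface) and `converged`.
#' @export
fit_quantile <- function(X, y, a, tau = 0.95, regularized = TRUE,
                         sd_y = stats::sd(y)) {
  X <- as.matrix(X)
  if (nrow(X) < ncol(X)) stop_yg("fewer rows than coefficients")
  sol <- rq_fit_ip(X, y, tau = tau, weights = a)
  if (!sol$converged)
    stop_yg("quantile fit did not converge (gap %.3g)", sol$gap)
  beta <- sol$coefficients
  q0 <- drop(X %*% beta)

  mk <- function(beta, q) {
    lf <- quantile_loss(y, q, a, tau)
    lam <- lambda_penalty(y, q, a, tau, sd_y)
    structure(list(coefficients = beta, tau = tau, loss = lf, lambda = lam,
                   objective = lf + lam,
                   fraction_below = fraction_below(y, q, a),
                   converged = TRUE),
              class = "yg_fit")
  }
  fit0 <- mk(beta, q0)
  if (!regularized) return(fit0)

  ic <- match("1", colnames(X))
  if (is.na(ic)) stop_yg("regularized path needs an intercept term")
  r <- y - q0
  # smallest shift with area share >= tau, and the step just below it
  d_hi <- weighted_quantile_area(r, a, tau)
  cand <- sort(unique(r[r < d_hi]))
  d_lo <- if (length(cand)) cand[length(cand)] else d_hi
  pick <- function(d) {
    b <- beta; b[ic] <- b[ic] + d
    mk(b, q0 + d)
  }
  fit_hi <- pick(d_hi)
  fit_lo <- pick(d_lo)
  best <- if (abs(fit_lo$fraction_below - tau) <
              abs(fit_hi$fraction_below - tau)) fit_lo else fit_hi
  if (best$objective <= fit0$objective) best else fit0
}

#' @export
print.yg_fit <- function(x, ...) {
  cat(sprintf("Quantile surface fit (tau = %.2f)\n", x$tau))
  cat(sprintf("  check loss %.5g  penalty %.5g  area share below %.4f\n",
              x$loss, x$lambda, x$fraction_below))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Fit the annual series of attainable-yield surfaces
#'
#' Fits one regularized quantile surface per year, each on that year's
#' records only, with a single pooled set of normalization factors (computed
#' once over all supplied records) so coefficients are comparable across
#' years.  Years with fewer than `min_ratio` records per coefficient are
#' skipped with a warning.
#'
#' @param records quality-passed census records.
#' @param spec a [model_spec()] without time terms.
#' @param years years to fit; defaults to all years present.
#' @param tau quantile level.
#' @param regularized apply the calibration step per year.
#' @param factors optional precomputed [normalization_factors()] (prediction
#'   and bootstrap paths reuse the original factors).
#' @param min_ratio minimum records-per-coefficient ratio.
#' @return object of class `yg_annual_series`: list of per-year `yg_fit`s
#'   plus the spec, factors and training covariate ranges.
#' @export
fit_annual_series <- function(records, spec, years = NULL, tau = 0.95,
                              regularized = TRUE, factors = NULL,
                              min_ratio = 5) {
  stopifnot(inherits(spec, "yg_spec"))
  if (any(term_vars(spec$terms) == "t"))
    stop_yg("annual fitting requires a spec without time terms (see strip_time_terms)")
  years <- years %||% sort(unique(records$year))
  vars <- tolower(setdiff(term_vars(spec$terms), character()))
  if (is.null(factors))
    factors <- normalization_factors(records, c(vars, "yield_t_ha"))
  ranges <- lapply(vars, function(v) range(records[[v]]))
  names(ranges) <- vars

  yf <- factors[factors$var == "yield_t_ha", ]
  fits <- list()
  p <- length(spec$terms)
  for (yr in years) {
    sub <- records[records$year == yr, , drop = FALSE]
    if (nrow(sub) < min_ratio * p) {
      warn_yg("year %s skipped: %d records < %g x %d coefficients",
              yr, nrow(sub), min_ratio, p)
      next
    }
    X <- build_design(sub, spec, factors)
    yz <- (sub$yield_t_ha - yf$mean) / yf$sd
    fit <- fit_quantile(X, yz, sub$area_ha, tau = tau,
                        regularized = regularized,
                        sd_y = stats::sd(yz))
    fit$year <- yr
    fits[[as.character(yr)]] <- fit
  }
  if (!length(fits))
    stop_yg("no year had at least %g records per coefficient", min_ratio)
  structure(list(fits = fits, spec = spec, factors = factors, tau = tau,
                 ranges = ranges),
            class = "yg_annual_series")
}

#' @export
print.yg_annual_series <- function(x, ...) {
  cat(sprintf("Annual attainable-yield surfaces: %d years (tau = %.2f)\n",
              length(x$fits), x$tau))
  cat("  model:", paste(x$spec$terms, collapse = " + "), "\n")
  invisible(x)
}

#' Predict attainable yields from a fitted surface
#'
#' Maps new records through the stored normalization factors, evaluates the
#' fitted surface and returns de-normalized attainable yields in t/ha,
#' floored at zero.  A warning is raised when covariates fall outside the
#' training support.
#'
#' @param series a `yg_annual_series`.
#' @param newdata records with the covariate columns in physical units.
#' @param year which fitted year to use.
#' @return numeric vector of attainable yields (t/ha).
#' @export
predict_attainable <- function(series, newdata, year) {
  stopifnot(inherits(series, "yg_annual_series"))
  fit <- series$fits[[as.character(year)]]
  if (is.null(fit)) stop_yg("no fit for year %s", year)
  for (v in names(series$ranges)) {
    rg <- series$ranges[[v]]
    if (any(newdata[[v]] < rg[1] | newdata[[v]] > rg[2]))
      warn_yg("covariate %s outside training support", v)
  }
  X <- build_design(newdata, series$spec, series$factors)
  yf <- series$factors[series$factors$var == "yield_t_ha", ]
  pred <- drop(X %*% fit$coefficients) * yf$sd + yf$mean
  if (any(pred < 0)) {
    warn_yg("%d negative raw predictions floored at 0", sum(pred < 0))
    pred <- pmax(pred, 0)
  }
  pred
}
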