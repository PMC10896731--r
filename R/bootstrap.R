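# Bootstrap ensembles of annual coefficient fits and the percentile
# intervals and sign calls every downstream significance decision reads.

#' Bootstrap ensemble of annual surface coefficients
#'
#' Case-resamples the fit year's census records (each record keeps its area
#' weight) and refits the regularized quantile surface `B` times.  Seeds are
#' laddered (master seed, year, replicate, attempt) so any single replicate
#' is reproducible in isolation.  Failed refits (e.g. a rank-deficient
#' resample) are redrawn up to `max_attempts` times; more than 5%
#' irrecoverable failures is an error.
#'
#' @param records census records (all years; the fit year is selected here).
#' @param spec a [model_spec()] without time terms.
#' @param year fit year.
#' @param B number of bootstrap replicates.
#' @param seed master integer seed.
#' @param tau quantile level.
#' @param factors [normalization_factors()]; computed from `records` when
#'   `NULL`.  Resamples reuse the original factors.
#' @param regularized use the calibration-regularized path.
#' @param max_attempts redraw attempts per failed replicate.
#' @return object of class `yg_ensemble`: `coefficients` (`B x p` matrix in
#'   z-score space), `spec`, `factors`, `year`, `tau`, `seed`, `failures`.
#' @export
bootstrap_fit <- function(records, spec, year, B = 1000, seed = 1,
                          tau = 0.95, factors = NULL, regularized = TRUE,
                          max_attempts = 3) {
  stopifnot(inherits(spec, "yg_spec"))
  if (B < 2) stop_yg("B must be at least 2")
  sub <- records[records$year == year, , drop = FALSE]
  if (!nrow(sub)) stop_yg("no records for year %s", year)
  vars <- tolower(term_vars(spec$terms))
  if (is.null(factors))
    factors <- normalization_factors(records, c(vars, "yield_t_ha"))
  yf <- factors[factors$var == "yield_t_ha", ]
  X <- build_design(sub, spec, factors)
  yz <- (sub$yield_t_ha - yf$mean) / yf$sd
  n <- nrow(sub)
  p <- length(spec$terms)

  coefs <- matrix(NA_real_, B, p, dimnames = list(NULL, spec$terms))
  failures <- 0L
  for (b in seq_len(B)) {
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      set.seed(derive_seed(seed, "year", year, "rep", b, "attempt", attempt))
      idx <- sample.int(n, n, replace = TRUE)
      fit <- tryCatch(
        fit_quantile(X[idx, , drop = FALSE], yz[idx], sub$area_ha[idx],
                     tau = tau, regularized = regularized),
        error = function(e) NULL)
      if (!is.null(fit)) {
        coefs[b, ] <- fit$coefficients
        done <- TRUE
        break
      }
    }
    if (!done) failures <- failures + 1L
  }
  if (failures > 0.05 * B)
    stop_yg("bootstrap: %d of %d replicates failed irrecoverably", failures, B)
  coefs <- coefs[stats::complete.cases(coefs), , drop = FALSE]
  structure(list(coefficients = coefs, spec = spec, factors = factors,
                 year = year, tau = tau, seed = seed, failures = failures),
            class = "yg_ensemble")
}

#' @export
print.yg_ensemble <- function(x, ...) {
  cat(sprintf("Bootstrap coefficient ensemble: year %s, B = %d, tau = %.2f\n",
              x$year, nrow(x$coefficients), x$tau))
  invisible(x)
}

#' Percentile confidence interval
#'
#' Empirical interval from the tails of a statistic's bootstrap (or
#' realization) distribution, using linear interpolation between order
#' statistics (R's default quantile convention).
#'
#' @param values numeric vector, length >= 2.
#' @param level interval level (0.95 gives the 2.5th and 97.5th
#'   percentiles; 0.75 supports the sensitivity analysis).
#' @return numeric `c(lo, hi)` with `lo <= hi`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  if (length(values) < 2) stop_yg("need at least 2 values")
  alpha <- (1 - level) / 2
  unname(stats::quantile(values, c(alpha, 1 - alpha), type = 7, names = FALSE))
}

#' Sign call from resampled slopes
#'
#' A trend is significantly positive (negative) when both percentile bounds
#' of the realization distribution are positive (negative); otherwise there
#' is no significant trend.
#'
#' @param values per-realization slope values.
#' @param level confidence level of the percentile interval.
#' @return `"positive"`, `"negative"` or `"none"`.
#' @export
significant_sign <- function(values, level = 0.95) {
  ci <- percentile_ci(values, level)
  if (ci[1] > 0 && ci[2] > 0) "positive"
  else if (ci[1] < 0 && ci[2] < 0) "negative"
  else "none"
}
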