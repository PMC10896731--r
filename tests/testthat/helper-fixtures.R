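# Fixture builders and independent oracles shared across tests.

# minimal census table: one crop, given yields/areas, one year
make_census <- function(yield, area = rep(1, length(yield)),
                        area_fraction = rep(1, length(yield)),
                        year = 2000, crop = "maize") {
  n <- length(yield)
  data.frame(unit_id = sprintf("U%03d", seq_len(n)), crop = crop,
             year = year, yield_t_ha = yield, area_ha = area,
             area_fraction = area_fraction, stringsAsFactors = FALSE)
}

# brute-force grid-search oracle for the area-weighted check loss with
# at most 2 coefficients; independent of the LP solver
grid_qr_oracle <- function(X, y, a, tau, lim = 3, res = 0.01) {
  stopifnot(ncol(X) <= 2)
  g <- seq(-lim, lim, by = res)
  if (ncol(X) == 1) {
    beta <- matrix(g, ncol = 1)
  } else {
    beta <- as.matrix(expand.grid(g, g))
  }
  Q <- X %*% t(beta)                       # n x n_grid predictions
  R <- y - Q
  W <- ifelse(R > 0, tau, 1 - tau)
  losses <- colSums(W * abs(R) * a) / sum(a)
  k <- which.min(losses)
  list(loss = losses[k], beta = beta[k, ])
}

# noiseless quantile-surface fixture: a fraction of (equal-weight) points
# lies exactly on the surface X beta, the rest strictly below, so the
# tau = 0.95 surface is X beta itself
exact_surface_fixture <- function(seed, n = 400, fr_on = 0.08,
                                  beta = c(5, 1.3, -0.7)) {
  set.seed(seed)
  X <- cbind(1, runif(n, -2, 2), runif(n, -2, 2))
  colnames(X) <- c("1", "A", "B")
  on <- sample(n, round(fr_on * n))
  eps <- -runif(n, 0.2, 2)
  eps[on] <- 0
  list(X = X, y = drop(X %*% beta) + eps, a = rep(1, n), beta = beta)
}

# long gap table from explicit per-unit series (single realization)
make_gap_table <- function(years, gap_by_unit, area_by_unit = NULL,
                           attainable = 10) {
  units <- names(gap_by_unit)
  if (is.null(area_by_unit)) area_by_unit <- setNames(rep(1, length(units)), units)
  do.call(rbind, lapply(units, function(u) {
    g <- gap_by_unit[[u]]
    data.frame(unit_id = u, year = years, rep = 0L,
               actual = attainable - g, attainable = attainable, gap = g,
               area = area_by_unit[[u]], stringsAsFactors = FALSE)
  }))
}

default_beta_terms <- function(panel) names(attr(panel, "config")$beta)

# fitted z-space coefficients mapped to the generator's scale (raw response,
# z-scored covariates) so they are comparable with attr(panel, "beta_z")
coef_on_truth_scale <- function(coefficients, factors) {
  yf <- factors[factors$var == "yield_t_ha", ]
  b <- coefficients * yf$sd
  b[1] <- b[1] + yf$mean
  b
}
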