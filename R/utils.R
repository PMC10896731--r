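#' @keywords internal
"_PACKAGE"

# Column order of the canonical census schema (delimited text interface).
CENSUS_COLS <- c("unit_id", "crop", "year", "yield_t_ha", "area_ha",
                 "area_fraction")
COVARIATE_COLS <- c("gdd", "map", "pci", "irr", "awc", "soc", "ph",
                    "slope30", "vf")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_yg <- function(...) stop(sprintf(...), call. = FALSE)
warn_yg <- function(...) warning(sprintf(...), call. = FALSE)

#' Area-weighted mean
#'
#' Weighted arithmetic mean with non-negative weights; at least one weight
#' must be positive.
#'
#' @param x numeric values.
#' @param w non-negative weights (harvested areas).
#' @param na.rm drop pairs where `x` or `w` is `NA`.
#' @return scalar weighted mean.
#' @export
weighted_mean_area <- function(x, w, na.rm = FALSE) {
  if (length(x) != length(w)) stop_yg("x and w must have equal length")
  if (na.rm) {
    keep <- !(is.na(x) | is.na(w))
    x <- x[keep]; w <- w[keep]
  }
  if (any(w < 0)) stop_yg("negative weights")
  sw <- sum(w)
  if (!length(w) || sw <= 0) stop_yg("no harvested area")
  sum(x * w) / sw
}

#' Area-weighted quantile
#'
#' Quantile of the left-continuous weighted empirical CDF:
#' `inf { t : F(t) >= p }` with `F(t) = sum(w[y <= t]) / sum(w)`.
#' Ties are broken by value order then by the optional `id` vector, making
#' the result deterministic on any input.
#'
#' @param x numeric values.
#' @param w non-negative weights; at least one positive.
#' @param p probability in (0, 1].
#' @param id optional secondary sort key for ties.
#' @return the weighted `p`-quantile of `x`.
#' @export
weighted_quantile_area <- function(x, w, p, id = NULL) {
  if (length(x) != length(w)) stop_yg("x and w must have equal length")
  if (any(w < 0)) stop_yg("negative weights")
  sw <- sum(w)
  if (!length(w) || sw <= 0) stop_yg("no harvested area")
  if (p <= 0 || p > 1) stop_yg("p must be in (0, 1]")
  ord <- if (is.null(id)) order(x) else order(x, id)
  xs <- x[ord]
  cw <- cumsum(w[ord]) / sw
  xs[which(cw >= p - 1e-12)[1L]]
}

# Deterministic 32-bit FNV-1a hash of a character scalar, reduced to a
# positive value below 2^31 so it is always a valid R random seed.
fnv_seed <- function(...) {
  s <- paste(c(...), collapse = "\r")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte since b < 256; keeps h a double in range
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit multiply by 16777619 in double arithmetic (split to keep exact)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

#' Derive a reproducible sub-seed
#'
#' Hashes a master seed together with a stream label (and further keys such as
#' year or replicate index) into an independent, reproducible seed below
#' `2^31`.  Used throughout so that any single bootstrap replicate or
#' simulation stream can be reproduced in isolation.
#'
#' @param seed master integer seed.
#' @param ... stream labels (character or numeric) identifying the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) fnv_seed(format(seed), ...)

# short config fingerprint for output headers
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = " ")
  sprintf("%08x", fnv_seed(s))
}

# days per month used for degree-day sums (non-leap climatological year)
DAYS_PER_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
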