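# Interior-point solver for area-weighted linear quantile regression.
#
# The fit minimizes  sum_i a_i * rho_tau(y_i - x_i' beta)  with the check
# (pinball) loss rho_tau(r) = r * (tau - 1[r < 0]).  Because rho_tau is
# positively homogeneous, row scaling turns the area-weighted problem into an
# unweighted one, whose LP dual is
#
#     max { y'd : X'd = (1 - tau) X'1,  d in [0, 1]^n } ,
#
# solved here with a Mehrotra predictor-corrector primal-dual interior-point
# iteration (the Frisch-Newton approach standard for quantile regression).
# The equality multipliers at the optimum are the regression coefficients.

#' Area-weighted quantile regression fit (interior point)
#'
#' Exact minimizer of the area-weighted check loss for a single quantile
#' `tau`.  This is the low-level engine behind [fit_quantile()].
#'
#' @param X design matrix (n x p), full column rank.
#' @param y response vector.
#' @param tau quantile level in (0, 1).
#' @param weights optional non-negative case weights (harvested areas).
#' @param tol duality-gap convergence tolerance (relative).
#' @param maxit maximum interior-point iterations.
#' @return list with `coefficients`, `iterations`, `gap` (final relative
#'   duality gap) and `converged`.
#' @export
rq_fit_ip <- function(X, y, tau = 0.95, weights = NULL,
                      tol = 1e-10, maxit = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_yg("length(y) != nrow(X)")
  if (tau <= 0 || tau >= 1) stop_yg("tau must be in (0, 1)")
  if (n < p) stop_yg("fewer rows than coefficients")
  if (!is.null(weights)) {
    if (length(weights) != n) stop_yg("weights length mismatch")
    if (any(weights < 0)) stop_yg("negative weights")
    if (sum(weights) <= 0) stop_yg("no harvested area")
    w <- weights / mean(weights)
    keep <- w > 0
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    w <- w[keep]
    n <- nrow(X)
    if (n < p) stop_yg("fewer positively weighted rows than coefficients")
    X <- X * w
    y <- y * w
  }
  if (qr(X)$rank < p) stop_yg("design matrix is rank deficient")

  A <- t(X)                       # p x n
  cc <- -y                        # minimize c'd  ==  maximize y'd
  b <- (1 - tau) * rowSums(A)

  x <- rep(1 - tau, n)            # dual variables, strictly interior
  s <- 1 - x
  # multipliers initialized at (minus) the least-squares fit
  M0 <- tcrossprod(A)
  diag(M0) <- diag(M0) + 1e-12 * (1 + mean(diag(M0)))
  ymult <- drop(solve(M0, A %*% cc))
  r0 <- cc - drop(crossprod(A, ymult))
  eps0 <- 1e-6 * (1 + max(abs(y)))
  z <- pmax(r0, 0) + eps0
  w_ <- z - r0                    # ensures z - w_ == r0 exactly

  scale0 <- 1 + sum(abs(y)) / n
  step <- function(v, dv) {
    neg <- dv < 0
    if (!any(neg)) return(1)
    min(1, 0.9995 * min(-v[neg] / dv[neg]))
  }

  it <- 0L; gap <- Inf
  while (it < maxit) {
    gap <- sum(x * z) + sum(s * w_)
    if (gap / (n * scale0) < tol) break
    it <- it + 1L

    q <- 1 / (z / x + w_ / s)
    r <- z - w_
    Aq <- A * rep(q, each = p)
    M <- tcrossprod(Aq, A)
    diag(M) <- diag(M) + 1e-12 * (1 + mean(diag(M)))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) stop_yg("interior-point normal equations are singular")
    solveM <- function(rhs) backsolve(ch, backsolve(ch, rhs, transpose = TRUE))

    # affine (predictor) direction
    dy <- drop(solveM(A %*% (q * r)))
    dx <- q * (drop(crossprod(A, dy)) - r)
    ds <- -dx
    dz <- -z - (z / x) * dx
    dw <- -w_ - (w_ / s) * ds
    ap <- min(step(x, dx), step(s, ds))
    ad <- min(step(z, dz), step(w_, dw))
    gap_aff <- sum((x + ap * dx) * (z + ad * dz)) +
      sum((s + ap * ds) * (w_ + ad * dw))
    sigma <- min(1, max(0, (gap_aff / gap)))^3
    mu <- sigma * gap / (2 * n)

    # corrector with Mehrotra second-order terms (affine products fixed)
    dxdz <- dx * dz
    dsdw <- ds * dw
    corr <- (mu - dxdz) / x - (mu - dsdw) / s
    dy <- drop(solveM(A %*% (q * (r - corr))))
    dx <- q * (drop(crossprod(A, dy)) - r + corr)
    ds <- -dx
    dz <- (mu - dxdz) / x - z - (z / x) * dx
    dw <- (mu - dsdw) / s - w_ - (w_ / s) * ds

    ap <- min(step(x, dx), step(s, ds))
    ad <- min(step(z, dz), step(w_, dw))
    x <- x + ap * dx; s <- s + ap * ds
    z <- z + ad * dz; w_ <- w_ + ad * dw
    ymult <- ymult + ad * dy
  }

  list(coefficients = -ymult, iterations = it,
       gap = gap / (n * scale0), converged = gap / (n * scale0) < tol)
}
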