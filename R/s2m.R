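# Cyclic second-difference operator on the 12-month annual cycle:
# row j is T[j-1] - 2 T[j] + T[j+1] with month 0 = December, month 13 =
# January.
second_diff_matrix <- function() {
  D <- matrix(0, 12, 12)
  for (j in 1:12) {
    D[j, j] <- -2
    D[j, if (j == 1) 12 else j - 1] <- 1
    D[j, if (j == 12) 1 else j + 1] <- 1
  }
  D
}

# 4x12 seasonal-membership matrix: A %*% T gives the 3-month sums.
season_sum_matrix <- function() {
  A <- matrix(0, 4, 12)
  sm <- season_months()
  for (s in 1:4) A[s, sm[[s]]] <- 1
  A
}

#' Seasonal-to-monthly interpolation, additive variables
#'
#' Reconstructs 12 monthly values from 4 seasonal means (DJF, MAM, JJA,
#' SON) as the smoothest annual cycle consistent with the seasons: the sum
#' of squared cyclic second differences is minimized subject to each
#' season's three months averaging exactly to the seasonal mean. Lagrange
#' multipliers turn this into a single 16 x 16 linear system (12 months +
#' 4 multipliers), solved directly. Flat assignment (every month equal to
#' its season) is feasible but jagged; this solution preserves the annual
#' cycle amplitude instead of damping it the way linear interpolation of
#' seasonal values does.
#'
#' @param S Numeric 4-vector of seasonal means (winter, spring, summer,
#'   fall).
#' @return Numeric 12-vector of monthly values; re-aggregating it with
#'   [seasonal_from_monthly()] reproduces `S` to machine precision.
#' @export
s2m_additive <- function(S) {
  stopifnot(length(S) == 4, all(is.finite(S)))
  D <- second_diff_matrix()
  A <- season_sum_matrix()
  Q <- 2 * crossprod(D)
  M <- rbind(cbind(Q, t(A)), cbind(A, matrix(0, 4, 4)))
  rhs <- c(rep(0, 12), 3 * S)
  sol <- solve(M, rhs)
  sol[1:12]
}

#' Seasonal-to-monthly interpolation, factor variables
#'
#' For zero-bounded variables the monthly values are change factors `f_j`
#' applied to a known monthly climatology `P_j`, and smoothness is imposed
#' on `log f` so factors stay positive. Each season's constraint is
#' weighted by the climatology:
#' `sum_j f_j P_j = F_s sum_j P_j` over the season's months. The Lagrange
#' stationarity conditions give 16 equations (12 nonlinear stationarity +
#' 4 constraints), solved with a MINPACK least-squares root finder
#' initialized from the flat solution `f_j = F_season(j)` (which satisfies
#' the constraints exactly), with deterministic rescaled restarts.
#'
#' @param F Numeric 4-vector of positive seasonal factors.
#' @param P_clim Numeric 12-vector of non-negative climatology weights;
#'   every season must have positive total weight. Months with zero weight
#'   drop out of their season's constraint and are set by smoothness alone.
#' @param tol Relative constraint residual required for success.
#' @return Numeric 12-vector of positive monthly factors.
#' @export
s2m_factor <- function(F, P_clim, tol = 1e-8) {
  stopifnot(length(F) == 4, length(P_clim) == 12)
  if (any(F <= 0)) stop("seasonal factors must be positive")
  if (any(P_clim < 0)) stop("climatology weights must be non-negative")
  A <- season_sum_matrix()
  wsum <- as.numeric(A %*% P_clim)
  if (any(wsum <= 0)) stop("every season needs positive total weight")
  cons_target <- F * wsum
  Q <- crossprod(second_diff_matrix())
  sidx <- season_of_month()

  resid_fun <- function(z) {
    x <- z[1:12]; lam <- z[13:16]
    ex <- exp(x)
    c(2 * as.numeric(Q %*% x) + lam[sidx] * P_clim * ex,
      as.numeric(A %*% (P_clim * ex)) - cons_target)
  }

  x0 <- log(F[sidx])
  scales <- c(1, 0.9, 1.1, 0.75)
  best <- NULL
  for (sc in scales) {
    z0 <- c(x0 * sc, rep(0, 4))
    fit <- minpack.lm::nls.lm(
      par = z0, fn = resid_fun,
      control = minpack.lm::nls.lm.control(
        maxiter = 400, ftol = 1e-15, ptol = 1e-13, maxfev = 20000))
    f <- exp(fit$par[1:12])
    cres <- max(abs(as.numeric(A %*% (P_clim * f)) - cons_target) /
                  pmax(abs(cons_target), 1e-12))
    if (is.null(best) || cres < best$cres) best <- list(f = f, cres = cres)
    if (cres <= tol) break
  }
  if (best$cres > tol)
    stop("factor seasonal-to-monthly solver failed to converge (residual ",
         signif(best$cres, 3), ")")
  best$f
}

#' Seasonal-to-monthly interpolation, shortwave exponents
#'
#' The power-law exponents gamma must stay positive, so the additive
#' solver is applied to `log(gamma)` and the result exponentiated; the
#' seasonal means of `log(gamma)` are preserved exactly.
#'
#' @param gamma_seasonal Numeric 4-vector of positive seasonal exponents.
#' @return Numeric 12-vector of positive monthly exponents.
#' @export
s2m_gamma <- function(gamma_seasonal) {
  if (any(gamma_seasonal <= 0)) stop("gamma must be positive")
  exp(s2m_additive(log(gamma_seasonal)))
}

#' Apply seasonal-to-monthly interpolation across a raster
#'
#' Cell-wise driver over a seasonal field stack. Additive and gamma kinds
#' need only the seasonal stack; factor kind additionally needs the
#' monthly climatology stack for the constraint weights.
#'
#' @param seasonal Array `n_lon x n_lat x 4`.
#' @param kind One of `"additive"`, `"factor"`, `"gamma"`.
#' @param P_clim Array `n_lon x n_lat x 12` (factor kind only).
#' @param mask Optional logical matrix; cells outside are `NA`.
#' @return Array `n_lon x n_lat x 12`.
#' @export
s2m_field <- function(seasonal, kind = c("additive", "factor", "gamma"),
                      P_clim = NULL, mask = NULL) {
  kind <- match.arg(kind)
  d <- dim(seasonal)
  stopifnot(length(d) == 3, d[3] == 4)
  if (kind == "factor") {
    stopifnot(!is.null(P_clim), all(dim(P_clim) == c(d[1], d[2], 12)))
  }
  out <- array(NA_real_, c(d[1], d[2], 12))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!is.null(mask) && !mask[i, j]) next
    S <- seasonal[i, j, ]
    if (anyNA(S)) next
    out[i, j, ] <- switch(kind,
      additive = s2m_additive(S),
      gamma = s2m_gamma(S),
      factor = tryCatch(s2m_factor(S, P_clim[i, j, ]),
                        error = function(e)
                          stop("cell (", i, ",", j, "): ",
                               conditionMessage(e))))
  }
  out
}
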