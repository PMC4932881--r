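# Independent oracles used across the suite. Each reimplements the
# quantity being tested from first principles, by a different route than
# the package code takes.

# Equality-constrained quadratic minimizer via the null-space method:
# minimize ||D t||^2 subject to A t = b. Independent of the Lagrange
# KKT-system route used by the solver under test.
qp_nullspace_oracle <- function(D, A, b) {
  t0 <- qr.solve(A, b)                      # any particular solution
  sv <- svd(A, nu = 0, nv = ncol(A))
  null_basis <- sv$v[, (qr(A)$rank + 1):ncol(A), drop = FALSE]
  M <- D %*% null_basis
  z <- qr.solve(crossprod(M), -crossprod(M, D %*% t0))
  as.numeric(t0 + null_basis %*% z)
}

# Augmented-Lagrangian minimizer for the log-smoothness factor problem:
# minimize sum over j of (x[j-1] - 2 x[j] + x[j+1])^2 (cyclic, x = log f)
# subject to the weighted seasonal constraints, by repeated unconstrained
# BFGS solves with multiplier updates (converges to the exact constrained
# optimum, unlike a pure quadratic penalty).
factor_penalty_oracle <- function(F, P, mu = 1e4, outer_iters = 12) {
  D <- local({
    m <- matrix(0, 12, 12)
    for (j in 1:12) {
      m[j, j] <- -2
      m[j, if (j == 1) 12 else j - 1] <- 1
      m[j, if (j == 12) 1 else j + 1] <- 1
    }
    m
  })
  seasons <- list(c(1, 2, 12), 3:5, 6:8, 9:11)
  targets <- vapply(1:4, function(s) F[s] * sum(P[seasons[[s]]]),
                    numeric(1))
  cons <- function(x) vapply(1:4, function(s)
    (sum(P[seasons[[s]]] * exp(x[seasons[[s]]])) - targets[s]) /
      max(targets[s], 1e-9), numeric(1))
  lam <- rep(0, 4)
  season_of <- integer(12)
  for (s in 1:4) season_of[seasons[[s]]] <- s
  norms <- pmax(targets, 1e-9)
  obj <- function(x) {
    cv <- cons(x)
    sum((D %*% x)^2) + sum(lam * cv) + mu / 2 * sum(cv^2)
  }
  grd <- function(x) {
    cv <- cons(x)
    g <- as.numeric(2 * crossprod(D) %*% x)
    coef <- (lam + mu * cv) / norms
    g + coef[season_of] * P * exp(x)
  }
  x <- log(F)[c(1, 1, 2, 2, 2, 3, 3, 3, 4, 4, 4, 1)]
  for (it in seq_len(outer_iters)) {
    x <- stats::optim(x, obj, gr = grd, method = "BFGS",
                      control = list(maxit = 5000, reltol = 1e-15))$par
    lam <- lam + mu * cons(x)
  }
  exp(x)
}

# Brute-force daily construction of the annual-cycle standard deviation:
# builds the piecewise-linear daily cycle through the month centres and
# takes the population sd about the month's own mean.
sigma_annual_brute <- function(T_prev, T_cur, T_next, n_prev, n_cur,
                               n_next, per_day = 20) {
  a_plus <- 2 * (T_next - T_cur) / (n_next + n_cur)
  a_minus <- 2 * (T_cur - T_prev) / (n_cur + n_prev)
  d <- (seq_len(round(n_cur * per_day)) - 0.5) / per_day
  off <- d - n_cur / 2
  v <- ifelse(off < 0, T_cur + a_minus * off, T_cur + a_plus * off)
  sqrt(mean((v - mean(v))^2))
}

# Exhaustive elliptical-shell search for a single submerged cell: scan
# every donor, apply the same shell-growth rule and inverse-distance
# weights, but with independently coded haversine distance.
fill_one_brute <- function(grid, field, present_land, target_ij,
                           w = 0.75) {
  hav <- function(lon1, lat1, lon2, lat2, R = 6371000) {
    to_r <- pi / 180
    dlat <- (lat2 - lat1) * to_r; dlon <- (lon2 - lon1) * to_r
    h <- sin(dlat / 2)^2 +
      cos(lat1 * to_r) * cos(lat2 * to_r) * sin(dlon / 2)^2
    2 * R * asin(pmin(sqrt(h), 1))
  }
  donors <- which(present_land & is.finite(field), arr.ind = TRUE)
  tl <- c(grid$lon[target_ij[1]], grid$lat[target_ij[2]])
  d <- hav(grid$lon[donors[, 1]], grid$lat[donors[, 2]], tl[1], tl[2])
  dphi <- abs(grid$lat[donors[, 2]] - tl[2]) * pi / 180
  a <- sqrt((1 - w) * d^2 + w * (6371000 * dphi)^2)
  eps <- grid$resolution * pi / 180 * 6371000
  a_max <- 1.5 * eps
  while (!any(a <= a_max)) a_max <- a_max + eps
  sel <- a <= a_max
  sum(field[donors[sel, , drop = FALSE]] / a[sel]) / sum(1 / a[sel])
}

# Small nested grid pair shared by regridding tests.
tiny_grids <- function() {
  list(coarse = make_grid(0, 10, 0, 6, 2),
       fine = make_grid(0, 10, 0, 6, 0.5))
}
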