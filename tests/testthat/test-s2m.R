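test_that("additive solver satisfies seasonal constraints exactly", {
  expect_equal(s2m_additive(c(7, 7, 7, 7)), rep(7, 12))
  set.seed(11)
  for (k in 1:25) {
    S <- rnorm(4, sd = 10)
    T <- s2m_additive(S)
    expect_lt(max(abs(seasonal_from_monthly(T) - S)), 1e-10)
  }
})

test_that("additive solver is the constrained smoothness optimum", {
  D <- paleodown:::second_diff_matrix()
  A <- paleodown:::season_sum_matrix()
  set.seed(12)
  for (k in 1:25) {
    S <- rnorm(4, sd = 8)
    T <- s2m_additive(S)
    oracle <- qp_nullspace_oracle(D, A, 3 * S)
    expect_equal(T, oracle, tolerance = 1e-8)
    # KKT residual of the 16-dimensional stationarity system
    lam <- qr.solve(t(A), -2 * crossprod(D) %*% T)
    kkt <- c(2 * crossprod(D) %*% T + t(A) %*% lam, A %*% T - 3 * S)
    expect_lt(max(abs(kkt)), 1e-10)
    # any feasible perturbation (in the constraint null space) is worse
    ns <- svd(A, nv = 12)$v[, 5:12]
    for (j in 1:3) {
      pert <- T + ns %*% rnorm(8, sd = 0.1)
      expect_gte(sum((D %*% pert)^2), sum((D %*% T)^2) - 1e-12)
    }
  }
})

test_that("additive solver amplifies rather than damps the cycle", {
  S <- c(-10, 2, 14, 3)
  T <- s2m_additive(S)
  expect_gte(max(T) - min(T), max(S) - min(S))
})

test_that("factor solver meets weighted constraints and stays positive", {
  A <- paleodown:::season_sum_matrix()
  expect_equal(s2m_factor(rep(1, 4), runif(12, 1, 100)), rep(1, 12),
               tolerance = 1e-8)
  expect_equal(s2m_factor(rep(2.5, 4), rep(10, 12)), rep(2.5, 12),
               tolerance = 1e-8)
  set.seed(13)
  for (k in 1:25) {
    F <- exp(rnorm(4, sd = 0.4))
    P <- runif(12, 5, 120)
    f <- s2m_factor(F, P)
    expect_true(all(f > 0))
    resid <- as.numeric(A %*% (P * f)) - F * as.numeric(A %*% P)
    expect_lt(max(abs(resid) / (F * as.numeric(A %*% P))), 1e-8)
  }
})

test_that("factor solver agrees with a penalty-method oracle", {
  set.seed(14)
  for (k in 1:5) {
    F <- exp(rnorm(4, sd = 0.3))
    P <- runif(12, 10, 100)
    f <- s2m_factor(F, P)
    f_oracle <- factor_penalty_oracle(F, P)
    expect_equal(f, f_oracle, tolerance = 1e-6)
  }
})

test_that("factor solver reduces to the additive solver under uniform weights", {
  set.seed(15)
  F <- exp(rnorm(4, sd = 0.5))
  f <- s2m_factor(F, rep(30, 12))
  # with uniform P the constraints become mean(log-ish) structure matched
  # by the additive solution in log space up to the arithmetic/geometric
  # distinction; verify stationarity instead: log f minimizes the cyclic
  # second-difference subject to mean(f) per season
  A <- paleodown:::season_sum_matrix()
  expect_equal(as.numeric(A %*% f) / 3, F, tolerance = 1e-8)
})

test_that("gamma solver preserves seasonal means in log space", {
  expect_equal(s2m_gamma(rep(1, 4)), rep(1, 12))
  expect_equal(s2m_gamma(rep(exp(1), 4)), rep(exp(1), 12))
  set.seed(16)
  for (k in 1:10) {
    g <- exp(rnorm(4, sd = 0.5))
    gm <- s2m_gamma(g)
    expect_true(all(gm > 0))
    expect_lt(max(abs(seasonal_from_monthly(log(gm)) - log(g))), 1e-10)
  }
  expect_error(s2m_gamma(c(1, -1, 1, 1)), "positive")
})

test_that("raster driver matches cell-wise calls and respects masks", {
  set.seed(17)
  seas <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  out <- s2m_field(seas, "additive", mask = mask)
  expect_equal(out[1, 1, ], s2m_additive(seas[1, 1, ]))
  expect_true(all(is.na(out[2, 1, ])))
})
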