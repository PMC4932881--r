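test_that("empirical quantile map pairs sorted samples exactly", {
  set.seed(1)
  obs <- runif(100, 0, 200)
  m <- fit_empirical_qmap(obs, obs)
  expect_equal(apply_empirical_qmap(m, m$q), m$q)

  m2 <- fit_empirical_qmap(obs, 2 * obs)
  expect_equal(apply_empirical_qmap(m2, m2$q), m2$q / 2)

  mod <- rgamma(100, shape = 2, scale = 30)
  m3 <- fit_empirical_qmap(obs, mod)
  # sort-and-pair oracle: f(q_j) = p_j for every sample quantile
  expect_equal(apply_empirical_qmap(m3, sort(mod)), sort(obs))
  # midpoints interpolate linearly
  qs <- sort(mod); ps <- sort(obs)
  mid <- (qs[10] + qs[11]) / 2
  expect_equal(apply_empirical_qmap(m3, mid), (ps[10] + ps[11]) / 2)
  expect_error(fit_empirical_qmap(1:2, 1:2), "3")
  expect_error(fit_empirical_qmap(1:5, 1:4), "equal length")
})

test_that("empirical map extends its end segments linearly", {
  p <- c(0, 10, 20, 40)
  q <- c(1, 2, 3, 5)
  m <- structure(list(p = p, q = q, mode = "empirical"),
                 class = "pd_qmap")
  # beyond q_max: slope of last segment is (40-20)/(5-3) = 10
  expect_equal(apply_empirical_qmap(m, 7), 40 + 10 * 2)
  # below q_min: slope 10/(2-1) = 10, floored at zero
  expect_equal(apply_empirical_qmap(m, 0.5), 0)
  expect_equal(apply_empirical_qmap(m, 0.9), 0)
})

test_that("paleo linear map recovers exact and noisy lines", {
  q <- seq(2, 40, length.out = 11)
  m <- fit_paleo_linear_qmap(q, q)
  expect_equal(c(m$a, m$b), c(1, 0), tolerance = 1e-12)
  m2 <- fit_paleo_linear_qmap(3 * q + 2, q)
  expect_equal(c(m2$a, m2$b), c(3, 2), tolerance = 1e-12)

  set.seed(5)
  p <- sort(2.2 * q + 1 + rnorm(11))
  m3 <- fit_paleo_linear_qmap(p, q)
  # closed-form normal-equations oracle on the sorted pairs
  qs <- sort(q)
  a_hat <- sum((qs - mean(qs)) * (p - mean(p))) / sum((qs - mean(qs))^2)
  b_hat <- mean(p) - a_hat * mean(qs)
  expect_equal(c(m3$a, m3$b), c(a_hat, b_hat), tolerance = 1e-10)
  expect_error(fit_paleo_linear_qmap(1:11, rep(2, 11)), "degenerate")
})

test_that("paleo map dry-end rule is continuous and positive", {
  mk <- function(a, b, q1) structure(
    list(a = a, b = b, q1 = q1, p = NULL, q = NULL, mode = "linear"),
    class = "pd_qmap")
  m <- mk(2, -1, 4)
  expect_equal(apply_paleo_linear_qmap(m, 4), 7)        # both branches
  expect_equal(apply_paleo_linear_qmap(m, 0), 0)
  expect_equal(apply_paleo_linear_qmap(m, 2), 2 * 7 / 4) # chord branch
  m2 <- mk(1.5, 0.5, 4)
  expect_equal(apply_paleo_linear_qmap(m2, 2), 1.5 * 2 + 0.5) # line branch

  # rule-table sweep: continuity at q1 and positivity for q > 0
  for (a in c(0.5, 1, 2)) for (b in c(-2, -0.5, 0, 1)) {
    for (q1 in c(0.5, 2, 5)) {
      if (a * q1 + b <= 0) next  # line already non-positive at q1
      mm <- mk(a, b, q1)
      expect_equal(apply_paleo_linear_qmap(mm, q1),
                   a * q1 + b, tolerance = 1e-12)
      qs <- seq(0.01, 2 * q1, length.out = 25)
      expect_true(all(apply_paleo_linear_qmap(mm, qs) > 0))
    }
  }
})

test_that("quantile-mapped precipitation downscales like the factor method", {
  gs <- tiny_grids()
  set.seed(6)
  clim_c <- matrix(runif(15, 20, 100), gs$coarse$n_lon)
  obs_f <- matrix(runif(gs$fine$n_lon * gs$fine$n_lat, 10, 150),
                  gs$fine$n_lon)
  expect_equal(qmap_to_fine(clim_c, clim_c, obs_f, gs$coarse, gs$fine),
               obs_f)
  expect_equal(qmap_to_fine(1.5 * clim_c, clim_c, obs_f, gs$coarse,
                            gs$fine), 1.5 * obs_f)
  p_alt <- clim_c * matrix(runif(15, 0.5, 2), gs$coarse$n_lon)
  oracle <- obs_f * bilinear_regrid(p_alt / clim_c, gs$coarse, gs$fine)
  expect_equal(qmap_to_fine(p_alt, clim_c, obs_f, gs$coarse, gs$fine),
               oracle)
  # zero-climatology cells carry factor 1
  clim0 <- clim_c; clim0[2, 2] <- 0
  p0 <- clim0; p0[2, 2] <- 0
  out <- qmap_to_fine(p0, clim0, obs_f, gs$coarse, gs$fine)
  expect_true(all(is.finite(out)))
})
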