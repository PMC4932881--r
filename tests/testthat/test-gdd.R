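test_that("degree-day expectation has the right limits", {
  expect_equal(gdd_day_expectation(10, 0, 5), 5)
  expect_equal(gdd_day_expectation(2, 0, 5), 0)
  expect_equal(gdd_day_expectation(5, 3, 5), 3 / sqrt(2 * pi))
  expect_equal(gdd_day_expectation(-20, 3, 5), 0, tolerance = 1e-8)
  expect_error(gdd_day_expectation(10, -1, 5), ">= 0")
})

test_that("degree-day expectation matches a Monte-Carlo oracle", {
  set.seed(21)
  n <- 2e5
  for (case in list(c(2, 5, 5), c(10, 4, 0), c(-3, 6, 0), c(7, 2, 5))) {
    draws <- pmax(rnorm(n, case[1], case[2]) - case[3], 0)
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(gdd_day_expectation(case[1], case[2], case[3]) -
                    mean(draws)), 3 * se)
  }
})

test_that("expectation dominates the naive hinge and converges to it", {
  Tbar <- seq(-15, 25, by = 1)
  est <- gdd_day_expectation(Tbar, 4, 5)
  naive <- pmax(Tbar - 5, 0)
  expect_true(all(est >= naive))
  # gap closes far from the base temperature
  expect_lt(est[length(est)] - naive[length(naive)], 1e-4)
  expect_lt(est[1], 1e-4)
})

test_that("annual-cycle spread matches the brute-force daily construction", {
  expect_equal(sigma_annual(10, 10, 10), 0)
  # symmetric V-shape
  brute <- sigma_annual_brute(20, 10, 20, 30, 30, 30)
  expect_equal(sigma_annual(20, 10, 20, 30, 30, 30), brute,
               tolerance = 0.02)
  # linear ramp
  brute <- sigma_annual_brute(10, 20, 30, 30, 30, 30)
  expect_equal(sigma_annual(10, 20, 30, 30, 30, 30), brute,
               tolerance = 0.02)
  set.seed(22)
  for (k in 1:10) {
    Ts <- rnorm(3, 10, 8)
    nd <- sample(c(28, 30, 31), 3, replace = TRUE)
    expect_equal(sigma_annual(Ts[1], Ts[2], Ts[3], nd[1], nd[2], nd[3]),
                 sigma_annual_brute(Ts[1], Ts[2], Ts[3], nd[1], nd[2],
                                    nd[3]),
                 tolerance = 0.02)
  }
})

test_that("daily standard deviation combines memory and cycle terms", {
  expect_equal(sigma_daily(1, 30, 0), sqrt(0.178 * 30))
  expect_equal(sigma_daily(0, 30, 2), 2)
  expect_equal(sigma_daily(1, 30, 0, a = 1), sqrt(30))  # white-noise limit
})

test_that("monthly totals scale the daily expectation by month length", {
  g <- gdd_month(20, 2, T0 = 5, n = 30)
  expect_gte(g, 450)
  expect_lt(g - 450, 1)          # warm-month correction is tiny
  expect_equal(gdd_month(-20, 3, 5, 30), 0, tolerance = 1e-6)
  # cool months: naive monthly estimator is 0 but the expectation is not
  expect_equal(30 * max(2 - 5, 0), 0)
  expect_gt(gdd_month(2, 5, 5, 30), 10)
})

test_that("station fixture recovers empirical degree days", {
  fx <- make_fixture(fixture_scenario(seed = 3, n_member_decades = 1,
                                      station_years = 10))
  st <- fx$stations[fx$stations$station == 1, ]
  tmean <- (st$tmax + st$tmin) / 2
  daily_gdd <- tapply(pmax(tmean - 5, 0), st$month, mean)
  # estimator from monthly statistics alone (mean and daily sd per month)
  mon_mean <- tapply(tmean, st$month, mean)
  mon_sd <- tapply(tmean, st$month, sd)
  est <- gdd_day_expectation(mon_mean, mon_sd, 5)
  annual_emp <- sum(daily_gdd * tabulate(st$month[st$year == 1], 12))
  annual_est <- sum(est * tabulate(st$month[st$year == 1], 12))
  expect_lt(abs(annual_est - annual_emp) / annual_emp, 0.02)
  # naive monthly estimator underestimates in the cool season
  naive <- pmax(mon_mean - 5, 0)
  cool <- which(mon_mean < 8)
  expect_true(all(naive[cool] <= daily_gdd[cool] + 1e-9))
  expect_gt(sum(daily_gdd[cool]), sum(naive[cool]))
})
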