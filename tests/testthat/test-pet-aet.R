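test_that("reference evapotranspiration vanishes without drivers", {
  # zero net radiation, zero wind: both transfer terms vanish
  expect_equal(pet_penman_monteith(20, 10, 12, 0, 100, 20, -80, 101.3),
               0)
  # zero net radiation and saturated air: wind term has no deficit
  Tmax <- 15; Tmin <- 15
  es <- 0.6108 * exp(17.27 * 15 / (15 + 237.3)) * 10  # hPa, saturated
  expect_equal(pet_penman_monteith(Tmax, Tmin, es, 5, 100, 20, -80,
                                   101.3), 0)
})

test_that("reference evapotranspiration matches an independent evaluation", {
  # dual implementation written directly from the reference-surface
  # combination equation
  pm_oracle <- function(Tmax, Tmin, vap_hpa, u2, swd, swu, lwn, P_kpa,
                        n) {
    es_t <- function(x) 0.6108 * exp(17.27 * x / (x + 237.3))
    Tm <- (Tmax + Tmin) / 2
    Rn <- (swd - swu + lwn) * 0.0864
    slope <- 4098 * es_t(Tm) / (Tm + 237.3)^2
    gam <- 0.000665 * P_kpa
    vpd <- max((es_t(Tmax) + es_t(Tmin)) / 2 - vap_hpa / 10, 0)
    num <- 0.408 * slope * Rn + gam * (900 / (Tm + 273)) * u2 * vpd
    max(num / (slope + gam * (1 + 0.34 * u2)), 0) * n
  }
  cases <- list(c(25, 12, 14, 2.5, 250, 50, -70, 95, 31),
                c(5, -5, 6, 4, 120, 40, -60, 101.3, 30),
                c(32, 20, 25, 1, 320, 60, -90, 88, 30))
  for (cs in cases) {
    expect_equal(
      pet_penman_monteith(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6],
                          cs[7], cs[8], cs[9]),
      pm_oracle(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6], cs[7], cs[8],
                cs[9]),
      tolerance = 1e-12)
  }
})

test_that("reference evapotranspiration is monotone in the deficit", {
  vals <- sapply(c(20, 15, 10, 5), function(vap)
    pet_penman_monteith(25, 15, vap, 3, 250, 50, -70, 100))
  expect_true(all(diff(vals) > 0))
  expect_warning(pet_penman_monteith(20, 10, 10, 2, 100, 120, -50, 100),
                 "clipped")
})

test_that("bucket water balance closes over random forcings", {
  set.seed(31)
  n <- 240
  precip <- runif(n, 0, 200)
  pet <- runif(n, 0, 150)
  Tm <- runif(n, -20, 30)
  rb <- run_bucket(precip, pet, Tm, spinup_months = 0)
  d_store <- (tail(rb$soil, 1) + tail(rb$snow, 1)) - 75
  expect_lt(abs(sum(precip) - sum(rb$aet) - sum(rb$runoff) - d_store),
            1e-6)
  expect_true(all(rb$aet <= pet + 1e-9))
  expect_true(all(rb$aet >= 0))
  expect_true(all(rb$soil >= 0 & rb$soil <= 150 + 1e-9))
  expect_true(all(rb$snow >= 0))
})

test_that("bucket limit cases behave physically", {
  s <- bucket_state(soil = 0, snow = 0)
  step <- aet_bucket(0, 50, 10, s)
  expect_equal(step$aet, 0)
  # demand fully met with surplus to runoff from a full bucket
  s2 <- bucket_state(soil = 150, snow = 0)
  step2 <- aet_bucket(120, 40, 15, s2)
  expect_equal(step2$aet, 40)
  expect_equal(step2$runoff, 80)
  # all-snow month: nothing melts below freezing, no evaporation
  s3 <- bucket_state(soil = 0, snow = 0)
  step3 <- aet_bucket(60, 30, -10, s3)
  expect_equal(step3$aet, 0)
  expect_equal(step3$state$snow, 60)
})

test_that("vectorized field bucket matches the scalar path", {
  set.seed(32)
  precip <- matrix(runif(36, 0, 150), 3, 12)
  pet <- matrix(runif(36, 0, 120), 3, 12)
  Tm <- matrix(runif(36, -10, 25), 3, 12)
  fld <- run_bucket_field(precip, pet, Tm, spinup_months = 24)
  for (i in 1:3) {
    one <- run_bucket(precip[i, ], pet[i, ], Tm[i, ],
                      spinup_months = 24)
    expect_equal(fld$aet[i, ], one$aet)
    expect_equal(fld$runoff[i, ], one$runoff)
  }
})

test_that("surface pressure follows the barometric formula", {
  expect_equal(surface_pressure(0), 101.3)
  expect_equal(surface_pressure(1000),
               101.3 * ((293 - 6.5) / 293)^5.26)
  z <- seq(0, 4000, by = 500)
  expect_true(all(diff(surface_pressure(z)) < 0))
  expect_error(surface_pressure(-600), "-500")
})
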