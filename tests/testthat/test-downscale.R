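test_that("bilinear regridding is exact on constants and planes", {
  gs <- tiny_grids()
  const <- matrix(3.7, gs$coarse$n_lon, gs$coarse$n_lat)
  out <- bilinear_regrid(const, gs$coarse, gs$fine)
  expect_equal(out, matrix(3.7, gs$fine$n_lon, gs$fine$n_lat))

  plane <- outer(gs$coarse$lon, gs$coarse$lat, function(x, y) 2 * x + 3 * y)
  out <- bilinear_regrid(plane, gs$coarse, gs$fine)
  truth <- outer(gs$fine$lon, gs$fine$lat, function(x, y) 2 * x + 3 * y)
  # exactness holds inside the hull of coarse centres; edge cells use
  # nearest-inside extension and are checked for monotonicity instead
  inside_x <- gs$fine$lon >= gs$coarse$lon[1] &
    gs$fine$lon <= gs$coarse$lon[gs$coarse$n_lon]
  inside_y <- gs$fine$lat >= gs$coarse$lat[1] &
    gs$fine$lat <= gs$coarse$lat[gs$coarse$n_lat]
  expect_equal(out[inside_x, inside_y], truth[inside_x, inside_y])
  expect_true(all(out >= min(plane) & out <= max(plane)))
})

test_that("bilinear weights match the 4-point formula at a hand point", {
  cg <- make_grid(0, 6, 0, 6, 2)   # centres 1,3,5
  set.seed(7)
  f <- matrix(rnorm(9), 3, 3)
  fg <- make_grid(1.5, 2.5, 1.5, 2.5, 1)  # single centre at (2, 2)
  out <- bilinear_regrid(f, cg, fg)
  tx <- (2 - 1) / 2; ty <- (2 - 1) / 2
  manual <- (1 - tx) * (1 - ty) * f[1, 1] + tx * (1 - ty) * f[2, 1] +
    (1 - tx) * ty * f[1, 2] + tx * ty * f[2, 2]
  expect_equal(out[1, 1], manual)
})

test_that("bilinear output without extension is missing outside the hull", {
  gs <- tiny_grids()
  f <- matrix(1:(gs$coarse$n_lon * gs$coarse$n_lat), gs$coarse$n_lon)
  out <- bilinear_regrid(f, gs$coarse, gs$fine, extend = FALSE)
  expect_true(is.na(out[1, 1]))      # fine centre 0.25 < first coarse 1
  expect_false(anyNA(out[5:15, 5:8]))
})

test_that("change-factor methods are identities under no model change", {
  gs <- tiny_grids()
  set.seed(1)
  ref <- matrix(runif(gs$coarse$n_lon * gs$coarse$n_lat, 5, 10),
                gs$coarse$n_lon)
  obs <- matrix(runif(gs$fine$n_lon * gs$fine$n_lat, 0, 30), gs$fine$n_lon)
  expect_equal(downscale_additive(ref, ref, obs, gs$coarse, gs$fine), obs)
  expect_equal(downscale_factor(ref, ref, obs, gs$coarse, gs$fine), obs)

  expect_equal(downscale_additive(ref + 2, ref, obs, gs$coarse, gs$fine),
               obs + 2)
  expect_equal(downscale_factor(2 * ref, ref, obs, gs$coarse, gs$fine),
               2 * obs)
})

test_that("downscaling composes with the regrid oracle", {
  gs <- tiny_grids()
  set.seed(2)
  ref <- matrix(runif(15, 5, 10), gs$coarse$n_lon)
  tgt <- ref + matrix(rnorm(15), gs$coarse$n_lon)
  obs <- matrix(runif(gs$fine$n_lon * gs$fine$n_lat, 0, 30), gs$fine$n_lon)
  expect_equal(downscale_additive(tgt, ref, obs, gs$coarse, gs$fine),
               obs + bilinear_regrid(tgt - ref, gs$coarse, gs$fine))
  tgt_pos <- ref * matrix(runif(15, 0.5, 2), gs$coarse$n_lon)
  expect_equal(downscale_factor(tgt_pos, ref, obs, gs$coarse, gs$fine),
               obs * bilinear_regrid(tgt_pos / ref, gs$coarse, gs$fine))
  expect_error(downscale_additive(tgt[1:2, ], ref, obs, gs$coarse,
                                  gs$fine), "mismatch")
  expect_error(downscale_factor(-tgt_pos, ref, obs, gs$coarse, gs$fine),
               "non-negative")
})

test_that("shortwave gamma transform round-trips and respects bounds", {
  expect_equal(shortwave_gamma(200, 200, 400, 400), matrix(1)[1, 1])
  expect_equal(shortwave_gamma(100, 200, 400, 400), 2)  # 0.25 = 0.5^2

  set.seed(3)
  B <- 400
  s0 <- runif(50, 0.05, 0.95)
  s_alt <- runif(50, 0.05, 0.95)
  g <- shortwave_gamma(s_alt * B, s0 * B, B, B)
  expect_true(all(g > 0))
  back <- apply_gamma(s0, g, B)
  expect_equal(back, s_alt * B, tolerance = 1e-12)

  expect_equal(apply_gamma(0.6, 0.5, 400), 400 * sqrt(0.6))
  expect_equal(apply_gamma(0.9, 1e6, 400), 0, tolerance = 1e-9)
  # polar night flagged
  expect_true(is.na(shortwave_gamma(0.5, 100, 0.5, 400)))
  expect_equal(apply_gamma(0.5, 1, 0.2), 0)
})
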