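test_that("summary-name grammar matches the populated naming table", {
  expect_true("qt-lwr-TMIN" %in% summary_names("TMIN"))
  expect_false("qt-hgr-TMIN" %in% summary_names("TMIN"))
  expect_false("mo-hgr-TMIN" %in% summary_names("TMIN"))
  expect_true(all(c("qt-hgr-TMAX", "mo-hgr-TMAX") %in%
                    summary_names("TMAX")))
  expect_equal(summary_names("PRCP")[1:2], c("an-sum-PRCP", "an-cv-PRCP"))
  expect_equal(summary_names("GDD")[2], "an-sd-GDD")
  expect_equal(summary_names("ETR")[1], "an-avg-ETR")
  expect_equal(summary_names("WDI")[1], "an-sum-WDI")
  expect_equal(length(summary_names("PRCP")), 6)
  expect_equal(length(summary_names("TMIN")), 4)
})

test_that("paleo windows hold 20 decades with truncated end windows", {
  w <- build_windows("paleo", run_range = c(-2200, 3))
  centers <- vapply(w, function(x) x$center_ka, numeric(1))
  expect_equal(max(centers), 22)
  expect_equal(min(centers), 0)
  # interior windows have exactly 20 decadal members
  interior <- w[centers > 0 & centers < 22]
  expect_true(all(vapply(interior, function(x) length(x$decades),
                         integer(1)) == 20L))
  # the 0.5 ka window spans 0.4-0.6 ka
  w05 <- w[[which(centers == 0.5)]]
  yrs <- decade_to_years(w05$decades)
  expect_equal(range(yrs), c(1351, 1550))
  expect_equal(length(w05$decades), 20L)
  # 0 ka window truncated by the end of the run: 1851-1990
  w0 <- w[[which(centers == 0)]]
  expect_equal(range(decade_to_years(w0$decades)), c(1851, 1990))
  # a run ending at decade -1 truncates to 1851-1950
  w_ec <- build_windows("paleo", run_range = c(-2100, -1))
  c_ec <- vapply(w_ec, function(x) x$center_ka, numeric(1))
  w0e <- w_ec[[which(c_ec == 0)]]
  expect_equal(range(decade_to_years(w0e$decades)), c(1851, 1950))
})

test_that("future ladder is 20-year windows at 10-year steps", {
  w <- build_windows("future")
  expect_equal(w[[1]]$label, "1950-2005")
  expect_equal(c(w[[2]]$start_year, w[[2]]$end_year), c(2011, 2030))
  expect_equal(c(w[[9]]$start_year, w[[9]]$end_year), c(2081, 2100))
  expect_equal(length(w), 9L)
  # consecutive ladder windows overlap by exactly 10 years
  for (k in 3:9) {
    expect_equal(w[[k]]$start_year - w[[k - 1]]$start_year, 10)
    expect_equal(length(intersect(w[[k]]$years, w[[k - 1]]$years)), 10L)
  }
})

test_that("window statistics reduce correctly on degenerate input", {
  cst <- rep(8, 12)
  s <- summarize_window(list(cst), "PRCP")
  expect_equal(s[["an-sum-PRCP"]], 96)
  expect_equal(s[["an-cv-PRCP"]], 0)
  expect_equal(s[["mo-lwr-PRCP"]], 8)
  expect_equal(s[["mo-hgr-PRCP"]], 8)
  expect_equal(s[["qt-hgr-PRCP"]], 24)   # quarterly total of a sum-type

  single <- rep(0, 12); single[7] <- 90
  s2 <- summarize_window(list(single), "PRCP")
  expect_equal(s2[["qt-hgr-PRCP"]], 90)  # JJA quarter holds the burst
  expect_equal(s2[["mo-lwr-PRCP"]], 0)
  expect_equal(s2[["mo-hgr-PRCP"]], 90)
})

test_that("window statistics equal brute-force recomputation", {
  set.seed(51)
  members <- lapply(1:5, function(k) array(runif(2 * 2 * 12, 0, 50),
                                           c(2, 2, 12)))
  s <- summarize_window(members, "PRCP")
  # brute force at one cell
  xs <- sapply(members, function(m) m[2, 1, ])   # 12 x 5
  expect_equal(s[["an-sum-PRCP"]][2, 1], mean(colSums(xs)))
  expect_equal(s[["an-cv-PRCP"]][2, 1],
               mean(apply(xs, 2, function(v) sd(v) / mean(v))))
  expect_equal(s[["mo-hgr-PRCP"]][2, 1], mean(apply(xs, 2, max)))
  expect_equal(s[["mo-lwr-PRCP"]][2, 1], mean(apply(xs, 2, min)))
  qt <- apply(xs, 2, function(v) {
    c(sum(v[c(1, 2, 12)]), sum(v[3:5]), sum(v[6:8]), sum(v[9:11]))
  })
  expect_equal(s[["qt-lwr-PRCP"]][2, 1], mean(apply(qt, 2, min)))
  expect_equal(s[["qt-hgr-PRCP"]][2, 1], mean(apply(qt, 2, max)))
  # temperature statistics use averages and sd
  st <- summarize_window(members, "TMAX")
  expect_equal(st[["an-avg-TMAX"]][2, 1], mean(colMeans(xs)))
  expect_equal(st[["an-sd-TMAX"]][2, 1], mean(apply(xs, 2, sd)))
})

test_that("moisture indices follow their definitions", {
  aet <- matrix(c(10, 20), 1); pet <- matrix(c(10, 40), 1)
  pr <- matrix(c(50, 10), 1)
  out <- derive_etr_wdi(aet, pet, pr)
  expect_equal(out$etr, matrix(c(1, 0.5), 1))
  expect_equal(out$wdi, matrix(c(-40, 30), 1))
  out0 <- derive_etr_wdi(matrix(0), matrix(0), matrix(5))
  expect_true(is.na(out0$etr[1, 1]))
})

test_that("anomaly cross-correlation recovers trivial and planted values", {
  g <- make_grid(0, 2, 0, 2, 1)
  set.seed(52)
  s <- make_correlated_series(g, n_months = 240, rho = 0.6)
  expect_equal(crosscorr_monthly_anomalies(s$a, s$a),
               matrix(1, 2, 2))
  # perfectly anti-correlated anomalies
  clim <- array(rep(1:12, each = 4), c(2, 2, 12))
  cyc <- array(rep(clim, 20), c(2, 2, 240))
  noise <- array(rnorm(2 * 2 * 240), c(2, 2, 240))
  expect_equal(crosscorr_monthly_anomalies(cyc + noise, cyc - noise),
               matrix(-1, 2, 2))
  # planted correlation within sampling bounds at n = 660
  s2 <- make_correlated_series(g, n_months = 660, rho = 0.6)
  r <- crosscorr_monthly_anomalies(s2$a, s2$b)
  expect_true(all(abs(r - 0.6) < 0.06))
})
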