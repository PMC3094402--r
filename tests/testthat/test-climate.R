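# one synthetic year of daily records
make_daily <- function(tmean, tmin, tmax, prcp, year = 2001) {
  dates <- seq(as.Date(paste0(year, "-01-01")),
               as.Date(paste0(year, "-12-31")), by = "day")
  data.frame(date = dates,
             tmean = rep_len(tmean, length(dates)),
             tmin = rep_len(tmin, length(dates)),
             tmax = rep_len(tmax, length(dates)),
             prcp = rep_len(prcp, length(dates)))
}

test_that("climate summaries propagate constants and average sinusoids analytically", {
  st <- station_record("c1", -10, 500, make_daily(25, 20, 30, 3))
  s <- summarize_climate(st, gravid_months = c(12, 1))
  expect_equal(unname(s["AP"]), 365 * 3)
  expect_equal(unname(s["AMT"]), 25)
  expect_equal(unname(s[c("AMinT", "AMaxT")]), c(20, 30))
  expect_equal(unname(s["MT"]), 25)
  expect_equal(unname(s["MP"]), 3 * 31)  # Dec and Jan both have 31 days
  expect_true(s["AMinT"] <= s["AMT"] && s["AMT"] <= s["AMaxT"])

  # sinusoidal year, gravid months Dec + Jan: compare to the day-count mean
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tm <- 22 + 5 * cos(2 * pi * (doy - 15) / 365)
  st2 <- station_record("c2", -20, 100,
                        data.frame(date = dates, tmean = tm, tmin = tm - 5,
                                   tmax = tm + 5, prcp = 2))
  s2 <- summarize_climate(st2, gravid_months = c(12, 1))
  sel <- as.integer(format(dates, "%m")) %in% c(12, 1)
  expect_equal(unname(s2["MT"]), mean(tm[sel]), tolerance = 1e-10)
  expect_equal(unname(s2["AMT"]), mean(tm), tolerance = 1e-10)

  # two identical years give the same summary as one
  st3 <- station_record("c3", -10, 500,
                        rbind(make_daily(25, 20, 30, 3, 2001),
                              make_daily(25, 20, 30, 3, 2002)))
  expect_equal(unname(summarize_climate(st3, c(12, 1))), unname(s))

  expect_error(summarize_climate(st, gravid_months = integer(0)), "non-empty")
  jan_only <- st
  jan_only$daily <- st$daily[as.integer(format(st$daily$date, "%m")) != 6, ]
  expect_error(summarize_climate(jan_only, 6), "full year|absent")
})

test_that("PCA retains the generating two-factor structure", {
  sim <- simulate_climate_matrix(60, seed = 12)
  cs <- reduce_climate(sim$M)
  expect_equal(cs$retained, 2L)
  # temperature variables load on one retained component, precipitation on the other
  temp_vars <- c("AMT", "AMinT", "AMaxT", "MT", "MMinT", "MMaxT")
  prcp_vars <- c("AP", "MP")
  L <- abs(cs$loadings[, 1:2])
  temp_cc <- which.max(colSums(L[temp_vars, ]))
  prcp_cc <- 3L - temp_cc
  expect_true(all(L[temp_vars, temp_cc] > 0.8))
  expect_true(all(L[prcp_vars, prcp_cc] > 0.8))
  # retained scores track their generating factors
  expect_gt(abs(cor(cs$scores[, temp_cc], sim$temperature)), 0.95)
  expect_gt(abs(cor(cs$scores[, prcp_cc], sim$precipitation)), 0.95)
  # standardized scores
  expect_equal(colMeans(cs$scores), c(CC1 = 0, CC2 = 0), tolerance = 1e-10)
  expect_equal(apply(cs$scores, 2, sd), c(CC1 = 1, CC2 = 1), tolerance = 1e-10)
  # percent variance identity
  expect_equal(cs$pct_var, 100 * cs$eigenvalues / 8, tolerance = 1e-10)
  expect_lte(sum(cs$pct_var[1:2]), 100)
})

test_that("PCA handles duplicated and degenerate variables", {
  set.seed(99)
  M <- cbind(a = rnorm(30), b = rnorm(30))
  M <- cbind(M, a2 = M[, "a"] + rnorm(30, sd = 1e-8))
  cs <- reduce_climate(M)
  expect_equal(abs(cs$loadings["a", 1]), abs(cs$loadings["a2", 1]),
               tolerance = 1e-3)
  expect_error(reduce_climate(cbind(M, k = rep(1, 30))), "constant column")
  expect_error(reduce_climate(M[1:2, ]), "at least 3")

  # pure-noise null: eigenvalues hover around 1, few retained
  set.seed(100)
  Mn <- matrix(rnorm(8 * 1000), ncol = 8,
               dimnames = list(NULL, paste0("v", 1:8)))
  csn <- reduce_climate(Mn)
  expect_lte(csn$retained, 4L)
  expect_true(all(abs(csn$pct_var - 12.5) < 3))
})

test_that("station matching applies the altitude-latitude equivalence", {
  a <- station_record("A", latitude = -10 , altitude = 600)
  b <- station_record("B", latitude = -10 - 200 / 111.32, altitude = 500)
  # A: 100 m altitude difference (cost 100 km); B: 200 km latitude difference
  pick <- match_station(c(-10, 500), list(a, b))
  expect_equal(pick$id, "A")
  expect_equal(attr(pick, "cost"), 100, tolerance = 1e-6)

  co <- station_record("C", latitude = -10, altitude = 500)
  pick2 <- match_station(c(-10, 500), list(a, b, co))
  expect_equal(pick2$id, "C")
  expect_equal(attr(pick2, "cost"), 0)

  # mirrored offsets tie: the latitude-closer station (M1) wins, always
  m1 <- station_record("M1", latitude = -10, altitude = 550)           # 50 m
  m2 <- station_record("M2", latitude = -10 - 50 / 111.32, altitude = 500) # 50 km
  for (r in 1:3)
    expect_equal(match_station(c(-10, 500), list(m1, m2))$id, "M1")
  for (r in 1:3)
    expect_equal(match_station(c(-10, 500), list(m2, m1))$id, "M1")

  # doubling the tradeoff can only shift choices toward latitude-closer stations
  pick_hi <- match_station(c(-10, 500), list(a, b), tradeoff = 200)
  expect_equal(pick_hi$id, "B")
  expect_error(match_station(c(-10, 500), list()), "empty")
})

test_that("tradeoff calibration recovers constructed coefficients", {
  set.seed(7)
  st <- data.frame(latitude = runif(30, -25, -5), altitude = runif(30, 0, 1500))
  st$score <- 0.01 * st$latitude * 111.32 + 0.01 * st$altitude
  expect_equal(calibrate_tradeoff(st), 100, tolerance = 1e-6)

  st2 <- st
  st2$score <- 0.02 * st2$latitude * 111.32 + rnorm(30, sd = 1e-12)
  expect_lt(calibrate_tradeoff(st2), 1e-6)

  st3 <- st
  st3$altitude <- st3$latitude * 10
  expect_error(calibrate_tradeoff(st3), "collinear")
  expect_error(calibrate_tradeoff(st[1:5, ]), "at least 10")
})
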