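test_that("VPD follows the Magnus saturation curve", {
  expect_equal(compute_vpd(20, 100), 0)
  # hand evaluation: e_s(20) = 0.6108 exp(345.4/257.3) = 2.3383 kPa
  expect_equal(compute_vpd(20, 50), 1.169, tolerance = 1e-3)
  expect_equal(compute_vpd(0, 0), 0.6108)
  expect_error(compute_vpd(20, 101), "humidity")
  expect_error(compute_vpd(20, -1), "humidity")
})

test_that("VPD is zero only at saturation and increases with temperature", {
  t <- seq(-5, 35, by = 2.5)
  expect_true(all(compute_vpd(t, 100) == 0))
  for (rh in c(0, 40, 95)) {
    v <- compute_vpd(t, rh)
    expect_true(all(v > 0))
    expect_true(all(diff(v) > 0))
  }
})

test_that("Thornthwaite PET matches its closed form and cold limit", {
  expect_equal(compute_pet_thornthwaite(rep(-3, 12), latitude = 46),
               rep(0, 12))
  # uniform 10 C, 12 h daylength, 30-day months:
  # I = 12 (10/5)^1.514 = 34.27, a = 1.0433, PET = 16 (100/I)^a = 48.89
  pet <- compute_pet_thornthwaite(rep(10, 12), daylength = rep(12, 12),
                                  days_in_month = rep(30, 12))
  expect_equal(pet, rep(48.89, 12), tolerance = 1e-3)
  # daylength enters linearly
  pet6 <- compute_pet_thornthwaite(rep(10, 12), daylength = rep(6, 12),
                                   days_in_month = rep(30, 12))
  expect_equal(pet6, pet / 2)
})

test_that("Thornthwaite annual PET is non-decreasing under uniform warming", {
  t0 <- c(-6, -4, 0, 4, 9, 13, 15, 14, 10, 5, -1, -5)
  totals <- vapply(seq(0, 4, by = 0.5), function(dt) {
    sum(compute_pet_thornthwaite(t0 + dt, latitude = 46.7))
  }, 0)
  expect_true(all(diff(totals) >= 0))
})

test_that("FAO-56 daily reference ET matches an independent re-coding", {
  # oracle: step-by-step scalar transcription of the published daily
  # combination equation (G = 0, albedo 0.23, standard net longwave)
  oracle_et0 <- function(tmin, tmax, rh, rs, u2, doy, lat, elev) {
    es_t <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
    tmean <- (tmin + tmax) / 2
    p <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
    gam <- 0.000665 * p
    del <- 4098 * es_t(tmean) / (tmean + 237.3)^2
    es <- (es_t(tmin) + es_t(tmax)) / 2
    ea <- es * rh / 100
    phi <- lat * pi / 180
    dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
    dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
    ws <- acos(-tan(phi) * tan(dec))
    ra <- 24 * 60 / pi * 0.082 * dr *
      (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
    rso <- (0.75 + 2e-5 * elev) * ra
    rns <- 0.77 * rs
    rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
      (0.34 - 0.14 * sqrt(ea)) * (1.35 * min(rs / rso, 1) - 0.35)
    rn <- rns - rnl
    num <- 0.408 * del * rn + gam * 900 / (tmean + 273) * u2 * (es - ea)
    max(num / (del + gam * (1 + 0.34 * u2)), 0)
  }
  # mid-latitude summer day with measured radiation
  args <- list(tmin = 12.3, tmax = 21.5, rh = 73, rs = 22.07,
               u2 = 2.078, doy = 187, lat = 50.8, elev = 100)
  want <- do.call(oracle_et0, args)
  got <- compute_pet_fao56(t_mean = (12.3 + 21.5) / 2, rh_mean = 73,
                           rs = 22.07, wind = 2.078, doy = 187,
                           latitude = 50.8, elevation = 100,
                           t_min = 12.3, t_max = 21.5)
  expect_equal(got, want, tolerance = 0.01)
  expect_gt(got, 2) # plausible summer magnitude, mm/day
  expect_lt(got, 8)
})

test_that("FAO-56 ET is zero without demand and increases with wind", {
  # saturated, calm midwinter day with net radiative loss: the aerodynamic
  # term vanishes (e_s = e_a) and the radiation term is negative, so the
  # physical clip at zero applies
  z <- compute_pet_fao56(t_mean = 0, rh_mean = 100, rs = 0.5, wind = 0,
                         doy = 355, latitude = 60, elevation = 0)
  expect_equal(z, 0)
  p1 <- compute_pet_fao56(20, 50, 20, 1, 180, 46.7, 1000,
                          t_min = 14, t_max = 26)
  p2 <- compute_pet_fao56(20, 50, 20, 2, 180, 46.7, 1000,
                          t_min = 14, t_max = 26)
  expect_gt(p2, p1)
})

test_that("daily aggregation uses means and sums and conserves precipitation", {
  ts <- seq(as.POSIXct("2013-06-01 00:00", tz = "UTC"),
            as.POSIXct("2013-06-03 23:50", tz = "UTC"), by = 600)
  met <- data.frame(timestamp = ts, t_air = 5, rh = 60,
                    precip = 0.1, rs = 0.05,
                    swc_05 = 0.10, swc_20 = 0.20, swc_50 = 0.30)
  d <- aggregate_daily(met)
  expect_equal(nrow(d), 3L)
  expect_equal(d$t_mean, rep(5, 3))
  expect_equal(d$precip, rep(14.4, 3), tolerance = 1e-12)
  expect_equal(d$swc_mean, rep(0.2, 3))
  expect_equal(sum(d$precip), sum(met$precip))
  # no-mass-loss property on a random series
  set.seed(4)
  met$precip <- rexp(nrow(met), 10)
  d2 <- aggregate_daily(met)
  expect_equal(sum(d2$precip), sum(met$precip))
})

test_that("incomplete days are flagged missing, not silently aggregated", {
  ts <- seq(as.POSIXct("2013-06-01 00:00", tz = "UTC"),
            by = 600, length.out = 144 + 10) # one full day + a stub
  met <- data.frame(timestamp = ts, t_air = 5, rh = 60, precip = 0, rs = 0)
  d <- aggregate_daily(met)
  expect_true(d$complete[1])
  expect_false(d$complete[2])
  expect_true(is.na(d$t_mean[2]))
})

test_that("gap filling interpolates short spans only and reports them", {
  ts <- seq(as.POSIXct("2013-06-01", tz = "UTC"), by = 600,
            length.out = 100)
  met <- data.frame(timestamp = ts, t_air = seq(4, 6, length.out = 100),
                    precip = 0.2)
  met$t_air[50] <- NA        # single gap
  met$t_air[70:90] <- NA     # long gap (21 > max_gap)
  met$precip[10:12] <- NA
  filled <- fill_gaps(met, max_gap = 6L)
  expect_equal(filled$t_air[50], (met$t_air[49] + met$t_air[51]) / 2)
  expect_true(all(is.na(filled$t_air[70:90])))
  expect_equal(filled$precip[10:12], rep(0, 3))
  rep_df <- attr(filled, "gap_report")
  expect_equal(sum(rep_df$n), 1L + 3L)
  expect_setequal(rep_df$method, c("linear", "zero"))
})

test_that("elevational extrapolation shifts temperature and scales rain", {
  days <- data.frame(date = seq(as.Date("2013-01-01"), by = 1,
                                length.out = 365),
                     t_mean = 10, precip = 0)
  days$precip[seq(5, 365, by = 10)] <- 10 # 370 mm/yr in events
  up <- lapse_extrapolate(days, 1000, lapse_spec(0.54, 12))
  expect_equal(unique(up$t_mean), 10 - 5.4)
  expect_equal(sum(up$precip) - sum(days$precip), 120, tolerance = 1e-9)
  expect_true(all(up$precip[days$precip == 0] == 0)) # dry days stay dry
  # +500 m adds 60 mm/yr at 12 mm per 100 m
  up5 <- lapse_extrapolate(days, 500, lapse_spec(0.54, 12))
  expect_equal(sum(up5$precip) - sum(days$precip), 60, tolerance = 1e-9)
  # identity and invertibility
  expect_equal(lapse_extrapolate(days, 0, lapse_spec()), days)
  back <- lapse_extrapolate(up, -1000, lapse_spec(0.54, 12))
  expect_equal(back$t_mean, days$t_mean, tolerance = 1e-9)
  expect_equal(back$precip, days$precip, tolerance = 1e-6)
})

test_that("the printed transect lapse arithmetic reproduces", {
  expect_equal(lapse_per_100m(3.7, 1160, 1715), 0.67, tolerance = 0.005)
})
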