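test_that("generators are pure functions of their seed", {
  a <- gen_microclimate(1160, seed = 5)
  b <- gen_microclimate(1160, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$t_air,
                         gen_microclimate(1160, seed = 6)$t_air))
  cd <- make_daily_climate()
  expect_identical(gen_dendrometer(cd, seed = 3), gen_dendrometer(cd, seed = 3))
  expect_identical(gen_sapflow(cd, seed = 3, step_min = 60),
                   gen_sapflow(cd, seed = 3, step_min = 60))
  st <- gen_station_monthly(1990:2000, seed = 2)
  expect_identical(st, gen_station_monthly(1990:2000, seed = 2))
  expect_identical(gen_ringwidths(st, 1991:2000, n_trees = 2, beta = NULL,
                                  seed = 4),
                   gen_ringwidths(st, 1991:2000, n_trees = 2, beta = NULL,
                                  seed = 4))
})

test_that("microclimate respects physical bounds and the elevation lapse", {
  met <- gen_microclimate(1715, seed = 2)
  expect_true(all(met$rh >= 0 & met$rh <= 100))
  expect_true(all(met$precip >= 0))
  expect_true(all(met$rs >= 0))
  expect_true(all(met$swc_20 >= 0.05 & met$swc_20 <= 0.4))
  expect_true(!is.unsorted(as.numeric(met$timestamp), strictly = TRUE))
  # lapse structure: 555 m apart at 0.54 K/100 m -> 3.0 K annual difference
  for (s in 1:3) {
    lo <- gen_microclimate(1160, seed = s)
    hi <- gen_microclimate(1715, seed = 100 + s)
    expect_equal(mean(lo$t_air) - mean(hi$t_air), 0.54 * 555 / 100,
                 tolerance = 0.02)
  }
})

test_that("dendrometer traces embody the zero-growth construction", {
  cd <- make_daily_climate()
  # noise- and shrink-free: partition recovers A exactly, TWD identically 0
  circ <- gen_dendrometer(cd, twd_scale = 0, noise_sd = 0, seed = 1)
  tr <- circumference_to_radius(data.frame(timestamp = circ$timestamp,
                                           circ = circ$circ))
  p <- partition_zero_growth(tr)
  expect_equal(max(p$twd), 0)
  expect_equal(max(p$gro) - min(p$gro), 1500, tolerance = 0.005)
  truth <- attr(circ, "truth")
  expect_equal(truth$A, 1500)
})

test_that("a scripted drought raises TWD above 100 um and relaxes after", {
  drought <- data.frame(start_doy = 175, end_doy = 200, swc_floor = 0.09)
  for (s in 1:3) {
    met <- gen_microclimate(1160, seed = s, drought = drought)
    cd <- aggregate_daily(met)
    circ <- gen_dendrometer(cd, seed = 50 + s)
    tr <- circumference_to_radius(data.frame(timestamp = circ$timestamp,
                                             circ = circ$circ))
    d <- daily_stem_stats(partition_zero_growth(tr))
    doy <- as.integer(format(d$date, "%j"))
    expect_gt(max(d$twd_max[doy >= 175 & doy <= 200]), 100)
    expect_lt(d$twd_max[doy == 205], 20)
  }
})

test_that("sap flow saturates with demand and collapses under drought", {
  cd <- make_daily_climate(doy = 150:250, swc = c(rep(0.25, 40),
                                                  rep(0.09, 20),
                                                  rep(0.25, 41)))
  sf <- gen_sapflow(cd, step_min = 60, seed = 4)
  d <- daily_sap_flow(scale_to_tree(sf, 100, 1))
  pre <- mean(d$flow_l[1:40])
  dry <- mean(d$flow_l[41:60])
  expect_lt(dry, 0.7 * pre) # >= 30% reduction
  # no-demand day: near-zero flow
  cd0 <- make_daily_climate(doy = 150:160)
  cd0$pet <- 0
  d0 <- daily_sap_flow(scale_to_tree(gen_sapflow(cd0, step_min = 60,
                                                 seed = 1), 100, 1))
  expect_lt(max(d0$flow_l), 1)
})

test_that("the high-elevation configuration decouples flow from soil water", {
  met <- gen_microclimate(1990, seed = 21)
  cd <- aggregate_daily(met)
  cd$pet <- compute_pet_fao56(cd$t_mean, cd$rh_mean, cd$rs_sum,
                              cd$wind_mean,
                              as.integer(format(cd$date, "%j")),
                              46.7, 1990, t_min = cd$t_min,
                              t_max = cd$t_max)
  cd <- cd[as.integer(format(cd$date, "%j")) %in% 150:250, ]
  sf <- gen_sapflow(cd, soil_limited = FALSE, step_min = 60, seed = 22)
  d <- daily_sap_flow(scale_to_tree(sf, 100, 1))
  rho <- cor(d$flow_l, cd$swc_mean[match(d$date, cd$date)],
             method = "spearman")
  expect_lt(abs(rho), 0.35)
})

test_that("ring ensembles hit their interseries-correlation target", {
  st <- gen_station_monthly(1949:2029, seed = 6)
  rwl <- gen_ringwidths(st, 1950:2029, n_trees = 10, rbar_target = 0.5,
                        seed = 6)
  expect_equal(ncol(rwl), 20L) # two cores per tree
  trees <- average_cores_to_tree(rwl)
  pw <- prewhiten_rwl(detrend_rwl(trees))
  stats <- chronology_stats(trees, prewhitened = pw)
  expect_equal(stats$eps, eps_from_rbar(0.5, 10), tolerance = 0.05)
  expect_true(all(as.matrix(rwl) > 0, na.rm = TRUE))
})

test_that("generated series survive the package file formats losslessly", {
  met <- gen_microclimate(1160, seed = 9)[1:200, ]
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(met, p, row.names = FALSE)
  back <- utils::read.csv(p)
  expect_equal(back$t_air, met$t_air, tolerance = 1e-10)
  expect_equal(back$precip, met$precip, tolerance = 1e-10)
  st <- gen_station_monthly(1990:2009, seed = 3)
  rwl <- gen_ringwidths(st, 1991:2009, n_trees = 3, beta = NULL, seed = 3)
  rwl[] <- lapply(rwl, round) # written at 1 um resolution
  p2 <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(rwl, p2)
  expect_equal(as.matrix(read_rwl(p2)), as.matrix(rwl), tolerance = 1e-12,
               ignore_attr = TRUE)
})
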