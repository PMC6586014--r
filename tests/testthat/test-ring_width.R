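test_that("core averaging uses available cores and rejects zero overlap", {
  a <- c(1000, 1200, 1400); attr(a, "first_year") <- 2000
  b <- c(1200, 1000, NA); attr(b, "first_year") <- 2000
  rwl <- as_rwl(list(T01A = a, T01B = b))
  tr <- average_cores_to_tree(rwl)
  expect_equal(names(tr), "T01")
  expect_equal(tr$T01, c(1100, 1100, 1400)) # last year: single core
  # identical cores: identity
  rwl2 <- as_rwl(list(T02A = a, T02B = a))
  expect_equal(average_cores_to_tree(rwl2)$T02, as.numeric(a))
  # disjoint cores: error
  c1 <- c(1, 2); attr(c1, "first_year") <- 2000
  c2 <- c(3, 4); attr(c2, "first_year") <- 2005
  expect_error(average_cores_to_tree(as_rwl(list(T03A = c1, T03B = c2))),
               "overlap")
})

test_that("BAI follows the ring-area algebra", {
  # widths all 1 mm: BAI = pi (2t - 1)
  bai <- compute_bai(rep(1000, 5))
  expect_equal(bai, pi * c(1, 3, 5, 7, 9), tolerance = 1e-12)
  expect_equal(compute_bai(700), pi * 0.49, tolerance = 1e-12)
  # telescoping conservation on random series
  for (s in 1:10) {
    set.seed(s)
    w <- runif(80, 200, 3000)
    expect_equal(sum(compute_bai(w)), pi * (sum(w) / 1000)^2,
                 tolerance = 1e-9)
  }
})

test_that("detrending returns unit indices on trend-only input", {
  t <- 1:120
  w <- 1800 * exp(-0.025 * t) + 250
  rwi <- detrend_series(w)
  expect_equal(as.numeric(rwi), rep(1, 120), tolerance = 1e-6)
  expect_equal(attr(rwi, "method"), "negexp")
  # constant series
  rwi2 <- detrend_series(rep(500, 60))
  expect_equal(as.numeric(rwi2), rep(1, 60), tolerance = 1e-9)
})

test_that("detrended noise x trend series centre on one without residual trend", {
  means <- slopes <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    t <- 1:100
    w <- (2000 * exp(-0.02 * t) + 300) * exp(rnorm(100, 0, 0.2))
    rwi <- as.numeric(detrend_series(w))
    means[s] <- mean(rwi)
    slopes[s] <- coef(lm(rwi ~ t))[2]
  }
  expect_lt(max(abs(means - 1)), 0.02)
  expect_lt(max(abs(slopes)), 0.001)
})

test_that("the frequency-cutoff smoother preserves level and damps wiggles", {
  set.seed(8)
  y <- 1 + 0.3 * sin(2 * pi * (1:100) / 8) # short-wavelength signal
  sm <- fcutoff_smooth(y, wavelength = 67)
  expect_equal(mean(sm), mean(y), tolerance = 1e-6)
  expect_lt(sd(sm), 0.1 * sd(y)) # 8-yr cycle far beyond the cutoff
})

test_that("prewhitening removes serial correlation and guards degeneracy", {
  set.seed(21)
  x <- as.numeric(arima.sim(list(ar = 0.7), 120))
  r <- prewhiten(x)
  ac1 <- cor(r[-1], r[-length(r)])
  expect_lt(abs(ac1), 0.1)
  expect_gte(attr(r, "order"), 1L)
  expect_lt(abs(mean(r) - mean(x)), 0.05) # level preserved
  expect_warning(r0 <- prewhiten(rep(1, 50)), "constant")
  expect_equal(as.numeric(r0), rep(1, 50))
})

test_that("white noise mostly selects order zero and passes through", {
  n0 <- 0L
  for (s in 1:40) {
    set.seed(s)
    x <- rnorm(100)
    r <- prewhiten(x)
    if (attr(r, "order") == 0L) {
      n0 <- n0 + 1L
      expect_equal(as.numeric(r), x, tolerance = 1e-6)
    }
  }
  # AIC admits some overfitting; the simulated selection rate is ~75%
  expect_gte(n0, 28L)
})

test_that("the biweight mean discounts outliers", {
  expect_equal(tukey_biweight_mean(c(0.9, 1.0, 1.1)), 1.0)
  expect_lt(abs(tukey_biweight_mean(c(rep(1, 9), 5)) - 1), 0.02)
  expect_true(is.na(tukey_biweight_mean(numeric(0))))
  # compare against plain mean under contamination
  set.seed(2)
  x <- c(rnorm(20, 1, 0.05), 10)
  expect_lt(abs(tukey_biweight_mean(x) - 1), abs(mean(x) - 1))
})

test_that("a single-series chronology is the series itself", {
  w <- c(1.1, 0.9, 1.0, 1.2); attr(w, "first_year") <- 2000
  ch <- build_chronology(as_rwl(list(A = w)))
  expect_equal(ch$index, as.numeric(w))
  expect_equal(ch$sample_depth, rep(1L, 4))
  expect_equal(ch$year, 2000:2003)
})

test_that("chronology statistics match their closed forms", {
  expect_equal(mean_sensitivity(c(2, 1, 2)), 2 / 3)
  expect_equal(mean_sensitivity(rep(7, 10)), 0)
  # scale invariance
  set.seed(3)
  w <- runif(50, 500, 2500)
  for (k in c(0.001, 1, 417)) {
    expect_equal(mean_sensitivity(k * w), mean_sensitivity(w),
                 tolerance = 1e-12)
  }
  expect_equal(eps_from_rbar(0.5, 10), 10 / 11)
  # snr from the same closed form
  st <- chronology_stats(make_rwl_ensemble(n = 4, seed = 5))
  expect_equal(st$snr, 4 * st$rbar / (1 - st$rbar), tolerance = 1e-12)
  expect_equal(st$eps, eps_from_rbar(st$rbar, 4), tolerance = 1e-12)
  # EPS monotone in N, limit 1
  ns <- 2:40
  epss <- eps_from_rbar(0.4, ns)
  expect_true(all(diff(epss) > 0))
  expect_equal(eps_from_rbar(1 - 1e-12, 5), 1, tolerance = 1e-9)
})

test_that("the pipeline recovers an injected common signal", {
  st <- gen_station_monthly(1949:2049, seed = 13)
  rwl <- gen_ringwidths(st, 1950:2049, n_trees = 10, beta = NULL,
                        rbar_target = 0.5, seed = 13)
  truth <- attr(rwl, "truth")
  trees <- average_cores_to_tree(rwl)
  pw <- prewhiten_rwl(detrend_rwl(trees))
  ch <- build_chronology(pw)
  expect_gt(cor(ch$index, truth$common), 0.9)
})

test_that("crossdating QC flags misdated series and clean sets pass", {
  # clean ensemble: no segment flagged
  rwl <- make_rwl_ensemble(n = 5, years = 1900:2049, sd_ind = 0.45,
                           seed = 31)
  qc <- crossdate_qc(rwl)
  expect_true(all(!qc$flagged))
  expect_true(all(qc$best_lag == 0L))
  # identical series: r exactly 1 everywhere
  one <- rwl[, 1]
  same <- as_rwl(stats::setNames(
    lapply(1:3, function(i) {
      v <- one
      attr(v, "first_year") <- 1900
      v
    }), c("A", "B", "C")))
  qc1 <- crossdate_qc(same)
  expect_true(all(qc1$r > 0.999))
  # one series misdated by +1 year (each ring assigned one year too late)
  shifted <- rwl
  shifted[["C01"]] <- c(NA, shifted[["C01"]][-nrow(shifted)])
  qc2 <- crossdate_qc(shifted)
  bad <- qc2[qc2$series == "C01", ]
  expect_true(any(bad$flagged))
  expect_true(any(bad$best_lag == -1L))
})

test_that("Tucson RWL files round-trip in both precision dialects", {
  set.seed(17)
  w1 <- round(runif(73, 300, 2600)); attr(w1, "first_year") <- 1923
  w2 <- round(runif(40, 300, 2600)); attr(w2, "first_year") <- 1951
  rwl <- as_rwl(list(ALP01A = w1, ALP02B = w2))
  for (prec in c(0.001, 0.01)) {
    path <- withr::local_tempfile(fileext = ".rwl")
    write_rwl(rwl, path, precision = prec)
    back <- read_rwl(path)
    expect_equal(rwl_years(back), rwl_years(rwl))
    tol <- if (prec == 0.001) 1e-9 else 5 # half a storage unit, um
    for (nm in names(rwl)) {
      d <- abs(back[[nm]] - rwl[[nm]])
      expect_lte(max(d, na.rm = TRUE), tol)
      expect_identical(is.na(back[[nm]]), is.na(rwl[[nm]]))
    }
  }
  # a genuine 999 um ring must survive the 0.001 mm dialect
  w3 <- c(500, 999, 1200); attr(w3, "first_year") <- 2000
  p <- withr::local_tempfile(fileext = ".rwl")
  write_rwl(as_rwl(list(X = w3)), p, precision = 0.001)
  expect_equal(read_rwl(p)$X, c(500, 999, 1200), ignore_attr = TRUE)
})
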