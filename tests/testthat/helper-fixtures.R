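# Shared fixtures, built in code.

# Small deterministic daily climate table (no weather noise): seasonal
# temperature, fixed VPD shape, constant soil water unless overridden.
make_daily_climate <- function(doy = 60:300, year = 2013, swc = 0.25,
                               vpd = NULL) {
  date <- as.Date(paste0(year, "-01-01")) + doy - 1
  t_mean <- 7 + 9 * cos(2 * pi * (doy - 200) / 365)
  if (is.null(vpd)) vpd <- pmax(0.2 + 0.08 * t_mean, 0)
  data.frame(date = date,
             t_mean = t_mean,
             vpd_mean = vpd,
             pet = pmax(0.3 * t_mean, 0),
             precip = 0,
             swc_mean = rep_len(swc, length(doy)))
}

# Hourly radius trace from a daily radius path (step interpolation).
make_trace <- function(radius, start = "2013-06-01") {
  data.frame(
    timestamp = as.POSIXct(start, tz = "UTC") + 3600 * seq_along(radius),
    radius = radius
  )
}

# rwl with n copies of one AR(1) series plus independent noise
make_rwl_ensemble <- function(n = 6, years = 1950:2049, phi = 0.5,
                              sd_common = 1, sd_ind = 0.7, seed = 1) {
  set.seed(seed)
  ny <- length(years)
  common <- as.numeric(stats::filter(rnorm(ny, 0, sd_common * sqrt(1 - phi^2)),
                                     phi, method = "recursive"))
  cores <- list()
  for (i in seq_len(n)) {
    w <- 1500 * exp(common / 4 + rnorm(ny, 0, sd_ind / 4))
    attr(w, "first_year") <- years[1]
    cores[[sprintf("C%02d", i)]] <- w
  }
  as_rwl(cores)
}
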