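#' Saturation vapour pressure (Magnus / FAO-56 form)
#'
#' @param t_air Air temperature in degrees Celsius.
#' @return Saturation vapour pressure in kPa.
#' @examples
#' svp(20) # ~2.34 kPa
#' @export
svp <- function(t_air) {
  0.6108 * exp(17.27 * t_air / (t_air + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' VPD is the difference between the saturation vapour pressure at air
#' temperature and the actual vapour pressure, \eqn{e_s(T)(1 - RH/100)}.
#' It quantifies the atmospheric demand driving transpiration and diurnal
#' stem shrinkage.
#'
#' @param t_air Air temperature, degrees Celsius.
#' @param rh Relative humidity, percent (0-100). `NA` propagates.
#' @return VPD in kPa, non-negative.
#' @examples
#' compute_vpd(20, 50)
#' compute_vpd(20, 100) # 0 at saturation
#' @export
compute_vpd <- function(t_air, rh) {
  bad <- !is.na(rh) & (rh < 0 | rh > 100)
  if (any(bad)) {
    stop("relative humidity outside [0, 100]")
  }
  vpd <- svp(t_air) * (1 - rh / 100)
  pmax(vpd, 0)
}

#' FAO-56 Penman-Monteith daily reference evapotranspiration
#'
#' Daily grass-reference ET0 following the standard daily formulation:
#' soil heat flux G = 0, albedo 0.23, net longwave from the Stefan-Boltzmann
#' estimate with humidity and cloudiness corrections, psychrometric constant
#' from elevation-dependent pressure. Radiation is taken from measurement
#' (global radiation sum), not from sunshine duration.
#'
#' @param t_mean Daily mean air temperature, degrees C.
#' @param t_min,t_max Daily minimum / maximum temperature, degrees C.
#'   Default to `t_mean` when the sub-daily range is unavailable.
#' @param rh_mean Daily mean relative humidity, percent.
#' @param rs Daily global radiation sum, MJ m-2 d-1.
#' @param wind Daily mean wind speed at 2 m, m s-1.
#' @param doy Day of year (1-366), used for extraterrestrial radiation.
#' @param latitude Site latitude, decimal degrees.
#' @param elevation Site elevation, m a.s.l.
#' @return Reference evapotranspiration, mm d-1, clipped at 0. Any missing
#'   input yields `NA` (never a silent zero).
#' @export
compute_pet_fao56 <- function(t_mean, rh_mean, rs, wind, doy, latitude,
                              elevation, t_min = t_mean, t_max = t_mean) {
  n <- max(length(t_mean), length(rs), length(doy))
  t_mean <- rep_len(t_mean, n); t_min <- rep_len(t_min, n)
  t_max <- rep_len(t_max, n); rh_mean <- rep_len(rh_mean, n)
  rs <- rep_len(rs, n); wind <- rep_len(wind, n); doy <- rep_len(doy, n)

  # atmospheric pressure and psychrometric constant
  pr <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * pr

  delta <- 4098 * svp(t_mean) / (t_mean + 237.3)^2
  es <- (svp(t_min) + svp(t_max)) / 2
  ea <- es * rh_mean / 100

  # extraterrestrial and clear-sky radiation
  ra <- extraterrestrial_radiation(doy, latitude)
  rso <- (0.75 + 2e-5 * elevation) * ra
  rns <- (1 - 0.23) * rs
  rel <- ifelse(rso > 0, pmin(rs / rso, 1), NA_real_)
  sigma <- 4.903e-9
  rnl <- sigma * ((t_max + 273.16)^4 + (t_min + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl

  num <- 0.408 * delta * rn +
    gamma * (900 / (t_mean + 273)) * wind * (es - ea)
  den <- delta + gamma * (1 + 0.34 * wind)
  pet <- num / den
  pmax(pet, 0)
}

#' Extraterrestrial radiation for daily periods
#'
#' @param doy Day of year.
#' @param latitude Latitude, decimal degrees.
#' @return Ra in MJ m-2 d-1.
#' @keywords internal
extraterrestrial_radiation <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(dec)
  ws <- acos(pmin(pmax(x, -1), 1)) # polar day/night guarded
  gsc <- 0.0820
  (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' Mean daylength by month and latitude
#'
#' Standard solar-geometry daylength evaluated at each month's mid day.
#'
#' @param latitude Latitude, decimal degrees.
#' @return Numeric vector of 12 mean daylengths in hours.
#' @export
monthly_daylength <- function(latitude) {
  mid <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  phi <- latitude * pi / 180
  dec <- 0.409 * sin(2 * pi * mid / 365 - 1.39)
  x <- -tan(phi) * tan(dec)
  ws <- acos(pmin(pmax(x, -1), 1))
  24 / pi * ws
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Temperature-based monthly PET: heat index
#' \eqn{I = \sum_{T>0} (T/5)^{1.514}}, exponent
#' \eqn{a = 6.75\times10^{-7} I^3 - 7.71\times10^{-5} I^2 + 0.01792 I + 0.49239},
#' and \eqn{PET_m = 16 (10 T/I)^a (L/12)(d/30)} with L the mean daylength and
#' d the number of days in the month; months with T <= 0 get 0.
#'
#' @param monthly_t Twelve monthly mean temperatures, degrees C (Jan-Dec).
#' @param latitude Latitude in decimal degrees (used for daylength), or
#'   `NULL` to supply `daylength` directly.
#' @param daylength Optional 12 mean daylengths in hours (overrides latitude).
#' @param days_in_month Days per month; defaults to the non-leap calendar.
#' @return Twelve monthly PET values, mm month-1.
#' @examples
#' compute_pet_thornthwaite(rep(10, 12), daylength = rep(12, 12),
#'                          days_in_month = rep(30, 12))
#' @export
compute_pet_thornthwaite <- function(monthly_t, latitude = NULL,
                                     daylength = NULL,
                                     days_in_month = c(31, 28, 31, 30, 31, 30,
                                                       31, 31, 30, 31, 30, 31)) {
  stopifnot(length(monthly_t) == 12L)
  if (is.null(daylength)) {
    if (is.null(latitude)) stop("supply either latitude or daylength")
    daylength <- monthly_daylength(latitude)
  }
  stopifnot(length(daylength) == 12L, length(days_in_month) == 12L)
  warm <- monthly_t > 0
  if (!any(warm)) {
    return(rep(0, 12))
  }
  heat_i <- sum((monthly_t[warm] / 5)^1.514)
  a <- 6.75e-7 * heat_i^3 - 7.71e-5 * heat_i^2 + 1.792e-2 * heat_i + 0.49239
  pet <- rep(0, 12)
  pet[warm] <- 16 * (10 * monthly_t[warm] / heat_i)^a *
    (daylength[warm] / 12) * (days_in_month[warm] / 30)
  pet
}

#' Aggregate a sub-daily meteorological series to daily values
#'
#' Means for temperature, humidity, VPD and soil water content (SWC first
#' averaged across depths), sums for radiation and precipitation. Days whose
#' completeness (fraction of expected intervals with non-missing temperature)
#' falls below `min_complete` are flagged and their aggregates set missing.
#'
#' @param met Data frame with a POSIXct `timestamp` column and any of
#'   `t_air`, `rh`, `rs`, `precip`, `wind`, and one or more `swc*` columns.
#' @param min_complete Minimum fraction of expected intervals per day
#'   (default 0.9).
#' @return Data frame, one row per day: `date`, `t_mean`, `t_min`, `t_max`,
#'   `rh_mean`, `vpd_mean`, `rs_sum`, `precip`, `wind_mean`, `swc_mean`,
#'   `n_obs`, `complete`.
#' @export
aggregate_daily <- function(met, min_complete = 0.9) {
  stopifnot(is.data.frame(met), "timestamp" %in% names(met))
  if (is.unsorted(as.numeric(met$timestamp), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  day <- as.Date(met$timestamp, tz = attr(met$timestamp, "tzone") %||% "UTC")
  swc_cols <- grep("^swc", names(met), value = TRUE)
  swc <- if (length(swc_cols)) {
    rowMeans(as.matrix(met[swc_cols]), na.rm = TRUE)
  } else {
    rep(NA_real_, nrow(met))
  }
  vpd <- if (all(c("t_air", "rh") %in% names(met))) {
    compute_vpd(met$t_air, met$rh)
  } else {
    rep(NA_real_, nrow(met))
  }
  getcol <- function(nm) if (nm %in% names(met)) met[[nm]] else rep(NA_real_, nrow(met))

  # expected intervals per day from the median sampling step
  step <- stats::median(diff(as.numeric(met$timestamp)))
  expected <- max(1, round(86400 / step))

  agg <- function(x, f) as.numeric(tapply(x, day, f))
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sum_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  min_na <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)

  t_air <- getcol("t_air")
  out <- data.frame(
    date = as.Date(names(tapply(t_air, day, length))),
    t_mean = agg(t_air, mean_na),
    t_min = agg(t_air, min_na),
    t_max = agg(t_air, max_na),
    rh_mean = agg(getcol("rh"), mean_na),
    vpd_mean = agg(vpd, mean_na),
    rs_sum = agg(getcol("rs"), sum_na),
    precip = agg(getcol("precip"), sum_na),
    wind_mean = agg(getcol("wind"), mean_na),
    swc_mean = agg(swc, mean_na),
    n_obs = agg(!is.na(t_air), sum),
    stringsAsFactors = FALSE
  )
  out$complete <- out$n_obs / expected >= min_complete
  vars <- c("t_mean", "t_min", "t_max", "rh_mean", "vpd_mean",
            "rs_sum", "precip", "wind_mean", "swc_mean")
  out[!out$complete, vars] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Fill short gaps in a meteorological series
#'
#' Gaps of at most `max_gap` consecutive missing intervals are linearly
#' interpolated (precipitation gaps are set to 0 instead, and reported);
#' longer gaps are left missing. Every filled span is listed in the
#' attached gap report.
#'
#' @param met Data frame as for [aggregate_daily()].
#' @param max_gap Maximum gap length, in intervals, to fill (default 36,
#'   i.e. 6 h at 10-min resolution).
#' @param vars Columns to fill; defaults to all numeric met columns present.
#' @return The filled data frame, with attribute `"gap_report"`: a data frame
#'   with one row per filled span (`variable`, `start`, `end`, `n`, `method`).
#' @export
fill_gaps <- function(met, max_gap = 36L,
                      vars = intersect(c("t_air", "rh", "rs", "precip",
                                         "wind", grep("^swc", names(met),
                                                      value = TRUE)),
                                       names(met))) {
  report <- list()
  for (v in vars) {
    x <- met[[v]]
    isna <- is.na(x)
    if (!any(isna) || all(isna)) next
    runs <- rle(isna)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      n <- runs$lengths[k]
      if (n > max_gap) next
      i0 <- starts[k]; i1 <- ends[k]
      # need both neighbours for interpolation (except precip -> 0)
      if (v == "precip") {
        x[i0:i1] <- 0
        method <- "zero"
      } else {
        if (i0 == 1L || i1 == length(x)) next # edge gap: no anchor
        x[i0:i1] <- zoo::na.approx(x, na.rm = FALSE)[i0:i1]
        method <- "linear"
      }
      report[[length(report) + 1L]] <- data.frame(
        variable = v,
        start = met$timestamp[i0],
        end = met$timestamp[i1],
        n = n, method = method,
        stringsAsFactors = FALSE
      )
    }
    met[[v]] <- x
  }
  gap_report <- if (length(report)) {
    do.call(rbind, report)
  } else {
    data.frame(variable = character(), start = met$timestamp[0],
               end = met$timestamp[0], n = integer(), method = character(),
               stringsAsFactors = FALSE)
  }
  attr(met, "gap_report") <- gap_report
  met
}

#' Extrapolate a daily climate series along elevation
#'
#' Temperature is shifted by the lapse rate times the elevation difference;
#' the annual precipitation increment implied by the precipitation lapse is
#' distributed proportionally over precipitation events (dry days stay dry).
#'
#' @param daily Data frame from [aggregate_daily()] (needs `t_mean` and
#'   `precip`; `t_min`/`t_max` shifted when present).
#' @param delta_elev_m Elevation difference, m (target minus base; positive
#'   = upward).
#' @param lapse A list or [lapse_spec()] with `dT_per_100m` (K per 100 m,
#'   positive value = cooling upward) and `dP_per_100m` (mm yr-1 per 100 m,
#'   positive = wetter upward).
#' @return The shifted daily data frame.
#' @examples
#' lapse_spec(0.54, 12)
#' @export
lapse_extrapolate <- function(daily, delta_elev_m, lapse) {
  stopifnot(is.finite(lapse$dT_per_100m), is.finite(lapse$dP_per_100m))
  out <- daily
  dt <- -lapse$dT_per_100m * delta_elev_m / 100
  for (v in intersect(c("t_mean", "t_min", "t_max"), names(out))) {
    out[[v]] <- out[[v]] + dt
  }
  if ("precip" %in% names(out)) {
    ptot <- sum(out$precip, na.rm = TRUE)
    dp_annual <- lapse$dP_per_100m * delta_elev_m / 100 *
      length(unique(format(out$date, "%Y")))
    if (ptot > 0) {
      out$precip <- out$precip * (1 + dp_annual / ptot)
      out$precip <- pmax(out$precip, 0)
    }
  }
  out
}

#' Elevational lapse specification
#'
#' @param dT_per_100m Temperature lapse, K per 100 m (positive = cooling
#'   with elevation).
#' @param dP_per_100m Precipitation lapse, mm yr-1 per 100 m (positive =
#'   wetter with elevation).
#' @return A `lapse_spec` list.
#' @export
lapse_spec <- function(dT_per_100m = 0.54, dP_per_100m = 12) {
  stopifnot(is.finite(dT_per_100m), is.finite(dP_per_100m))
  structure(list(dT_per_100m = dT_per_100m, dP_per_100m = dP_per_100m),
            class = "lapse_spec")
}

#' Per-100-m lapse rate between two elevations
#'
#' @param delta Total difference of the variable between the two sites
#'   (e.g. K of annual mean temperature).
#' @param elev1,elev2 The two site elevations, m.
#' @return Lapse per 100 m of elevation.
#' @examples
#' lapse_per_100m(3.7, 1160, 1715) # ~0.67
#' @export
lapse_per_100m <- function(delta, elev1, elev2) {
  de <- abs(elev2 - elev1)
  if (de == 0) stop("elevations are equal")
  delta / (de / 100)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
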