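#' Default elevation-transect site table
#'
#' Five larch sites spanning the colline to high-subalpine belts, with the
#' reference climate normals (annual mean temperature 6.6 degrees C and
#' annual precipitation 528 mm at 1570 m) and the local lapse rates
#' (0.54 K and 12 mm per 100 m).
#'
#' @return Data frame `site_id`, `elevation`, with attributes
#'   `ref_elevation`, `t_ann_ref`, `p_ann_ref`, `lapse`.
#' @export
site_specs <- function() {
  out <- data.frame(
    site_id = c("S1100", "S1200", "S1700", "S2000", "S2200"),
    elevation = c(1070, 1160, 1715, 1990, 2250),
    stringsAsFactors = FALSE
  )
  attr(out, "ref_elevation") <- 1570
  attr(out, "t_ann_ref") <- 6.6
  attr(out, "p_ann_ref") <- 528
  attr(out, "lapse") <- lapse_spec(0.54, 12)
  out
}

# daylight bell shape on [0, 1], zero at night
diurnal_bell <- function(hour, sunrise = 6, sunset = 20) {
  x <- (hour - sunrise) / (sunset - sunrise)
  ifelse(x > 0 & x < 1, sin(pi * x), 0)
}

#' Generate a synthetic sub-daily microclimate series for one site-year
#'
#' Emulates a continental-alpine mountain climate: sinusoidal annual and
#' diurnal temperature cycles with centred AR(1) day-to-day anomalies,
#' relative humidity anti-correlated with temperature and boosted on wet
#' days, clear-sky radiation damped by a cloud factor tied to precipitation
#' occurrence (two-state wet/dry chain with gamma amounts scaled to the
#' site's annual normal), lognormal wind, and soil water content from a
#' single-bucket balance forced by precipitation and an evaporative-demand
#' proxy. Scripted drought episodes suppress rain and pull SWC down to a
#' floor. Elevation enters through the lapse rules: the temperature normal
#' drops and the precipitation normal rises with elevation.
#'
#' @param elevation Site elevation, m.
#' @param year Calendar year of the series (default 2013).
#' @param seed Random seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param step_min Sampling interval, minutes (default 60).
#' @param drought Optional data frame of scripted episodes with columns
#'   `start_doy`, `end_doy`, `swc_floor` (m3 m-3).
#' @param ref_elevation,t_ann_ref,p_ann_ref,lapse Climate normals and lapse
#'   rates; defaults follow [site_specs()].
#' @param t_amp_seasonal Seasonal temperature half-amplitude, K (default
#'   8.5; peak near DOY 200).
#' @param t_amp_diurnal Diurnal half-amplitude, K (default 4; peak 14:00).
#' @param noise_sd,noise_phi Day-to-day AR(1) anomaly sd (K) and
#'   autocorrelation (defaults 2.5, 0.7); the anomaly series is centred so
#'   the annual mean matches the lapse-derived normal exactly.
#' @param latitude Latitude, decimal degrees (default 46.7).
#' @return Data frame `timestamp`, `t_air` (degC), `rh` (%), `rs` (MJ m-2
#'   per interval), `precip` (mm per interval), `wind` (m s-1), `swc_05`,
#'   `swc_20`, `swc_50` (m3 m-3).
#' @export
gen_microclimate <- function(elevation, year = 2013, seed = 1,
                             step_min = 60, drought = NULL,
                             ref_elevation = 1570, t_ann_ref = 6.6,
                             p_ann_ref = 528, lapse = lapse_spec(),
                             t_amp_seasonal = 8.5, t_amp_diurnal = 4,
                             noise_sd = 2.5, noise_phi = 0.7,
                             latitude = 46.7) {
  set.seed(seed)
  de <- elevation - ref_elevation
  t_ann <- t_ann_ref - lapse$dT_per_100m * de / 100
  p_ann <- max(p_ann_ref + lapse$dP_per_100m * de / 100, 10)

  t0 <- as.POSIXct(paste0(year, "-01-01 00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste0(year, "-12-31 23:59:59"), tz = "UTC")
  ts <- seq(t0, t1, by = step_min * 60)
  doy <- as.integer(format(ts, "%j"))
  hour <- as.numeric(format(ts, "%H")) + as.numeric(format(ts, "%M")) / 60
  ndays <- max(doy)
  per_day <- sum(doy == 1L)

  # centred AR(1) daily anomaly: annual mean is exactly the normal
  eps <- stats::rnorm(ndays, 0, noise_sd * sqrt(1 - noise_phi^2))
  anom <- as.numeric(stats::filter(eps, noise_phi, method = "recursive"))
  anom <- anom - mean(anom)

  # precipitation: two-state daily chain, gamma amounts
  p01 <- 0.25; p11 <- 0.55
  wet <- logical(ndays)
  wet[1] <- stats::runif(1) < p01 / (1 + p01 - p11)
  u <- stats::runif(ndays)
  for (d in 2:ndays) {
    wet[d] <- u[d] < if (wet[d - 1]) p11 else p01
  }
  shape <- 0.7
  amounts <- numeric(ndays)
  if (any(wet)) {
    amounts[wet] <- stats::rgamma(sum(wet), shape = shape,
                                  scale = p_ann / (sum(wet) * shape))
  }
  if (!is.null(drought)) {
    for (k in seq_len(nrow(drought))) {
      span <- seq(drought$start_doy[k], drought$end_doy[k])
      wet[span] <- FALSE
      amounts[span] <- 0
      # scripted episodes end with a drought-breaking rainfall that
      # refills the soil bucket
      nxt <- max(span) + 1L
      if (nxt <= ndays) {
        wet[nxt] <- TRUE
        amounts[nxt] <- amounts[nxt] + 30
      }
    }
  }

  t_seas <- t_ann + t_amp_seasonal * cos(2 * pi * (doy - 200) / 365)
  t_air <- t_seas + anom[doy] -
    t_amp_diurnal * cos(2 * pi * (hour - 14) / 24)

  rh <- 72 + 18 * wet[doy] - 2.2 * (t_air - t_seas) +
    stats::rnorm(length(ts), 0, 4)
  rh <- pmin(pmax(rh, 5), 100)

  ra_day <- extraterrestrial_radiation(doy, latitude)
  cloud <- ifelse(wet, 0.35, 1) *
    pmin(pmax(stats::rnorm(ndays, 1, 0.08), 0.6), 1.2)
  rs_day <- 0.72 * ra_day * cloud[doy]
  bell <- diurnal_bell(hour)
  # normalise the bell so interval values sum to the daily total
  bell_sum <- sum(diurnal_bell(seq(0, 24 - 24 / per_day, by = 24 / per_day)))
  rs <- rs_day * bell / bell_sum

  wind <- stats::rlnorm(length(ts), meanlog = log(1.5), sdlog = 0.4)
  precip <- amounts[doy] / per_day

  # bucket soil water balance (daily), depth 300 mm
  fc <- 0.35; wp <- 0.08; depth <- 300
  t_day <- t_seas[match(seq_len(ndays), doy)] +
    anom # daily mean temperature
  et_pot <- pmax(0.22 * t_day + 0.4, 0) # mm/d evaporative-demand proxy
  s <- numeric(ndays)
  s[1] <- 0.30 * depth
  for (d in 2:ndays) {
    rel <- (s[d - 1] / depth - wp) / (fc - wp)
    rel <- min(max(rel, 0), 1)
    s[d] <- s[d - 1] + amounts[d] - et_pot[d] * rel
    s[d] <- min(max(s[d], wp * depth), fc * depth)
  }
  swc <- s / depth
  if (!is.null(drought)) {
    for (k in seq_len(nrow(drought))) {
      span <- seq(drought$start_doy[k], drought$end_doy[k])
      floor_k <- drought$swc_floor[k]
      # fast dry-down to the scripted floor, then hold
      n_ramp <- min(5L, length(span))
      ramp <- c(seq(swc[span[1]], floor_k, length.out = n_ramp),
                rep(floor_k, length(span) - n_ramp))
      swc[span] <- pmin(swc[span], ramp)
    }
  }

  data.frame(
    timestamp = ts,
    t_air = t_air,
    rh = rh,
    rs = rs,
    precip = precip,
    wind = wind,
    swc_05 = pmin(pmax(swc[doy] * 0.92, wp), fc),
    swc_20 = swc[doy],
    swc_50 = pmin(pmax(swc[doy] * 1.06, wp), fc)
  )
}

#' Generate a synthetic dendrometer circumference trace
#'
#' Builds an hourly (or finer) stem-circumference record consistent with the
#' zero-growth model: a Gompertz cumulative-growth line deposited during
#' shrinkage-free hours, minus a reversible shrinkage signal with a diurnal
#' component proportional to the day's VPD and a drought component that
#' builds up while soil water is below a threshold and relaxes after it
#' recovers. Growth increments are suppressed while drought shrinkage is
#' active, so the zero-growth assumption holds by construction. Output is
#' circumference (2 pi x radius) in micrometers.
#'
#' @param climate_daily Daily climate data frame (needs `date`, `vpd_mean`,
#'   `swc_mean`).
#' @param A,mu,lam Gompertz ground-truth parameters (defaults 1500 um,
#'   25 um/d, DOY 130).
#' @param twd_scale Diurnal shrinkage per unit VPD, um/kPa (default 10;
#'   0 disables the diurnal component).
#' @param swc_threshold SWC below which drought shrinkage builds (default
#'   0.12 m3 m-3).
#' @param episode_rise Maximum drought-shrinkage build-up rate, um/d
#'   (default 60).
#' @param wp Wilting point used to scale the soil-water deficit (default
#'   0.08 m3 m-3).
#' @param episode_max Saturation level of drought shrinkage, um (default
#'   250).
#' @param relax_tau Post-drought relaxation e-folding time, days (default
#'   1.5).
#' @param noise_sd Hourly AR(1) measurement-noise sd, um (default 2; 0
#'   disables noise).
#' @param season DOY range of the trace (default 60-300).
#' @param step_min Sampling interval, minutes (default 60).
#' @param seed Random seed.
#' @return Data frame `timestamp`, `circ` (um), with attribute `truth`
#'   (list of the generating parameters).
#' @export
gen_dendrometer <- function(climate_daily, A = 1500, mu = 25, lam = 130,
                            twd_scale = 10, swc_threshold = 0.12,
                            episode_rise = 60, episode_max = 250,
                            relax_tau = 1.5, wp = 0.08, noise_sd = 2,
                            season = c(60, 300), step_min = 60, seed = 1) {
  set.seed(seed)
  stopifnot(all(c("date", "vpd_mean", "swc_mean") %in% names(climate_daily)))
  cd <- climate_daily
  cd$doy <- as.integer(format(cd$date, "%j"))
  cd <- cd[cd$doy >= season[1] & cd$doy <= season[2], , drop = FALSE]
  cd <- cd[order(cd$doy), , drop = FALSE]
  ndays <- nrow(cd)
  per_day <- as.integer(24 * 60 / step_min)

  # drought shrinkage state, daily
  ep <- numeric(ndays)
  for (d in seq_len(ndays)) {
    prev <- if (d == 1L) 0 else ep[d - 1L]
    swc <- cd$swc_mean[d]
    if (!is.na(swc) && swc < swc_threshold) {
      deficit <- min((swc_threshold - swc) / (swc_threshold - wp), 1)
      ep[d] <- prev + episode_rise * deficit * (1 - prev / episode_max)
    } else {
      ep[d] <- prev * exp(-1 / relax_tau)
    }
  }

  g_line <- gompertz_curve(cd$doy, A, mu, lam)
  inc <- diff(c(g_line[1], g_line))

  hours <- seq(0, 24 - 24 / per_day, by = 24 / per_day)
  bell <- diurnal_bell(hours)
  n <- ndays * per_day
  shrink <- numeric(n)
  grow_rate <- numeric(n)
  for (d in seq_len(ndays)) {
    idx <- ((d - 1L) * per_day + 1L):(d * per_day)
    vpd <- cd$vpd_mean[d]
    if (is.na(vpd)) vpd <- 0
    diurnal <- twd_scale * vpd * bell
    shrink[idx] <- diurnal + ep[d]
    # deposit the day's growth increment over shrink-free intervals;
    # drought shrinkage suppresses growth for the whole day
    if (ep[d] < 1) {
      free <- which(diurnal <= 1e-9)
      if (length(free)) grow_rate[idx[free]] <- inc[d] / length(free)
    }
  }
  gcum <- cumsum(grow_rate)
  noise <- if (noise_sd > 0) {
    as.numeric(stats::filter(stats::rnorm(n, 0, noise_sd * sqrt(1 - 0.8^2)),
                             0.8, method = "recursive"))
  } else {
    rep(0, n)
  }
  radius <- gcum - shrink + noise

  t0 <- as.POSIXct(paste(format(cd$date[1]), "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1L) * step_min * 60
  out <- data.frame(timestamp = ts, circ = 2 * pi * radius)
  attr(out, "truth") <- list(A = A, mu = mu, lam = lam,
                             ip = gompertz_ip(A, mu, lam),
                             twd_scale = twd_scale, episode = ep)
  out
}

#' Generate a synthetic tissue-heat-balance sap-flow trace
#'
#' Daily flow amplitude follows saturating responses to evaporative demand
#' and (optionally) soil water, `q = qmax * PET/(PET + k_pet) * f(SWC)`,
#' shaped into a diurnal bell and perturbed by multiplicative lognormal
#' noise. With `soil_limited = FALSE` (the high-elevation configuration)
#' the soil term is identically 1, emulating a site with no soil-water
#' limitation.
#'
#' @param climate_daily Daily data frame (needs `date`, `pet`, `swc_mean`).
#' @param qmax Peak rate per unit circumference, kg h-1 cm-1 (default 0.1).
#' @param k_pet Half-saturation of the demand response, mm d-1 (default 2).
#' @param soil_limited Apply the soil-water limitation (default TRUE).
#' @param wp Wilting point for the soil term (default 0.08).
#' @param k_swc Half-saturation of the soil term above `wp` (default 0.05).
#' @param sensors Sensor labels; two sensors get gains 0.9 / 1.1 around the
#'   tree mean (default `c("N", "S")`).
#' @param noise_sdlog Lognormal noise sd on the log scale (default 0.15).
#' @param step_min Sampling interval, minutes (default 10, the logger
#'   native rate).
#' @param seed Random seed.
#' @return Data frame `timestamp`, `sensor`, `rate` (kg h-1 cm-1), with
#'   attribute `truth`.
#' @export
gen_sapflow <- function(climate_daily, qmax = 0.1, k_pet = 2,
                        soil_limited = TRUE, wp = 0.08, k_swc = 0.05,
                        sensors = c("N", "S"), noise_sdlog = 0.15,
                        step_min = 10, seed = 1) {
  set.seed(seed)
  stopifnot(all(c("date", "pet", "swc_mean") %in% names(climate_daily)))
  cd <- climate_daily[order(climate_daily$date), , drop = FALSE]
  ndays <- nrow(cd)
  per_day <- as.integer(24 * 60 / step_min)
  pet <- ifelse(is.na(cd$pet), 0, cd$pet)
  sat_p <- pet / (pet + k_pet)
  sat_s <- if (soil_limited) {
    s <- pmax(cd$swc_mean - wp, 0)
    s / (s + k_swc)
  } else {
    rep(1, ndays)
  }
  q_day <- qmax * sat_p * sat_s

  hours <- seq(0, 24 - 24 / per_day, by = 24 / per_day)
  bell <- diurnal_bell(hours, sunrise = 6, sunset = 20)
  gains <- if (length(sensors) == 2L) c(0.9, 1.1) else rep(1, length(sensors))
  t0 <- as.POSIXct(paste(format(cd$date[1]), "00:00:00"), tz = "UTC")
  n <- ndays * per_day
  ts <- t0 + (seq_len(n) - 1L) * step_min * 60
  base <- numeric(n)
  for (d in seq_len(ndays)) {
    idx <- ((d - 1L) * per_day + 1L):(d * per_day)
    base[idx] <- q_day[d] * bell
  }
  res <- list()
  for (k in seq_along(sensors)) {
    noise <- stats::rlnorm(n, -noise_sdlog^2 / 2, noise_sdlog)
    res[[k]] <- data.frame(timestamp = ts, sensor = sensors[k],
                           rate = base * gains[k] * noise,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$timestamp, out$sensor), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- list(qmax = qmax, k_pet = k_pet,
                             soil_limited = soil_limited, q_day = q_day)
  out
}

#' Generate a synthetic monthly climate-station series
#'
#' Monthly mean temperature around a sinusoidal normal (July peak) with
#' Gaussian interannual noise, and monthly precipitation from gamma draws
#' around summer-peaked monthly normals; annual totals fluctuate around the
#' station normal.
#'
#' @param years Calendar years to cover.
#' @param t_ann Annual mean temperature normal, degrees C (default 6.6).
#' @param p_ann Annual precipitation normal, mm (default 528).
#' @param t_amp Seasonal half-amplitude, K (default 8.5).
#' @param t_sd Interannual monthly temperature sd, K (default 1.3).
#' @param p_shape Gamma shape of monthly precipitation (default 4).
#' @param seed Random seed.
#' @return Data frame `year`, `month`, `t`, `p`.
#' @export
gen_station_monthly <- function(years, t_ann = 6.6, p_ann = 528,
                                t_amp = 8.5, t_sd = 1.3, p_shape = 4,
                                seed = 1) {
  set.seed(seed)
  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  t_norm <- t_ann + t_amp * cos(2 * pi * (grid$month - 7) / 12)
  # summer-peaked monthly precipitation weights (convective regime)
  w <- 1 + 0.8 * cos(2 * pi * (1:12 - 7) / 12)
  w <- w / sum(w)
  p_norm <- p_ann * w[grid$month]
  grid$t <- t_norm + stats::rnorm(nrow(grid), 0, t_sd)
  grid$p <- stats::rgamma(nrow(grid), shape = p_shape,
                          scale = p_norm / p_shape)
  grid
}

#' Generate a synthetic ring-width ensemble with known climate signal
#'
#' Tree-level widths are a negative-exponential age trend times a lognormal
#' signal `exp(beta . z(climate) + common AR(1) + individual noise)`; the
#' common and individual variance components are set to hit a target mean
#' interseries correlation. Two cores per tree are the tree series times
#' independent lognormal core noise.
#'
#' @param monthly Station series from [gen_station_monthly()] covering
#'   `years` and the preceding year.
#' @param years Ring years to generate.
#' @param n_trees Number of trees (default 15).
#' @param beta Named numeric vector of climate coefficients on the log
#'   scale; names are predictor labels as produced by
#'   [monthly_climate_matrix()] (default `c(P.Jun = 0.6)`; use `NULL` for
#'   a climate-free null ensemble).
#' @param rbar_target Target mean interseries correlation (default 0.5).
#' @param ar_phi,ar_sd Common AR(1) signal autocorrelation and sd
#'   (defaults 0.3, 0.3).
#' @param age_a,age_b,age_k Age-trend parameters of
#'   `w = age_a exp(-age_b t) + age_k`, micrometers (defaults 2500, 0.03,
#'   600).
#' @param core_sdlog Core-level lognormal noise sd (default 0.1).
#' @param seed Random seed.
#' @return Ring-width data frame (two cores per tree, columns `T01A`,
#'   `T01B`, ...), with attribute `truth` (list: `beta`, `common`,
#'   `rbar_target`, `sd_common`, `sd_ind`).
#' @export
gen_ringwidths <- function(monthly, years, n_trees = 15,
                           beta = c(P.Jun = 0.6), rbar_target = 0.5,
                           ar_phi = 0.3, ar_sd = 0.3,
                           age_a = 2500, age_b = 0.03, age_k = 600,
                           core_sdlog = 0.1, seed = 1) {
  set.seed(seed)
  ny <- length(years)
  signal <- rep(0, ny)
  if (!is.null(beta) && length(beta)) {
    x <- monthly_climate_matrix(monthly, years)
    if (nrow(x) != ny) stop("monthly climate does not cover years + 1")
    for (nm in names(beta)) {
      if (!nm %in% colnames(x)) stop("unknown climate column: ", nm)
      signal <- signal + beta[[nm]] * as.numeric(scale(x[, nm]))
    }
  }
  ar <- as.numeric(stats::filter(stats::rnorm(ny, 0,
                                              ar_sd * sqrt(1 - ar_phi^2)),
                                 ar_phi, method = "recursive"))
  common <- signal + ar
  var_common <- sum(beta^2) + ar_sd^2
  sd_ind <- sqrt(var_common * (1 - rbar_target) / rbar_target)
  age <- age_a * exp(-age_b * seq_len(ny)) + age_k

  cores <- list()
  for (i in seq_len(n_trees)) {
    ind <- stats::rnorm(ny, 0, sd_ind)
    tree <- age * exp(common + ind)
    for (cl in c("A", "B")) {
      w <- tree * stats::rlnorm(ny, -core_sdlog^2 / 2, core_sdlog)
      w <- pmax(w, 10) # widths strictly positive
      attr(w, "first_year") <- years[1]
      cores[[sprintf("T%02d%s", i, cl)]] <- w
    }
  }
  out <- as_rwl(cores)
  attr(out, "truth") <- list(beta = beta, common = common,
                             rbar_target = rbar_target,
                             sd_common = sqrt(var_common), sd_ind = sd_ind)
  out
}
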