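#' Convert a dendrometer circumference trace to stem radius
#'
#' Band dendrometers record circumference change; radial analyses use
#' radius = circumference / (2*pi). Optionally averages the radius to hourly
#' resolution (the native 10-min signal is noisy and the zero-growth
#' partition is defined on hourly means).
#'
#' @param circ Data frame with columns `timestamp` (POSIXct, strictly
#'   increasing) and `circ` (micrometers, relative to installation);
#'   optionally `tree_id`.
#' @param hourly Average radius to hourly means (default `TRUE`).
#' @return Data frame with `timestamp` and `radius` (micrometers), plus
#'   `tree_id` when present.
#' @export
circumference_to_radius <- function(circ, hourly = TRUE) {
  stopifnot(is.data.frame(circ), all(c("timestamp", "circ") %in% names(circ)))
  if (is.unsorted(as.numeric(circ$timestamp), strictly = TRUE)) {
    stop("timestamps must be strictly increasing")
  }
  radius <- circ$circ / (2 * pi)
  out <- data.frame(timestamp = circ$timestamp, radius = radius)
  if (!is.null(circ$tree_id)) out$tree_id <- circ$tree_id[1]
  if (hourly) {
    hr <- as.POSIXct(trunc(out$timestamp, units = "hours"))
    agg <- tapply(out$radius, hr, mean)
    out2 <- data.frame(
      timestamp = as.POSIXct(names(agg),
                             tz = attr(circ$timestamp, "tzone") %||% "UTC"),
      radius = as.numeric(agg)
    )
    out2 <- out2[order(out2$timestamp), , drop = FALSE]
    if (!is.null(circ$tree_id)) out2$tree_id <- circ$tree_id[1]
    rownames(out2) <- NULL
    return(out2)
  }
  out
}

#' Partition a stem radius trace into growth and tree water deficit
#'
#' Zero-growth decomposition: the growth line GRO is the running maximum of
#' the radius over current and all previous readings, and the tree water
#' deficit TWD is the (non-negative) deviation below it,
#' `twd = gro - radius`. The model assumes radial growth happens only at
#' stem water saturation, so any radius below the previous maximum reflects
#' reversible, drought-related shrinkage rather than growth.
#'
#' @param trace Data frame with `timestamp` and `radius` (micrometers),
#'   ordered in time.
#' @return The input with added columns `gro` (non-decreasing) and `twd`
#'   (>= 0); the identity `radius = gro - twd` holds exactly.
#' @examples
#' tr <- data.frame(timestamp = as.POSIXct("2013-06-01") + 3600 * (0:4),
#'                  radius = c(100, 105, 103, 103, 108))
#' partition_zero_growth(tr)$gro # 100 105 105 105 108
#' @export
partition_zero_growth <- function(trace) {
  stopifnot(is.data.frame(trace), "radius" %in% names(trace))
  if (nrow(trace) == 0L) stop("empty trace")
  if (anyNA(trace$radius)) stop("radius contains missing values; fill gaps first")
  trace$gro <- cummax(trace$radius)
  trace$twd <- trace$gro - trace$radius
  trace
}

#' Daily statistics of a partitioned stem trace
#'
#' Daily radius change (DRC) is the difference of consecutive daily mean
#' radii (first day missing); TWD is summarised by its daily maximum (used
#' in climate models) and daily minimum (growth-period criterion).
#'
#' @param part Data frame from [partition_zero_growth()].
#' @return Data frame with one row per day: `date`, `radius_mean`, `drc`,
#'   `twd_max`, `twd_min`, `gro_max`.
#' @export
daily_stem_stats <- function(part) {
  stopifnot(all(c("timestamp", "radius", "gro", "twd") %in% names(part)))
  day <- as.Date(part$timestamp,
                 tz = attr(part$timestamp, "tzone") %||% "UTC")
  agg <- function(x, f) as.numeric(tapply(x, day, f))
  out <- data.frame(
    date = as.Date(names(tapply(part$radius, day, length))),
    radius_mean = agg(part$radius, mean),
    twd_max = agg(part$twd, max),
    twd_min = agg(part$twd, min),
    gro_max = agg(part$gro, max),
    stringsAsFactors = FALSE
  )
  out$drc <- c(NA_real_, diff(out$radius_mean))
  rownames(out) <- NULL
  out[, c("date", "radius_mean", "drc", "twd_max", "twd_min", "gro_max")]
}

#' Detect the main growth period of a season
#'
#' The main growth period is the longest run of days with (a) a sliding
#' GRO increase rate at or above a fraction of the season's maximum rate and
#' (b) daily minimum TWD close to zero. This mirrors the operational
#' definition "continuously increasing dendrometer record, high daily growth
#' rate, minimum daily TWD close to 0".
#'
#' @param stats Daily data frame from [daily_stem_stats()], one season.
#' @param window Sliding window (days) over which the GRO rate is assessed
#'   (default 5).
#' @param rate_frac Minimum GRO rate as a fraction of the season maximum
#'   rate (default 0.2).
#' @param twd_max_um Maximum allowed daily minimum TWD, micrometers
#'   (default 30).
#' @return A one-row data frame `start_doy`, `end_doy`, `n_days`,
#'   `qualified` (FALSE with NA bounds when no day qualifies).
#' @export
detect_growth_period <- function(stats, window = 5L, rate_frac = 0.2,
                                 twd_max_um = 30) {
  doy <- as.integer(format(stats$date, "%j"))
  # centred sliding-window GRO rate (um/day)
  n <- nrow(stats)
  rate <- rep(NA_real_, n)
  half <- window %/% 2
  for (i in seq_len(n)) {
    i0 <- max(1L, i - half); i1 <- min(n, i + half)
    rate[i] <- (stats$gro_max[i1] - stats$gro_max[i0]) / max(1L, i1 - i0)
  }
  max_rate <- max(rate, na.rm = TRUE)
  if (!is.finite(max_rate) || max_rate <= 0) {
    return(data.frame(start_doy = NA_integer_, end_doy = NA_integer_,
                      n_days = 0L, qualified = FALSE))
  }
  ok <- rate >= rate_frac * max_rate & stats$twd_min <= twd_max_um
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) {
    return(data.frame(start_doy = NA_integer_, end_doy = NA_integer_,
                      n_days = 0L, qualified = FALSE))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  best <- true_runs[which.max(runs$lengths[true_runs])]
  data.frame(start_doy = doy[starts[best]], end_doy = doy[ends[best]],
             n_days = runs$lengths[best], qualified = TRUE)
}
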