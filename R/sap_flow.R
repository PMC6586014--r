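#' Scale sap-flow rates per unit circumference to tree level
#'
#' Tissue-heat-balance sensors report flow per unit trunk circumference
#' (kg h-1 cm-1). Tree-level flow is that rate times the effective
#' circumference, i.e. the stem circumference minus the bark and phloem
#' ring: `C_eff = C - 2*pi*t_bark`. Trees with both a north and a south
#' sensor are averaged across sensors before scaling; single-sensor
#' timestamps are used as-is and flagged.
#'
#' @param trace Data frame with `timestamp`, `rate` (kg h-1 cm-1) and
#'   optionally `sensor` (e.g. "N"/"S"). Negative rates (night-time noise)
#'   are clipped to 0; the clipped count is reported as an attribute.
#' @param circumference_cm Stem circumference at sensor height, cm.
#' @param bark_phloem_cm Combined bark + phloem thickness, cm.
#' @return Data frame `timestamp`, `rate_tree` (kg h-1), `n_sensors`; with
#'   attributes `c_eff_cm` and `n_clipped`.
#' @export
scale_to_tree <- function(trace, circumference_cm, bark_phloem_cm) {
  stopifnot(all(c("timestamp", "rate") %in% names(trace)))
  c_eff <- circumference_cm - 2 * pi * bark_phloem_cm
  if (!is.finite(c_eff) || c_eff <= 0) {
    stop("effective circumference must be positive")
  }
  n_clipped <- sum(trace$rate < 0, na.rm = TRUE)
  trace$rate <- pmax(trace$rate, 0)
  if (is.null(trace$sensor)) trace$sensor <- "single"
  key <- as.numeric(trace$timestamp)
  mean_rate <- tapply(trace$rate, key, mean, na.rm = TRUE)
  n_sensors <- tapply(!is.na(trace$rate), key, sum)
  out <- data.frame(
    timestamp = as.POSIXct(as.numeric(names(mean_rate)),
                           origin = "1970-01-01",
                           tz = attr(trace$timestamp, "tzone") %||% "UTC"),
    rate_tree = as.numeric(mean_rate) * c_eff,
    n_sensors = as.integer(n_sensors)
  )
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "c_eff_cm") <- c_eff
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Integrate tree-level sap flow to daily sums
#'
#' Step integration of the kg h-1 series over each calendar day (1 kg of
#' xylem water = 1 litre). Days with less than `min_complete` of the
#' expected intervals are flagged incomplete so that site means can exclude
#' them.
#'
#' @param tree_series Data frame `timestamp`, `rate_tree` (kg h-1).
#' @param min_complete Minimum fraction of expected intervals (default 0.9).
#' @return Data frame `date`, `flow_l` (litres per day), `n_obs`,
#'   `complete`.
#' @export
daily_sap_flow <- function(tree_series, min_complete = 0.9) {
  stopifnot(all(c("timestamp", "rate_tree") %in% names(tree_series)))
  ts <- tree_series$timestamp
  day <- as.Date(ts, tz = attr(ts, "tzone") %||% "UTC")
  step_h <- stats::median(diff(as.numeric(ts))) / 3600
  expected <- max(1, round(24 / step_h))
  flow <- tapply(tree_series$rate_tree * step_h, day, sum, na.rm = TRUE)
  n_obs <- tapply(!is.na(tree_series$rate_tree), day, sum)
  out <- data.frame(
    date = as.Date(names(flow)),
    flow_l = as.numeric(flow),
    n_obs = as.integer(n_obs)
  )
  out$complete <- out$n_obs / expected >= min_complete
  rownames(out) <- NULL
  out
}

#' Site mean and standard error of daily sap flow
#'
#' Arithmetic mean and standard error (sd / sqrt(n)) across trees present
#' (and complete) on each day.
#'
#' @param daily_by_tree Data frame with `tree_id`, `date`, `flow_l` and
#'   optionally `complete` (incomplete days excluded).
#' @return Data frame `date`, `mean_flow_l`, `se_flow_l` (NA with a single
#'   tree), `n_trees`.
#' @export
site_aggregate <- function(daily_by_tree) {
  stopifnot(all(c("tree_id", "date", "flow_l") %in% names(daily_by_tree)))
  d <- daily_by_tree
  if (!is.null(d$complete)) d <- d[d$complete, , drop = FALSE]
  mean_f <- tapply(d$flow_l, d$date, mean)
  n <- tapply(d$flow_l, d$date, length)
  se <- tapply(d$flow_l, d$date, function(x) {
    if (length(x) < 2L) NA_real_ else stats::sd(x) / sqrt(length(x))
  })
  out <- data.frame(
    date = as.Date(names(mean_f)),
    mean_flow_l = as.numeric(mean_f),
    se_flow_l = as.numeric(se),
    n_trees = as.integer(n)
  )
  rownames(out) <- NULL
  out
}
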