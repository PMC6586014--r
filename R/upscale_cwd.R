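#' Annual climatic water deficit of a climate cell
#'
#' CWD is defined as annual precipitation minus annual potential
#' evapotranspiration, the latter from the temperature-based Thornthwaite
#' method ([compute_pet_thornthwaite()]). Positive values indicate a water
#' surplus, negative values a deficit.
#'
#' @param cell A list or one-row data frame with `monthly_t` (12 monthly
#'   mean temperatures, degrees C), `annual_p` (mm) and `latitude`
#'   (decimal degrees).
#' @return CWD in mm yr-1.
#' @export
annual_cwd <- function(cell) {
  pet <- compute_pet_thornthwaite(cell$monthly_t, latitude = cell$latitude)
  cell$annual_p - sum(pet)
}

#' Apply a warming scenario to a climate cell
#'
#' A uniform temperature offset is added to every month and annual
#' precipitation is scaled by `1 + delta_p_frac`.
#'
#' @param cell Climate cell as in [annual_cwd()].
#' @param scenario List with `delta_t` (K) and `delta_p_frac` (fraction,
#'   negative = reduction; must be > -1).
#' @return The transformed cell.
#' @export
apply_scenario <- function(cell, scenario) {
  stopifnot(scenario$delta_p_frac > -1)
  cell$monthly_t <- cell$monthly_t + scenario$delta_t
  cell$annual_p <- cell$annual_p * (1 + scenario$delta_p_frac)
  cell
}

#' Classify larch growth conditions of a climate cell
#'
#' Cells below the species' thermal floor (annual mean temperature below
#' `t_min_limit`) are `below-thermal-limit` regardless of water balance;
#' otherwise the class is set by the annual climatic water deficit against
#' two calibrated cut points: below the first cut `severely-restricted`
#' (red), between the cuts `drought-restricted` (yellow), above the second
#' `favorable` (green).
#'
#' @param cell Climate cell as in [annual_cwd()].
#' @param thresholds Numeric length-2 vector, increasing: the red/yellow and
#'   yellow/green CWD cut points (mm). See [calibrate_cwd_thresholds()].
#' @param t_min_limit Thermal floor, degrees C (default -2.5).
#' @return One-row data frame: `class`, `cwd`, `t_ann`.
#' @export
classify_cell <- function(cell, thresholds, t_min_limit = -2.5) {
  if (length(thresholds) != 2L || diff(thresholds) <= 0) {
    stop("thresholds must be two increasing CWD cut points")
  }
  t_ann <- mean(cell$monthly_t)
  cwd <- annual_cwd(cell)
  class <- if (t_ann < t_min_limit) {
    "below-thermal-limit"
  } else if (cwd < thresholds[1]) {
    "severely-restricted"
  } else if (cwd < thresholds[2]) {
    "drought-restricted"
  } else {
    "favorable"
  }
  data.frame(class = class, cwd = cwd, t_ann = t_ann,
             stringsAsFactors = FALSE)
}

#' Classify a grid of climate cells
#'
#' @param cells Data frame with one row per cell: columns `cell_id`
#'   (optional), `latitude`, `annual_p`, and `t01`..`t12` (monthly mean
#'   temperatures).
#' @param thresholds CWD cut points as in [classify_cell()].
#' @param scenario Optional scenario list applied to every cell first.
#' @param t_min_limit Thermal floor (default -2.5).
#' @return List with `cells` (input plus `class`, `cwd`, `t_ann`) and
#'   `tally` (named class counts).
#' @export
classify_grid <- function(cells, thresholds, scenario = NULL,
                          t_min_limit = -2.5) {
  tcols <- sprintf("t%02d", 1:12)
  stopifnot(all(tcols %in% names(cells)),
            all(c("latitude", "annual_p") %in% names(cells)))
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- list(monthly_t = as.numeric(cells[i, tcols]),
                 annual_p = cells$annual_p[i],
                 latitude = cells$latitude[i])
    if (!is.null(scenario)) cell <- apply_scenario(cell, scenario)
    res[[i]] <- classify_cell(cell, thresholds, t_min_limit)
  }
  res <- do.call(rbind, res)
  out <- cbind(cells, res)
  levels <- c("severely-restricted", "drought-restricted", "favorable",
              "below-thermal-limit")
  tally <- table(factor(out$class, levels = levels))
  list(cells = out, tally = c(tally))
}

#' Monthly climate normals for a transect elevation
#'
#' Builds a synthetic 12-month climate from station normals plus elevational
#' lapse rates: annual mean temperature shifted by the temperature lapse and
#' given a sinusoidal seasonal cycle (July peak), and annual precipitation
#' shifted by the precipitation lapse and distributed over months with
#' summer-peaked weights typical of the continental-alpine convective
#' regime.
#'
#' @param elevation Target elevation, m.
#' @param ref_elevation Elevation of the station normals, m (default 1570).
#' @param t_ann_ref Station annual mean temperature, degrees C (default
#'   6.6).
#' @param p_ann_ref Station annual precipitation, mm (default 528).
#' @param lapse A [lapse_spec()] (default 0.54 K and 12 mm per 100 m).
#' @param t_amplitude Seasonal half-amplitude of monthly temperature, K
#'   (default 8.5).
#' @param latitude Latitude, decimal degrees (default 46.7).
#' @return Climate cell list: `monthly_t`, `annual_p`, `latitude`,
#'   `elevation`.
#' @export
transect_cell <- function(elevation, ref_elevation = 1570,
                          t_ann_ref = 6.6, p_ann_ref = 528,
                          lapse = lapse_spec(), t_amplitude = 8.5,
                          latitude = 46.7) {
  de <- elevation - ref_elevation
  t_ann <- t_ann_ref - lapse$dT_per_100m * de / 100
  p_ann <- max(p_ann_ref + lapse$dP_per_100m * de / 100, 1)
  m <- 1:12
  monthly_t <- t_ann + t_amplitude * cos(2 * pi * (m - 7) / 12)
  list(monthly_t = monthly_t, annual_p = p_ann, latitude = latitude,
       elevation = elevation)
}

#' Calibrate CWD classification cut points from transect sites
#'
#' The class boundaries are calibration outputs, not constants: given the
#' five transect elevations and the class each is known to fall in
#' (red, red, yellow, green, green with increasing elevation), the cut
#' points are placed midway between the annual CWD of the adjacent sites
#' that straddle each boundary.
#'
#' @param elevations Transect site elevations, increasing (default
#'   1070, 1160, 1715, 1990, 2250 m).
#' @param classes Known class per site, in `"red"`, `"yellow"`, `"green"`
#'   (default red, red, yellow, green, green).
#' @param ... Passed to [transect_cell()].
#' @return List with `thresholds` (length-2 numeric) and `site_cwd`
#'   (named CWD per site).
#' @export
calibrate_cwd_thresholds <- function(elevations = c(1070, 1160, 1715,
                                                    1990, 2250),
                                     classes = c("red", "red", "yellow",
                                                 "green", "green"), ...) {
  stopifnot(length(elevations) == length(classes),
            !is.unsorted(elevations))
  cwd <- vapply(elevations,
                function(e) annual_cwd(transect_cell(e, ...)), 0)
  names(cwd) <- paste0("S", elevations)
  if (is.unsorted(cwd)) {
    stop("site CWD not monotone in elevation; cannot place cut points")
  }
  ry <- c(max(cwd[classes == "red"]), min(cwd[classes == "yellow"]))
  yg <- c(max(cwd[classes == "yellow"]), min(cwd[classes == "green"]))
  thresholds <- c(mean(ry), mean(yg))
  list(thresholds = thresholds, site_cwd = cwd)
}
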