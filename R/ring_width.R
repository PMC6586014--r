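#' Ring-width tables
#'
#' Ring-width sets are held in the field's conventional layout: a data frame
#' with one column per series (core or tree) and calendar years as row
#' names; `NA` outside a series' span. Widths are in micrometers.
#'
#' @param widths Named list of numeric vectors, each with a `first_year`
#'   attribute, or a matrix/data.frame with year rownames.
#' @return A ring-width data frame with year rownames.
#' @export
as_rwl <- function(widths) {
  if (is.data.frame(widths) || is.matrix(widths)) {
    out <- as.data.frame(widths)
    stopifnot(!is.null(rownames(out)))
    return(out)
  }
  yr0 <- vapply(widths, function(x) as.integer(attr(x, "first_year")), 1L)
  yr1 <- yr0 + vapply(widths, length, 1L) - 1L
  years <- seq(min(yr0), max(yr1))
  out <- data.frame(row.names = as.character(years))
  for (i in seq_along(widths)) {
    v <- rep(NA_real_, length(years))
    v[match(seq(yr0[i], yr1[i]), years)] <- as.numeric(widths[[i]])
    out[[names(widths)[i]]] <- v
  }
  out
}

#' Years of a ring-width table
#' @param rwl Ring-width data frame with year rownames.
#' @return Integer vector of years.
#' @export
rwl_years <- function(rwl) as.integer(rownames(rwl))

#' Average cores to tree-level ring series
#'
#' Per-year arithmetic mean over the available cores of each tree; years
#' covered by only one core use that core's value. Trees whose cores never
#' overlap are rejected (they cannot be verified against each other).
#'
#' @param rwl Ring-width data frame (cores as columns).
#' @param tree_ids Tree identifier per column; by default the column name
#'   with a trailing core letter stripped (e.g. `"S12_03A"` -> `"S12_03"`).
#' @return Ring-width data frame with one column per tree.
#' @export
average_cores_to_tree <- function(rwl,
                                  tree_ids = sub("[A-Za-z]$", "", names(rwl))) {
  stopifnot(length(tree_ids) == ncol(rwl))
  out <- data.frame(row.names = rownames(rwl))
  for (tid in unique(tree_ids)) {
    cols <- which(tree_ids == tid)
    m <- as.matrix(rwl[, cols, drop = FALSE])
    if (length(cols) > 1L) {
      n_common <- sum(rowSums(!is.na(m)) == length(cols))
      if (n_common == 0L) {
        stop("cores of tree '", tid, "' have no overlapping years")
      }
    }
    v <- rowMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    out[[tid]] <- v
  }
  out
}

#' Basal area increment from a ring-width series
#'
#' With `R_t` the cumulative radius at the end of year t (pith assumption
#' `R_0 = 0`), `BAI_t = pi (R_t^2 - R_{t-1}^2)` in mm^2.
#'
#' @param widths_um Ring widths in micrometers, one value per year.
#' @return Basal area increments, mm^2 per year.
#' @examples
#' compute_bai(rep(1000, 3)) # pi * c(1, 3, 5)
#' @export
compute_bai <- function(widths_um) {
  w_mm <- widths_um / 1000
  r <- cumsum(w_mm)
  pi * (r^2 - c(0, r[-length(r)])^2)
}

# -- detrending ---------------------------------------------------------------

#' Second-difference penalized smoother with a 50% frequency-response cutoff
#'
#' Minimises `sum (y - g)^2 + lambda * sum (diff(g, 2))^2`. The transfer
#' function of this filter is `H(f) = 1 / (1 + lambda (2 sin(pi f))^4)`;
#' `lambda` is chosen so that `H = f_resp` at the requested wavelength, the
#' standard frequency-cutoff specification of dendrochronological smoothing
#' splines.
#'
#' @param y Numeric series (no NA).
#' @param wavelength Wavelength (years) at which the response is `f_resp`.
#' @param f_resp Frequency response at `wavelength` (default 0.5).
#' @return The smoothed series.
#' @export
fcutoff_smooth <- function(y, wavelength, f_resp = 0.5) {
  n <- length(y)
  if (n < 4L || wavelength <= 2) return(rep(mean(y), n))
  lambda <- (1 / f_resp - 1) / (2 * sin(pi / wavelength))^4
  d2 <- diff(diag(n), differences = 2)
  a <- diag(n) + lambda * crossprod(d2)
  as.numeric(solve(a, y))
}

#' Detrend a ring-width series to a ring-width index
#'
#' Two-stage standardisation. Stage 1 removes the biological age trend by a
#' modified negative exponential `w = a exp(-b t) + k` (a, b > 0, k >= 0);
#' if that cannot be fit, a linear regression with non-positive slope; if
#' that fails too, the horizontal mean. Stage 2 removes stand-dynamics
#' variability with the penalized smoother of [fcutoff_smooth()] at a 50%
#' frequency response at `frac` times the series length. Indices are ratios
#' observed/expected at each stage, so the two stages multiply.
#'
#' @param widths Ring widths (positive, no internal NA), one per year.
#' @param frac Wavelength of the stage-2 cutoff as a fraction of series
#'   length (default 2/3).
#' @param spline Apply the stage-2 smoother (default TRUE).
#' @return Numeric RWI series with attributes `method` (stage-1 model used)
#'   and `curve` (the combined expected values).
#' @export
detrend_series <- function(widths, frac = 2 / 3, spline = TRUE) {
  w <- as.numeric(widths)
  stopifnot(all(is.finite(w)), all(w > 0))
  n <- length(w)
  t <- seq_len(n)
  expected <- NULL
  method <- "negexp"
  # stage 1: modified negative exponential
  fit <- tryCatch({
    b0 <- max(0.01, -stats::coef(stats::lm(log(w) ~ t))[[2]])
    f <- minpack.lm::nlsLM(w ~ a * exp(-b * t) + k,
                           start = list(a = max(w) - min(w) + 1e-3,
                                        b = b0, k = min(w)),
                           lower = c(a = 1e-9, b = 1e-9, k = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- stats::predict(f)
    if (any(p <= 0)) NULL else p
  }, error = function(e) NULL)
  if (!is.null(fit)) {
    expected <- fit
  } else {
    lf <- stats::lm(w ~ t)
    if (stats::coef(lf)[[2]] <= 0 && all(stats::predict(lf) > 0)) {
      expected <- stats::predict(lf)
      method <- "linear"
    } else {
      expected <- rep(mean(w), n)
      method <- "mean"
    }
  }
  rwi <- w / expected
  if (spline && n >= 10L) {
    sm <- fcutoff_smooth(rwi, wavelength = frac * n)
    sm[sm <= 0] <- mean(rwi) # guard: never divide by a non-positive level
    rwi <- rwi / sm
    expected <- expected * sm
  }
  attr(rwi, "method") <- method
  attr(rwi, "curve") <- expected
  rwi
}

#' Detrend every series of a ring-width table
#'
#' @param rwl Ring-width data frame.
#' @param ... Passed to [detrend_series()].
#' @return Data frame of RWI series, same shape as `rwl`.
#' @export
detrend_rwl <- function(rwl, ...) {
  out <- rwl
  for (j in seq_along(rwl)) {
    v <- rwl[[j]]
    ok <- !is.na(v)
    out[[j]][ok] <- as.numeric(detrend_series(v[ok], ...))
  }
  out
}

#' Prewhiten a detrended series with an AR model
#'
#' Fits AR(p) for p = 0..`max_order` by maximum likelihood, selects the
#' order by AIC and returns the residuals plus the series mean (level
#' preserved). Constant input is returned unchanged with a warning.
#'
#' @param x Detrended (RWI) series, no NA.
#' @param max_order Maximum AR order considered (default 3).
#' @return Residual series with attribute `order` (selected p).
#' @export
prewhiten <- function(x, max_order = 3L) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) {
    warning("constant series; returning unchanged")
    attr(x, "order") <- 0L
    return(x)
  }
  aics <- rep(Inf, max_order + 1L)
  fits <- vector("list", max_order + 1L)
  for (p in 0:max_order) {
    f <- tryCatch(stats::arima(x, order = c(p, 0, 0), method = "ML"),
                  error = function(e) NULL)
    if (!is.null(f)) {
      fits[[p + 1L]] <- f
      aics[p + 1L] <- f$aic
    }
  }
  if (all(!is.finite(aics))) {
    warning("no AR model could be fit; returning unchanged")
    attr(x, "order") <- NA_integer_
    return(x)
  }
  best <- which.min(aics)
  out <- as.numeric(stats::residuals(fits[[best]])) + mean(x)
  attr(out, "order") <- best - 1L
  out
}

#' Prewhiten every series of an RWI table
#' @param rwi Data frame of RWI series.
#' @param ... Passed to [prewhiten()].
#' @return Data frame of residual series; selected orders in attribute
#'   `orders`.
#' @export
prewhiten_rwl <- function(rwi, ...) {
  out <- rwi
  orders <- integer(ncol(rwi))
  for (j in seq_along(rwi)) {
    ok <- !is.na(rwi[[j]])
    pw <- prewhiten(rwi[[j]][ok], ...)
    out[[j]][ok] <- as.numeric(pw)
    orders[j] <- attr(pw, "order")
  }
  attr(out, "orders") <- stats::setNames(orders, names(rwi))
  out
}

#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate discounting outliers: weights
#' `(1 - u^2)^2` for `|u| < 1` with `u = (x - m) / (c * S)`, `S` the median
#' absolute deviation; starts at the median, at most `max_iter` iterations.
#'
#' @param x Numeric vector (NA dropped).
#' @param c Tuning constant (default 9).
#' @param max_iter Maximum iterations (default 10).
#' @return The robust mean (NA for empty input).
#' @export
tukey_biweight_mean <- function(x, c = 9, max_iter = 10L) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  m <- stats::median(x)
  for (i in seq_len(max_iter)) {
    s <- stats::median(abs(x - m))
    if (s == 0) return(m)
    u <- (x - m) / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-12) {
      return(m_new)
    }
    m <- m_new
  }
  m
}

#' Build a site chronology by robust averaging
#'
#' Per-year Tukey biweight robust mean across series, with the per-year
#' sample depth recorded.
#'
#' @param rwi Data frame of (typically prewhitened) RWI series, year
#'   rownames.
#' @return Data frame `year`, `index`, `sample_depth`; years with no series
#'   are dropped.
#' @export
build_chronology <- function(rwi) {
  m <- as.matrix(rwi)
  depth <- rowSums(!is.na(m))
  idx <- apply(m, 1, tukey_biweight_mean)
  keep <- depth >= 1L
  data.frame(year = rwl_years(rwi)[keep],
             index = as.numeric(idx[keep]),
             sample_depth = as.integer(depth[keep]))
}

#' Mean sensitivity of a ring series
#'
#' Mean absolute relative difference between consecutive values,
#' `mean(|2 (w[t+1] - w[t]) / (w[t+1] + w[t])|)`; scale-invariant.
#'
#' @param w Ring widths (one series).
#' @return Mean sensitivity (0 for a constant series).
#' @examples
#' mean_sensitivity(c(2, 1, 2)) # 2/3
#' @export
mean_sensitivity <- function(w) {
  w <- w[!is.na(w)]
  if (length(w) < 2L) return(NA_real_)
  d <- abs(2 * diff(w) / (w[-1] + w[-length(w)]))
  mean(d)
}

#' Chronology statistics
#'
#' Site-level descriptive statistics of a ring-width set: mean sensitivity
#' (MS) and first-order autocorrelation (AC1) averaged over the raw series
#' (before prewhitening, per dendro convention); mean interseries
#' correlation rbar over pairwise-common years of the prewhitened series;
#' and the derived signal-to-noise ratio `SNR = N rbar / (1 - rbar)` and
#' expressed population signal `EPS = N rbar / (N rbar + 1 - rbar)`.
#'
#' @param rwl Raw ring-width data frame (for MS, AC1).
#' @param prewhitened Prewhitened RWI data frame (for rbar); when `NULL`,
#'   rbar is computed on `rwl`.
#' @param min_overlap Minimum pairwise overlap in years for a correlation
#'   to enter rbar (default 30).
#' @return List with `ms`, `ac1`, `rbar`, `snr`, `eps`, `n_series`.
#' @export
chronology_stats <- function(rwl, prewhitened = NULL, min_overlap = 30L) {
  ms <- mean(vapply(rwl, mean_sensitivity, 0), na.rm = TRUE)
  ac1_one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
    stats::cor(x[-1], x[-length(x)])
  }
  ac1 <- mean(vapply(rwl, ac1_one, 0), na.rm = TRUE)
  base <- if (is.null(prewhitened)) rwl else prewhitened
  rbar <- interseries_rbar(base, min_overlap)
  n <- ncol(rwl)
  snr <- if (is.na(rbar) || rbar >= 1) NA_real_ else n * rbar / (1 - rbar)
  eps <- eps_from_rbar(rbar, n)
  list(ms = ms, ac1 = ac1, rbar = rbar, snr = snr, eps = eps, n_series = n)
}

#' Mean interseries correlation
#' @param rwl Ring-width or RWI data frame.
#' @param min_overlap Minimum common years per pair.
#' @return Mean of pairwise Pearson correlations (rbar).
#' @export
interseries_rbar <- function(rwl, min_overlap = 30L) {
  n <- ncol(rwl)
  if (n < 2L) return(NA_real_)
  rs <- c()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !is.na(rwl[[i]]) & !is.na(rwl[[j]])
      if (sum(ok) >= min_overlap) {
        rs <- c(rs, stats::cor(rwl[[i]][ok], rwl[[j]][ok]))
      }
    }
  }
  if (!length(rs)) NA_real_ else mean(rs)
}

#' Expressed population signal from rbar and sample size
#'
#' `EPS = N rbar / (N rbar + (1 - rbar))`, the fraction of the hypothetical
#' perfect-chronology variance captured by an N-tree chronology; commonly
#' thresholded at 0.85.
#'
#' @param rbar Mean interseries correlation.
#' @param n Number of series.
#' @return EPS in `[0, 1]`.
#' @examples
#' eps_from_rbar(0.5, 10) # 0.909...
#' @export
eps_from_rbar <- function(rbar, n) {
  n * rbar / (n * rbar + (1 - rbar))
}

#' Segment-correlation crossdating quality control
#'
#' Each series is prewhitened and split into segments of `seg_len` years
#' lagged by `overlap`; each segment is correlated against the robust mean
#' of all other prewhitened series (leave-one-out master). Segments whose
#' correlation falls below the critical value are flagged, and the lag in
#' `-max_lag..max_lag` maximising the correlation is reported as a dating
#' suggestion.
#'
#' @param rwl Ring-width data frame.
#' @param seg_len Segment length, years (default 50).
#' @param overlap Lag between successive segment starts (default 25).
#' @param r_min Flagging threshold; default the one-tailed critical r at
#'   `alpha`.
#' @param alpha Significance level for the default threshold (default 0.01).
#' @param max_lag Dating-error search range, years (default 10).
#' @return Data frame with one row per (series, segment): `series`,
#'   `start_year`, `end_year`, `n`, `r`, `flagged`, `best_lag`.
#' @export
crossdate_qc <- function(rwl, seg_len = 50L, overlap = 25L, r_min = NULL,
                         alpha = 0.01, max_lag = 10L) {
  stopifnot(ncol(rwl) >= 2L)
  years <- rwl_years(rwl)
  rwi <- detrend_rwl(rwl)
  pw <- prewhiten_rwl(rwi)
  if (is.null(r_min)) {
    df <- seg_len - 2L
    tcrit <- stats::qt(1 - alpha, df)
    r_min <- tcrit / sqrt(df + tcrit^2)
  }
  res <- list()
  for (j in seq_along(pw)) {
    series <- pw[[j]]
    master <- apply(as.matrix(pw[, -j, drop = FALSE]), 1,
                    tukey_biweight_mean)
    ok <- which(!is.na(series))
    if (!length(ok)) next
    span0 <- ok[1]; span1 <- ok[length(ok)]
    starts <- seq(span0, span1, by = overlap)
    for (s in starts) {
      e <- min(s + seg_len - 1L, span1)
      n_seg <- e - s + 1L
      if (n_seg < max(10L, seg_len %/% 2L) && s != span0) next
      idx <- s:e
      use <- idx[!is.na(series[idx]) & !is.na(master[idx])]
      if (length(use) < 10L) next
      r <- stats::cor(series[use], master[use])
      # best lag: shift the series by L relative to the master
      best_lag <- 0L; best_r <- r
      for (L in seq(-max_lag, max_lag)) {
        if (L == 0L) next
        mi <- use + L
        keep <- mi >= 1L & mi <= length(master)
        keep[keep] <- !is.na(master[mi[keep]])
        if (sum(keep) < 10L) next
        rl <- stats::cor(series[use[keep]], master[mi[keep]])
        if (is.finite(rl) && rl > best_r) {
          best_r <- rl
          best_lag <- L
        }
      }
      res[[length(res) + 1L]] <- data.frame(
        series = names(pw)[j],
        start_year = years[s], end_year = years[e], n = length(use),
        r = r, flagged = r < r_min, best_lag = best_lag,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "r_min") <- r_min
  out
}
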