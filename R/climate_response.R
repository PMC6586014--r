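#' Monthly climate predictor matrix for climate-growth analysis
#'
#' Builds the year-by-month predictor matrix used by response functions:
#' monthly mean temperature and monthly precipitation totals, with
#' previous-year months lagged into each chronology year's row. The default
#' window runs from June of the previous year through September of the
#' current year (16 months, 32 columns with both variables); previous-year
#' columns are labelled in lower case (e.g. `t.jun.prev`), current-year in
#' capitals (`T.Jun`).
#'
#' @param monthly Data frame with columns `year`, `month` (1-12), and the
#'   variables `t` (monthly mean temperature) and/or `p` (monthly total
#'   precipitation).
#' @param years Chronology years to cover (rows); years whose full window is
#'   not available are dropped and reported in attribute `dropped_years`.
#' @param start_month Month of the previous year that opens the window
#'   (default 6 = June).
#' @param end_month Month of the current year that closes it (default 9 =
#'   September).
#' @param variables Which variables to include (default both).
#' @return Numeric matrix, rownames = chronology years, one column per
#'   variable x month.
#' @export
monthly_climate_matrix <- function(monthly, years,
                                   start_month = 6L, end_month = 9L,
                                   variables = c("t", "p")) {
  stopifnot(all(c("year", "month") %in% names(monthly)),
            all(variables %in% names(monthly)))
  mnames <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
              "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
  # window: (prev year, start_month..12) then (current, 1..end_month)
  win <- rbind(
    data.frame(offset = -1L, month = seq(start_month, 12L)),
    data.frame(offset = 0L, month = seq(1L, end_month))
  )
  cols <- character(0)
  for (v in variables) {
    lab <- ifelse(win$offset < 0L,
                  paste0(tolower(v), ".", tolower(mnames[win$month]), ".prev"),
                  paste0(toupper(v), ".", mnames[win$month]))
    cols <- c(cols, lab)
  }
  key <- paste(monthly$year, monthly$month)
  x <- matrix(NA_real_, nrow = length(years), ncol = length(cols),
              dimnames = list(as.character(years), cols))
  ci <- 0L
  for (v in variables) {
    for (k in seq_len(nrow(win))) {
      ci <- ci + 1L
      idx <- match(paste(years + win$offset[k], win$month[k]), key)
      x[, ci] <- monthly[[v]][idx]
    }
  }
  ok <- stats::complete.cases(x)
  dropped <- years[!ok]
  x <- x[ok, , drop = FALSE]
  attr(x, "dropped_years") <- dropped
  x
}

#' Static bootstrap principal-components response function
#'
#' Relates a (residual) chronology to monthly climate predictors while
#' accounting for their collinearity: predictors and chronology are
#' standardized, predictors are decomposed into principal components,
#' components passing the retention rule (Kaiser, eigenvalue > 1, by
#' default) are kept, the chronology is regressed on their scores and the
#' coefficients are rotated back onto the original monthly variables.
#' Uncertainty comes from bootstrap resampling of years with replacement;
#' a coefficient is significant when its percentile confidence interval
#' excludes zero.
#'
#' @param chron Numeric chronology values, aligned with the rows of `x`
#'   (or a data frame from [build_chronology()], matched by year rownames).
#' @param x Predictor matrix from [monthly_climate_matrix()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided significance level (default 0.05).
#' @param seed Random seed for the bootstrap.
#' @param eigen_min PC retention threshold on the correlation-matrix
#'   eigenvalues (default 1, the Kaiser rule); use 0 to retain all.
#' @param min_years Minimum number of common years (default 30).
#' @return Data frame with one row per predictor column: `variable`,
#'   `coef` (median bootstrap coefficient), `ci_lower`, `ci_upper`,
#'   `significant`; metadata in attributes `n_boot`, `alpha`, `n_years`,
#'   `n_pcs` (retained components on the full sample).
#' @export
static_response <- function(chron, x, n_boot = 1000L, alpha = 0.05,
                            seed = NULL, eigen_min = 1, min_years = 30L) {
  if (is.data.frame(chron)) {
    idx <- match(rownames(x), as.character(chron$year))
    if (anyNA(idx)) stop("chronology does not cover all predictor years")
    y <- chron$index[idx]
  } else {
    stopifnot(length(chron) == nrow(x))
    y <- as.numeric(chron)
  }
  n <- nrow(x)
  if (n < min_years) {
    stop("only ", n, " common years; need at least ", min_years)
  }
  if (!is.null(seed)) set.seed(seed)
  # rotation and retention are estimated once on the full sample; the
  # bootstrap resamples years of the fixed score matrix (the classical
  # design for bootstrapped response functions)
  xs <- scale(x)
  if (any(attr(xs, "scaled:scale") == 0)) {
    stop("constant climate column; cannot standardize")
  }
  ys <- as.numeric(scale(y))
  eg <- eigen(crossprod(xs) / (n - 1), symmetric = TRUE)
  keep <- which(eg$values > eigen_min)
  if (!length(keep)) {
    stop("no principal component passes the retention rule ",
         "(all eigenvalues <= ", eigen_min, ")")
  }
  n_pcs <- length(keep)
  v <- eg$vectors[, keep, drop = FALSE]
  scores <- xs %*% v
  full <- as.numeric(v %*% stats::lm.fit(scores, ys)$coefficients)

  boot <- matrix(NA_real_, nrow = n_boot, ncol = ncol(x))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    gamma <- stats::lm.fit(scores[idx, , drop = FALSE],
                           ys[idx])$coefficients
    boot[b, ] <- as.numeric(v %*% gamma)
  }
  qs <- apply(boot, 2, stats::quantile,
              probs = c(alpha / 2, 0.5, 1 - alpha / 2), na.rm = TRUE)
  out <- data.frame(
    variable = colnames(x),
    coef = qs[2, ],
    ci_lower = qs[1, ],
    ci_upper = qs[3, ],
    stringsAsFactors = FALSE
  )
  out$significant <- out$ci_lower > 0 | out$ci_upper < 0
  attr(out, "coef_full") <- stats::setNames(full, colnames(x))
  attr(out, "n_boot") <- n_boot
  attr(out, "alpha") <- alpha
  attr(out, "n_years") <- n
  attr(out, "n_pcs") <- n_pcs
  rownames(out) <- NULL
  out
}

#' Moving-window bootstrap response function
#'
#' [static_response()] evaluated on sliding windows of fixed width, the
#' standard tool to detect temporal change in climate-growth relations.
#' Windows whose minimum chronology sample depth falls below `min_depth`
#' are skipped when depths are supplied.
#'
#' @param chron Chronology data frame (`year`, `index`, optionally
#'   `sample_depth`) or numeric vector aligned with `x` rows.
#' @param x Predictor matrix from [monthly_climate_matrix()].
#' @param window Window width in years (default 25).
#' @param step Window step in years (default 1).
#' @param alpha Significance level (default 0.1, the moving-analysis
#'   convention).
#' @param n_boot Bootstrap resamples per window (default 1000).
#' @param seed Random seed.
#' @param min_depth Minimum sample depth per window (default 5 trees);
#'   applied only when `chron` carries `sample_depth`.
#' @param ... Passed to [static_response()].
#' @return Data frame stacking the per-window results, with columns
#'   `win_start`, `win_end` prepended.
#' @export
moving_response <- function(chron, x, window = 25L, step = 1L, alpha = 0.1,
                            n_boot = 1000L, seed = NULL, min_depth = 5L,
                            ...) {
  years <- as.integer(rownames(x))
  n <- nrow(x)
  if (n < window) stop("overlap (", n, " yr) shorter than window (", window, ")")
  if (is.data.frame(chron)) {
    idx <- match(rownames(x), as.character(chron$year))
    if (anyNA(idx)) stop("chronology does not cover all predictor years")
    y <- chron$index[idx]
    depth <- if (!is.null(chron$sample_depth)) chron$sample_depth[idx] else NULL
  } else {
    y <- as.numeric(chron)
    depth <- NULL
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- seq(1L, n - window + 1L, by = step)
  res <- list()
  for (s in starts) {
    idx <- s:(s + window - 1L)
    if (!is.null(depth) && min(depth[idx]) < min_depth) next
    r <- static_response(y[idx], x[idx, , drop = FALSE], n_boot = n_boot,
                         alpha = alpha, seed = NULL, min_years = window, ...)
    r <- cbind(data.frame(win_start = years[s],
                          win_end = years[s + window - 1L]), r)
    res[[length(res) + 1L]] <- r
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_windows") <- length(res)
  out
}
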