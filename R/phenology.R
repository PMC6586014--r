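#' Gompertz growth curve (growth-parameter form)
#'
#' The sigmoid used for seasonal radial growth, in the parameterisation whose
#' parameters are directly interpretable: `A` the upper asymptote (total
#' yearly growth, micrometers), `mu` the maximum growth rate (um/day), `lam`
#' the lag phase / start of growth (day of year):
#' \deqn{y(t) = A \exp(-\exp(\mu e / A (\lambda - t) + 1))}
#' The inflection point is analytic, \eqn{I_p = \lambda + A/(e\mu)}, the
#' curve value there is \eqn{A/e} and the slope there is exactly `mu`.
#'
#' @param t Day of year (numeric vector).
#' @param A Upper asymptote, > 0.
#' @param mu Maximum growth rate, > 0.
#' @param lam Lag parameter (DOY at which the tangent at the inflection
#'   crosses zero).
#' @return Cumulative growth at `t`, same units as `A`.
#' @examples
#' gompertz_curve(157.6, A = 1500, mu = 25, lam = 130) # ~A/e
#' @export
gompertz_curve <- function(t, A, mu, lam) {
  if (any(A <= 0) || any(mu <= 0)) stop("A and mu must be positive")
  A * exp(-exp(mu * exp(1) / A * (lam - t) + 1))
}

#' Inflection point of a Gompertz fit
#'
#' @param A,mu,lam Gompertz parameters as in [gompertz_curve()].
#' @return DOY of maximum growth rate, `lam + A / (e * mu)`.
#' @export
gompertz_ip <- function(A, mu, lam) {
  lam + A / (exp(1) * mu)
}

#' Fit a Gompertz curve to a seasonal cumulative-growth series
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the growth-parameter
#' Gompertz form, with a small multistart around data-driven initial values
#' (A = observed maximum, mu = maximum daily increment, lam = first day
#' exceeding 5% of the maximum). The series should be shifted to start at
#' zero increment (subtract the pre-season level before fitting).
#'
#' @param doy Day-of-year vector.
#' @param gro Cumulative growth (micrometers), same length as `doy`.
#' @param init Optional list with `A`, `mu`, `lam` overriding the
#'   data-driven start.
#' @return A one-row data frame: `A`, `mu`, `lam`, `ip`, `rss`, `converged`.
#'   On non-convergence from every start, parameters are `NA` and
#'   `converged` is `FALSE`.
#' @export
fit_gompertz <- function(doy, gro, init = NULL) {
  stopifnot(length(doy) == length(gro))
  keep <- is.finite(doy) & is.finite(gro)
  doy <- doy[keep]; gro <- gro[keep]
  failed <- data.frame(A = NA_real_, mu = NA_real_, lam = NA_real_,
                       ip = NA_real_, rss = NA_real_, converged = FALSE)
  if (length(doy) < 10L || max(gro) <= 0 || stats::sd(gro) == 0) {
    return(failed)
  }
  a0 <- max(gro)
  d <- diff(gro) / diff(doy)
  mu0 <- max(d[is.finite(d)], 0)
  if (mu0 <= 0) mu0 <- a0 / diff(range(doy))
  lam0 <- doy[which(gro > 0.05 * a0)[1]]
  if (is.na(lam0)) lam0 <- stats::median(doy)
  starts <- list(list(A = a0, mu = mu0, lam = lam0))
  if (!is.null(init)) starts <- c(list(init), starts)
  # perturbed restarts
  for (fA in c(1.2, 0.9)) {
    for (fl in c(-10, 10)) {
      starts[[length(starts) + 1L]] <-
        list(A = a0 * fA, mu = mu0 * fA, lam = lam0 + fl)
    }
  }
  best <- NULL
  dat <- data.frame(t = doy, y = gro)
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-exp(mu * exp(1) / A * (lam - t) + 1)),
        data = dat,
        start = list(A = s$A, mu = max(s$mu, 1e-6), lam = s$lam),
        lower = c(A = 1e-6, mu = 1e-9, lam = min(doy) - 200),
        upper = c(A = 50 * a0, mu = Inf, lam = max(doy) + 200),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(A = cf[["A"]], mu = cf[["mu"]], lam = cf[["lam"]],
                   rss = rss)
    }
  }
  if (is.null(best)) return(failed)
  data.frame(A = best$A, mu = best$mu, lam = best$lam,
             ip = gompertz_ip(best$A, best$mu, best$lam),
             rss = best$rss, converged = TRUE)
}

#' Fit Gompertz phenology per tree and year
#'
#' Convenience wrapper applying [fit_gompertz()] to each (tree, year) group
#' of a daily GRO table, after shifting each season to start at zero.
#'
#' @param gro_daily Data frame with `tree_id`, `date`, `gro` (daily maximum
#'   GRO, micrometers).
#' @return Data frame with one row per tree-year: `tree_id`, `year`, the fit
#'   columns of [fit_gompertz()].
#' @export
fit_gompertz_by_tree <- function(gro_daily) {
  stopifnot(all(c("tree_id", "date", "gro") %in% names(gro_daily)))
  gro_daily$year <- as.integer(format(gro_daily$date, "%Y"))
  groups <- split(gro_daily, list(gro_daily$tree_id, gro_daily$year),
                  drop = TRUE)
  res <- lapply(groups, function(g) {
    doy <- as.integer(format(g$date, "%j"))
    f <- fit_gompertz(doy, g$gro - min(g$gro))
    cbind(data.frame(tree_id = g$tree_id[1], year = g$year[1]), f)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
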