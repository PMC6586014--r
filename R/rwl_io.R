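#' Read a Tucson (RWL) ring-width file
#'
#' Decadal-row Tucson format: series id in columns 1-8, the decade's first
#' year, then up to ten width values. Both common precision dialects are
#' auto-detected from the stop marker: 999 marks 0.01 mm units, -9999 marks
#' 0.001 mm units. Widths are returned in micrometers.
#'
#' @param path Path to the `.rwl` file.
#' @return Ring-width data frame (year rownames, one column per series).
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # skip optional 3-line Tucson header (non-data lines)
  series <- list()
  for (ln in lines) {
    id <- trimws(substr(ln, 1, 8))
    rest <- trimws(substr(ln, 9, nchar(ln)))
    toks <- strsplit(rest, "\\s+")[[1]]
    if (length(toks) < 2L) next
    year <- suppressWarnings(as.integer(toks[1]))
    vals <- suppressWarnings(as.numeric(toks[-1]))
    if (is.na(year) || anyNA(vals)) next # header or comment line
    if (is.null(series[[id]])) {
      series[[id]] <- numeric(0)
      attr(series[[id]], "first_year") <- year
    }
    fy <- attr(series[[id]], "first_year")
    v <- c(series[[id]], vals)
    attr(v, "first_year") <- fy
    series[[id]] <- v
  }
  # the stop marker is the LAST value of each series; it decides the dialect
  # (999 intra-series is a legitimate 0.999 mm ring and must be kept)
  for (id in names(series)) {
    v <- as.numeric(series[[id]])
    fy <- attr(series[[id]], "first_year")
    u <- 1 # micrometers per stored unit when 0.001 mm
    last <- v[length(v)]
    if (isTRUE(last == -9999)) {
      v <- v[-length(v)]
    } else if (isTRUE(last == 999)) {
      v <- v[-length(v)]
      u <- 10
    }
    v <- v * u
    v[v < 0] <- NA_real_
    attr(v, "first_year") <- fy
    series[[id]] <- v
  }
  as_rwl(series)
}

#' Write a ring-width table to a Tucson (RWL) file
#'
#' @param rwl Ring-width data frame in micrometers.
#' @param path Output path.
#' @param precision Output dialect: `0.001` mm (stop marker -9999, default)
#'   or `0.01` mm (stop marker 999).
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rwl, path, precision = 0.001) {
  stopifnot(precision %in% c(0.001, 0.01))
  div <- if (precision == 0.001) 1 else 10
  stopmark <- if (precision == 0.001) -9999 else 999
  years <- rwl_years(rwl)
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(rwl)) {
    v <- rwl[[nm]]
    ok <- which(!is.na(v))
    y0 <- years[ok[1]]; y1 <- years[ok[length(ok)]]
    vals <- round(v[ok[1]:ok[length(ok)]] / div)
    yrs <- y0:y1
    vals <- c(vals, stopmark)
    yrs <- c(yrs, y1 + 1L)
    i <- 1L
    while (i <= length(vals)) {
      decade_end <- (yrs[i] %/% 10) * 10 + 9
      j <- max(which(yrs <= decade_end))
      row_vals <- vals[i:j]
      cat(sprintf("%-8s%4d%s\n", substr(nm, 1, 8), yrs[i],
                  paste(sprintf("%6d", row_vals), collapse = "")),
          file = con)
      i <- j + 1L
    }
  }
  invisible(path)
}
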