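#' @keywords internal
bioclim_vars <- function() c("mat", "ts", "twp", "ap", "ps", "pdp")

new_climate_stack <- function(layers, grid) {
  structure(c(layers[bioclim_vars()], list(grid = grid)),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  cat("<climate_stack> layers:", paste(bioclim_vars(), collapse = ", "), "\n")
  print(x$grid)
  invisible(x)
}

#' Convert a climate stack to a wide tibble
#'
#' @param x A `climate_stack`.
#' @param ... Unused.
#' @return Tibble with `cell, row, col, x, y` and one column per bioclim
#'   variable.
#' @method as_tibble climate_stack
#' @export
as_tibble.climate_stack <- function(x, ...) {
  out <- cell_centers(x$grid)
  for (v in bioclim_vars()) out[[v]] <- as.vector(x[[v]])
  out
}

# population (divide-by-n) standard deviation along the 3rd array margin
pop_sd_3 <- function(a) {
  mu <- rowMeans(a, dims = 2)
  sq <- (a - as.vector(mu))^2
  sqrt(rowMeans(sq, dims = 2))
}

#' Derive the six bioclimatic variables from a monthly climate series
#'
#' Computes, cell-wise over the 12 monthly values:
#' * `mat` - annual mean temperature (degrees C);
#' * `ts`  - temperature seasonality: the population standard deviation of
#'   the period means expressed as a percentage of the annual mean
#'   (`100 * sd(T) / mat`), or plain `100 * sd(T)` under the `"sd_x100"`
#'   convention;
#' * `twp` - maximum temperature of the warmest period (degrees C);
#' * `ap`  - annual precipitation (mm, sum of months);
#' * `ps`  - precipitation seasonality, `100 * sd(P) / mean(P)` (0 where the
#'   mean is 0);
#' * `pdp` - precipitation of the driest period (mm, minimum month).
#'
#' Periods are calendar months. Nodata (`NA`) propagates. Cells where
#' `mat <= 0` leave `ts` undefined under the percent-of-mean convention; they
#' are set to nodata with a warning.
#'
#' @param series A `monthly_climate` from [make_monthly_climate()].
#' @param ts_convention `"percent_of_mean"` (default) or `"sd_x100"`.
#' @return A `climate_stack` with layers `mat, ts, twp, ap, ps, pdp`.
#' @export
derive_bioclim <- function(series,
                           ts_convention = c("percent_of_mean", "sd_x100")) {
  stopifnot(inherits(series, "monthly_climate"))
  ts_convention <- match.arg(ts_convention)
  tarr <- series$temperature
  parr <- series$precipitation
  stopifnot(dim(tarr)[3] == 12, dim(parr)[3] == 12)

  mat <- rowMeans(tarr, dims = 2)
  tsd <- pop_sd_3(tarr)
  if (ts_convention == "percent_of_mean") {
    bad <- !is.na(mat) & mat <= 0
    if (any(bad)) {
      warning(
        sum(bad), " cell(s) have annual mean temperature <= 0; ",
        "temperature seasonality set to nodata there"
      )
    }
    ts <- ifelse(bad, NA_real_, 100 * tsd / mat)
  } else {
    ts <- 100 * tsd
  }
  twp <- apply(tarr, c(1, 2), max)
  ap <- rowSums(parr, dims = 2)
  pmean <- rowMeans(parr, dims = 2)
  psd <- pop_sd_3(parr)
  ps <- ifelse(!is.na(pmean) & pmean == 0, 0, 100 * psd / pmean)
  pdp <- apply(parr, c(1, 2), min)

  new_climate_stack(
    list(mat = mat, ts = ts, twp = twp, ap = ap, ps = ps, pdp = pdp),
    series$grid
  )
}

#' Average yearly monthly-climate series over a time window
#'
#' Month-wise arithmetic mean of the yearly series whose year labels fall in
#' the closed window `[center_year - half_window_years, center_year +
#' half_window_years]`. Used to turn interannually varying series into the
#' smoothed climatology representing a decade label.
#'
#' @param series_by_year List of `monthly_climate` objects (any order); each
#'   carries its `year_label`.
#' @param center_year Centre of the window.
#' @param half_window_years Half-width of the closed window (default 10, i.e.
#'   21 yearly series).
#' @return A `monthly_climate` labelled `center_year`.
#' @export
window_average <- function(series_by_year, center_year, half_window_years = 10) {
  stopifnot(length(series_by_year) >= 1)
  years_have <- vapply(series_by_year, `[[`, numeric(1), "year_label")
  years_need <- seq(center_year - half_window_years,
    center_year + half_window_years,
    by = 1
  )
  missing <- setdiff(years_need, years_have)
  if (length(missing) > 0) {
    stop("missing yearly series for window [",
      min(years_need), ", ", max(years_need), "]: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  use <- series_by_year[years_have %in% years_need]
  out <- use[[1]]
  tsum <- out$temperature
  psum <- out$precipitation
  for (s in use[-1]) {
    check_same_grid(s$grid, out$grid)
    tsum <- tsum + s$temperature
    psum <- psum + s$precipitation
  }
  out$temperature <- tsum / length(use)
  out$precipitation <- psum / length(use)
  out$year_label <- center_year
  out
}
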