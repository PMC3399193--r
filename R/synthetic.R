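#' Generate a mosaic of contiguous labelled subregions
#'
#' Partitions the grid into `n_regions` contiguous biogeographic subregions by
#' a Voronoi tessellation of cell centres around `n_regions` uniformly drawn
#' seed cells. The mosaic stands in for real biogeographic regionalisations
#' used to clip potential distributions to occupied subregions.
#'
#' @param grid A [grid_spec()].
#' @param n_regions Number of regions, between 1 and the number of cells.
#' @param seed Integer seed; the partition is reproducible under a fixed seed.
#' @return A `region_mosaic`: list with `labels` (integer matrix of region ids
#'   1..n_regions), `region_ids`, `seed_cells`, `grid`.
#' @export
make_region_mosaic <- function(grid, n_regions, seed = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  nc <- n_cells(grid)
  if (n_regions < 1 || n_regions > nc) {
    stop("`n_regions` must be between 1 and the number of cells (", nc, ")",
      call. = FALSE
    )
  }
  centers <- cell_centers(grid)
  seed_cells <- with_seed(
    derive_seed(seed, "mosaic"),
    sort(sample.int(nc, n_regions))
  )
  sx <- centers$x[seed_cells]
  sy <- centers$y[seed_cells]
  # squared Euclidean distance cell -> each seed; ties resolved to the lowest
  # region id so the partition is deterministic
  d2 <- outer(centers$x, sx, "-")^2 + outer(centers$y, sy, "-")^2
  lab <- max.col(-d2, ties.method = "first")
  structure(
    list(
      labels = new_raster(as.integer(lab), grid),
      region_ids = seq_len(n_regions),
      seed_cells = seed_cells,
      grid = grid
    ),
    class = "region_mosaic"
  )
}

#' Generate a 12-month baseline climate series
#'
#' Builds a synthetic monthly climatology on a km grid: temperature follows a
#' south-north gradient plus a seasonal cosine cycle plus cell-month noise;
#' precipitation distributes an annual total over the months, concentrated in
#' a wet season, with its own (optional) meridional gradient and fractional
#' noise. This emulates the structure of interpolated monthly climate surfaces
#' (strongly seasonal, spatially smooth with local variation).
#'
#' @param grid A [grid_spec()].
#' @param south_north_temp_gradient Temperature change in degrees C per
#'   1000 km of northing (negative: cooler to the north).
#' @param seasonal_amplitude Amplitude (degrees C) of the annual temperature
#'   cycle; must be >= 0.
#' @param wet_season_months Integer months (1-12) receiving `wet_fraction` of
#'   annual precipitation.
#' @param mean_annual_precip Domain-mean annual precipitation, mm; must be >= 0.
#' @param noise_sd SD (degrees C) of independent cell-month temperature noise.
#' @param seed Integer seed (bit-reproducible output under a fixed seed).
#' @param base_temp Domain-mean annual temperature at the grid's mid-northing.
#' @param peak_month Month of the temperature maximum.
#' @param wet_fraction Fraction of annual precipitation falling in
#'   `wet_season_months`.
#' @param precip_gradient_per_1000km Fractional change in annual precipitation
#'   per 1000 km of northing.
#' @param precip_noise_frac SD of multiplicative cell-month precipitation
#'   noise (fraction of the monthly mean).
#' @param year_label Calendar year the series represents.
#' @return A `monthly_climate`: list with 3-d arrays `temperature` and
#'   `precipitation` (`n_rows x n_cols x 12`), `grid`, `year_label`.
#' @export
make_monthly_climate <- function(grid,
                                 south_north_temp_gradient = -10,
                                 seasonal_amplitude = 4,
                                 wet_season_months = c(12, 1, 2, 3),
                                 mean_annual_precip = 1000,
                                 noise_sd = 0.3,
                                 seed = 1,
                                 base_temp = 25,
                                 peak_month = 1,
                                 wet_fraction = 0.85,
                                 precip_gradient_per_1000km = 1.5,
                                 precip_noise_frac = 0.05,
                                 year_label = 1990) {
  stopifnot(inherits(grid, "grid_spec"))
  if (seasonal_amplitude < 0 || mean_annual_precip < 0 || noise_sd < 0 ||
    precip_noise_frac < 0 || wet_fraction < 0 || wet_fraction > 1) {
    stop("amplitude, precipitation and noise parameters must be non-negative ",
      "(and `wet_fraction` in [0,1])",
      call. = FALSE
    )
  }
  wet_season_months <- as.integer(wet_season_months)
  if (length(wet_season_months) == 0 ||
    any(wet_season_months < 1 | wet_season_months > 12)) {
    stop("`wet_season_months` must be a non-empty subset of 1:12", call. = FALSE)
  }
  nr <- grid$n_rows
  nc <- grid$n_cols
  centers <- cell_centers(grid)
  y_mid <- grid$origin_y + nr * grid$cell_size_km / 2
  dy_km <- matrix(centers$y - y_mid, nr, nc)

  months <- 1:12
  seasonal <- seasonal_amplitude * cos(2 * pi * (months - peak_month) / 12)
  wet <- months %in% wet_season_months
  w <- numeric(12)
  w[wet] <- wet_fraction / sum(wet)
  if (any(!wet)) w[!wet] <- (1 - wet_fraction) / sum(!wet)

  temp <- array(NA_real_, c(nr, nc, 12))
  prec <- array(NA_real_, c(nr, nc, 12))
  t_spatial <- base_temp + south_north_temp_gradient * dy_km / 1000
  p_spatial <- pmax(0.05, 1 + precip_gradient_per_1000km * dy_km / 1000)
  with_seed(derive_seed(seed, "monthly-climate", year_label), {
    for (m in months) {
      tn <- if (noise_sd > 0) matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc) else 0
      pn <- if (precip_noise_frac > 0) {
        matrix(stats::rnorm(nr * nc, 0, precip_noise_frac), nr, nc)
      } else {
        0
      }
      temp[, , m] <- t_spatial + seasonal[m] + tn
      prec[, , m] <- pmax(0, mean_annual_precip * w[m] * p_spatial * (1 + pn))
    }
  })
  structure(
    list(temperature = temp, precipitation = prec, grid = grid,
         year_label = year_label),
    class = "monthly_climate"
  )
}

#' Describe a global circulation model for synthetic futures
#'
#' @param gcm_id Label for the circulation model.
#' @param n_realizations Number of realizations (runs) available; >= 1.
#' @param temp_trend_per_decade Warming trend, degrees C per decade.
#' @param precip_factor_per_decade Multiplicative precipitation change per
#'   decade; must be > 0 (e.g. 0.99 for -1% per decade).
#' @param realization_noise_sd_temp SD (degrees C) of the per-realization
#'   temperature offset.
#' @param realization_noise_sd_precip SD (fraction) of the per-realization
#'   precipitation scaling noise.
#' @return A `gcm_spec` list.
#' @export
gcm_spec <- function(gcm_id, n_realizations,
                     temp_trend_per_decade,
                     precip_factor_per_decade = 1,
                     realization_noise_sd_temp = 0.1,
                     realization_noise_sd_precip = 0.02) {
  if (n_realizations < 1) stop("`n_realizations` must be >= 1", call. = FALSE)
  if (precip_factor_per_decade <= 0) {
    stop("`precip_factor_per_decade` must be > 0", call. = FALSE)
  }
  structure(
    list(
      gcm_id = as.character(gcm_id),
      n_realizations = as.integer(n_realizations),
      temp_trend_per_decade = temp_trend_per_decade,
      precip_factor_per_decade = precip_factor_per_decade,
      realization_noise_sd_temp = realization_noise_sd_temp,
      realization_noise_sd_precip = realization_noise_sd_precip
    ),
    class = "gcm_spec"
  )
}

#' Generate future monthly climate series for a GCM ensemble
#'
#' For every combination of circulation model, realization and decade, shifts
#' the baseline temperatures by `trend x elapsed decades` plus a realization
#' noise offset, and scales precipitation by `factor^elapsed` times a
#' realization noise factor (clamped at zero). Elapsed decades are counted
#' from the baseline's `year_label`.
#'
#' @param baseline A `monthly_climate` from [make_monthly_climate()].
#' @param gcms List of [gcm_spec()] objects.
#' @param decades Numeric vector of decade year labels (e.g. `seq(1990, 2080,
#'   10)`); must be non-empty.
#' @param seed Integer seed; draws are keyed by (gcm, realization, decade) so
#'   the collection is reproducible regardless of iteration order.
#' @return A tibble with columns `gcm_id`, `realization`, `decade`, `series`
#'   (list-column of `monthly_climate`); `sum(n_realizations)` rows per decade.
#' @export
make_future_series <- function(baseline, gcms, decades, seed = 1) {
  stopifnot(inherits(baseline, "monthly_climate"))
  if (length(decades) == 0) stop("`decades` must be non-empty", call. = FALSE)
  if (inherits(gcms, "gcm_spec")) gcms <- list(gcms)
  stopifnot(all(vapply(gcms, inherits, logical(1), "gcm_spec")))
  rows <- list()
  for (g in gcms) {
    for (decade in as.numeric(decades)) {
      elapsed <- (decade - baseline$year_label) / 10
      for (r in seq_len(g$n_realizations)) {
        noise <- with_seed(
          derive_seed(seed, "future", g$gcm_id, r, decade),
          list(
            dt = stats::rnorm(1, 0, g$realization_noise_sd_temp),
            dp = stats::rnorm(1, 0, g$realization_noise_sd_precip)
          )
        )
        shift <- g$temp_trend_per_decade * elapsed + noise$dt
        scale <- g$precip_factor_per_decade^elapsed * max(0, 1 + noise$dp)
        series <- baseline
        series$temperature <- baseline$temperature + shift
        series$precipitation <- pmax(baseline$precipitation * scale, 0)
        series$year_label <- decade
        rows[[length(rows) + 1]] <- tibble::tibble(
          gcm_id = g$gcm_id, realization = r, decade = decade,
          series = list(series)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Species metadata record
#'
#' @param species_id Species identifier.
#' @param movement_class One of `"M"` (migratory), `"N"` (nomadic), `"P"`
#'   (partially migratory), `"S"` (sedentary), `"SN"` (sedentary/nomadic).
#' @param biogeo_group One of `"arid"`, `"CYP"`, `"temperate"`, `"tropical"`,
#'   `"ubiquitous"`.
#' @param dispersal_category One of `"full"`, `"rate_limited"`, `"none"`.
#' @param dispersal_rate_km_per_year Dispersal rate, km/yr; required (default
#'   3) when `dispersal_category = "rate_limited"` and must be absent
#'   otherwise.
#' @param status Optional conservation status label.
#' @return A one-row tibble.
#' @export
species_meta <- function(species_id, movement_class, biogeo_group,
                         dispersal_category,
                         dispersal_rate_km_per_year = if (identical(dispersal_category, "rate_limited")) 3 else NULL,
                         status = NA_character_) {
  movement_class <- match.arg(movement_class, c("M", "N", "P", "S", "SN"))
  biogeo_group <- match.arg(
    biogeo_group, c("arid", "CYP", "temperate", "tropical", "ubiquitous")
  )
  dispersal_category <- match.arg(
    dispersal_category, c("full", "rate_limited", "none")
  )
  if (identical(dispersal_category, "rate_limited")) {
    if (is.null(dispersal_rate_km_per_year) || is.na(dispersal_rate_km_per_year)) {
      stop("rate-limited species need `dispersal_rate_km_per_year`", call. = FALSE)
    }
  } else if (!is.null(dispersal_rate_km_per_year)) {
    stop("`dispersal_rate_km_per_year` is only meaningful for rate-limited ",
      "species",
      call. = FALSE
    )
  }
  tibble::tibble(
    species_id = as.character(species_id),
    movement_class = movement_class,
    biogeo_group = biogeo_group,
    dispersal_category = dispersal_category,
    dispersal_rate_km_per_year =
      if (is.null(dispersal_rate_km_per_year)) NA_real_ else dispersal_rate_km_per_year,
    status = status
  )
}

#' Create a virtual species with a known Gaussian climatic niche
#'
#' True suitability at a cell is `exp(-0.5 * sum_v ((x_v - c_v) / w_v)^2)`
#' over the six bioclim variables, so suitability is 1 at the niche centre and
#' decays with climatic (Mahalanobis-style, axis-aligned) distance. The true
#' range is the set of cells with suitability at or above
#' `prevalence_threshold`.
#'
#' @param niche_center Named numeric vector over the six bioclim variables
#'   (`mat, ts, twp, ap, ps, pdp`).
#' @param niche_width Positive named numeric vector, same variables.
#' @param prevalence_threshold Suitability cutoff in (0, 1] defining the true
#'   range.
#' @param meta A one-row metadata tibble from [species_meta()].
#' @param climate A `climate_stack` (see [derive_bioclim()]).
#' @return A `virtual_species`: list with `meta`, `niche_center`,
#'   `niche_width`, `prevalence_threshold`, `suitability` (matrix in \[0,1\]),
#'   `true_range` (0/1 matrix), `grid`.
#' @export
make_virtual_species <- function(niche_center, niche_width,
                                 prevalence_threshold, meta, climate) {
  stopifnot(inherits(climate, "climate_stack"))
  vars <- bioclim_vars()
  if (!all(vars %in% names(niche_center)) || !all(vars %in% names(niche_width))) {
    stop("`niche_center` and `niche_width` must name all of: ",
      paste(vars, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(niche_width[vars] <= 0)) {
    stop("`niche_width` must be strictly positive for every variable",
      call. = FALSE
    )
  }
  grid <- climate$grid
  z2 <- matrix(0, grid$n_rows, grid$n_cols)
  for (v in vars) {
    z2 <- z2 + ((climate[[v]] - niche_center[[v]]) / niche_width[[v]])^2
  }
  suit <- exp(-0.5 * z2)
  structure(
    list(
      meta = meta,
      niche_center = niche_center[vars],
      niche_width = niche_width[vars],
      prevalence_threshold = prevalence_threshold,
      suitability = suit,
      true_range = new_raster(
        as.numeric(!is.na(suit) & suit >= prevalence_threshold), grid
      ) + suit * 0, # propagate NA
      grid = grid
    ),
    class = "virtual_species"
  )
}

#' Sample presence-only occurrence records
#'
#' Draws `n_points` presence records with per-cell probability proportional to
#' `suitability * bias` (atlas-style sampling: repeats per cell are allowed).
#' Points are reported at cell-centre coordinates.
#'
#' @param suitability Suitability matrix in \[0, 1\] (`NA` = nodata).
#' @param grid A [grid_spec()].
#' @param n_points Number of records to draw; >= 1.
#' @param bias Optional non-negative bias matrix (e.g. accessibility); `NULL`
#'   for unbiased sampling.
#' @param seed Integer seed; the point set is reproducible under a fixed seed.
#' @param species_id Optional id recorded with each point.
#' @return Tibble `species_id, cell, row, col, x, y`.
#' @export
sample_occurrences <- function(suitability, grid, n_points, bias = NULL,
                               seed = 1, species_id = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"), n_points >= 1)
  w <- as.vector(suitability)
  if (!is.null(bias)) w <- w * as.vector(bias)
  w[is.na(w)] <- 0
  if (all(w <= 0)) {
    stop("no suitable habitat: all sampling weights are zero",
      call. = FALSE
    )
  }
  cells <- with_seed(
    derive_seed(seed, "occurrences", species_id),
    sample.int(length(w), n_points, replace = TRUE, prob = w)
  )
  centers <- cell_centers(grid)
  out <- centers[cells, ]
  out <- tibble::add_column(out, species_id = species_id, .before = 1)
  out
}
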