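new_binary_range <- function(presence, grid, species_id = NA_character_,
                             decade = NA_real_, scenario = NA_character_,
                             threshold = NA_real_) {
  structure(
    list(
      presence = presence, grid = grid, species_id = species_id,
      decade = decade, scenario = scenario, threshold = threshold
    ),
    class = "binary_range"
  )
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf(
    "<binary_range> %s decade=%s scenario=%s: %d presence cells\n",
    ifelse(is.na(x$species_id), "(unnamed)", x$species_id),
    format(x$decade), format(x$scenario),
    sum(x$presence == 1, na.rm = TRUE)
  ))
  invisible(x)
}

#' Threshold a suitability map into a binary range
#'
#' Cells with suitability greater than or equal to the threshold become
#' presence (1), cells below it absence (0); nodata stays nodata.
#'
#' @param map A `suitability_map`.
#' @param threshold Threshold in (0, 1), typically the entropy-equating
#'   logistic threshold from [entropy_threshold()].
#' @param decade,scenario Labels stored on the result.
#' @return A `binary_range`.
#' @export
binarize <- function(map, threshold, decade = NA_real_,
                     scenario = NA_character_) {
  stopifnot(inherits(map, "suitability_map"))
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly in (0, 1)", call. = FALSE)
  }
  pres <- ifelse(is.na(map$values), NA_real_, as.numeric(map$values >= threshold))
  new_binary_range(
    new_raster(pres, map$grid), map$grid,
    species_id = map$species_id, decade = decade, scenario = scenario,
    threshold = threshold
  )
}

#' Clip a potential distribution to occupied subregions
#'
#' The realized distribution keeps presence only within subregions containing
#' at least one occurrence record; subregions never reporting the species are
#' treated as unsuitable beyond climate (dispersal limits, habitat,
#' competition). Occurrence points falling on nodata cells are ignored with a
#' warning.
#'
#' @param potential A `binary_range` (current potential distribution).
#' @param mosaic A `region_mosaic`.
#' @param occurrences Tibble with a `cell` column (or `x`/`y` coordinates) of
#'   occurrence records; must be non-empty.
#' @return A `binary_range` of the realized distribution.
#' @export
realized_from_potential <- function(potential, mosaic, occurrences) {
  stopifnot(inherits(potential, "binary_range"), inherits(mosaic, "region_mosaic"))
  check_same_grid(potential$grid, mosaic$grid)
  if (nrow(occurrences) == 0) stop("`occurrences` must be non-empty", call. = FALSE)
  cells <- if ("cell" %in% names(occurrences)) {
    occurrences$cell
  } else {
    xy_to_cell(potential$grid, occurrences$x, occurrences$y)
  }
  labs <- as.vector(mosaic$labels)[cells]
  if (any(is.na(labs))) {
    warning(sum(is.na(labs)), " occurrence point(s) fall outside all regions",
      " (nodata); ignored")
    labs <- labs[!is.na(labs)]
  }
  occupied <- unique(labs)
  keep <- matrix(as.vector(mosaic$labels) %in% occupied,
    potential$grid$n_rows, potential$grid$n_cols
  )
  out <- potential
  out$presence <- ifelse(is.na(potential$presence), NA_real_,
    potential$presence * as.numeric(keep)
  )
  out$scenario <- "realized"
  out
}

# Euclidean centre-to-centre distance (km) from every cell to the nearest
# presence cell of `range`; Inf when the range is empty.
distance_to_presence <- function(range) {
  grid <- range$grid
  centers <- cell_centers(grid)
  pres <- which(!is.na(as.vector(range$presence)) & as.vector(range$presence) == 1)
  n <- n_cells(grid)
  if (length(pres) == 0) {
    return(rep(Inf, n))
  }
  px <- centers$x[pres]
  py <- centers$y[pres]
  out <- numeric(n)
  # chunked brute force keeps memory bounded on larger grids
  chunk <- max(1L, floor(4e6 / length(pres)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(centers$x[idx], px, "-")^2 + outer(centers$y[idx], py, "-")^2
    out[idx] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out
}

#' Build decade-wise dispersal masks
#'
#' For decade index `d = 1..n_decades`, the mask contains every cell whose
#' centre lies within `rate_km_per_year * 10 * d` km (Euclidean) of the
#' nearest presence cell of the current realized range. Masks are anchored on
#' the current range (not grown iteratively), so they are nested and always
#' contain the current range.
#'
#' @param current A `binary_range` (current realized distribution; a warning
#'   is emitted and empty masks returned when it has no presence cells).
#' @param rate_km_per_year Dispersal rate, km/yr; >= 0 (default 3).
#' @param n_decades Number of decade masks to build (default 10).
#' @return A `dispersal_mask_set`: list with `masks` (list of logical
#'   matrices, one per decade index), `radii_km`, `rate`, `base`.
#' @export
build_masks <- function(current, rate_km_per_year = 3, n_decades = 10) {
  stopifnot(inherits(current, "binary_range"), rate_km_per_year >= 0)
  n_pres <- sum(current$presence == 1, na.rm = TRUE)
  if (n_pres == 0) {
    warning("current range is empty; dispersal masks contain no cells")
  }
  dist <- distance_to_presence(current)
  radii <- rate_km_per_year * 10 * seq_len(n_decades)
  nodata <- is.na(as.vector(current$presence))
  masks <- lapply(radii, function(r) {
    m <- dist <= r & !nodata
    matrix(m, current$grid$n_rows, current$grid$n_cols)
  })
  structure(
    list(
      masks = masks, radii_km = radii, rate = rate_km_per_year,
      base = current, grid = current$grid
    ),
    class = "dispersal_mask_set"
  )
}

#' Apply a dispersal scenario to a future potential distribution
#'
#' * `"full"`: unlimited dispersal; the future potential range is unchanged.
#' * `"rate_limited"`: intersection with the decade's dispersal mask (the
#'   current range buffered by `rate * 10 * decade_index` km).
#' * `"none"`: intersection with the current realized distribution (or, with
#'   `none_level = "region"`, with the subregions the species currently
#'   occupies).
#'
#' @param future_potential A `binary_range` for one future decade.
#' @param scenario `"full"`, `"rate_limited"` or `"none"`.
#' @param current_realized Current realized `binary_range` (required for
#'   `"none"`, and for `"region"`-level clipping).
#' @param masks A `dispersal_mask_set` (required for `"rate_limited"`).
#' @param decade_index Decade index `d >= 1` into `masks` (required for
#'   `"rate_limited"`).
#' @param none_level `"cell"` (default: intersect with the realized cells) or
#'   `"region"` (intersect with occupied subregions; needs `mosaic`).
#' @param mosaic A `region_mosaic` (only for `none_level = "region"`).
#' @return A `binary_range` with the scenario label set.
#' @export
apply_scenario <- function(future_potential, scenario,
                           current_realized = NULL, masks = NULL,
                           decade_index = NULL,
                           none_level = c("cell", "region"), mosaic = NULL) {
  stopifnot(inherits(future_potential, "binary_range"))
  scenario <- match.arg(scenario, c("full", "rate_limited", "none"))
  none_level <- match.arg(none_level)
  out <- future_potential
  if (scenario == "full") {
    out$scenario <- "full"
    return(out)
  }
  if (scenario == "rate_limited") {
    if (is.null(masks) || is.null(decade_index)) {
      stop("rate-limited scenario requires `masks` and `decade_index`",
        call. = FALSE
      )
    }
    keep <- masks$masks[[decade_index]]
  } else {
    if (is.null(current_realized)) {
      stop("no-dispersal scenario requires `current_realized`", call. = FALSE)
    }
    if (none_level == "cell") {
      keep <- !is.na(current_realized$presence) & current_realized$presence == 1
    } else {
      if (is.null(mosaic)) {
        stop("`none_level = \"region\"` requires `mosaic`", call. = FALSE)
      }
      occ_cells <- which(!is.na(as.vector(current_realized$presence)) &
        as.vector(current_realized$presence) == 1)
      occupied <- unique(as.vector(mosaic$labels)[occ_cells])
      keep <- matrix(
        as.vector(mosaic$labels) %in% occupied,
        out$grid$n_rows, out$grid$n_cols
      )
    }
  }
  out$presence <- ifelse(is.na(future_potential$presence), NA_real_,
    future_potential$presence * as.numeric(keep)
  )
  out$scenario <- scenario
  out
}

#' Select the scenario output matching each species' dispersal category
#'
#' The assignment of species to dispersal categories is input metadata (from
#' movement ecology and habitat specificity), not computed; this helper just
#' picks, per species, the matching scenario output, giving the "realistic"
#' dispersal projection.
#'
#' @param meta Metadata tibble with `species_id` and `dispersal_category`.
#' @param outputs Named list of per-scenario outputs: elements `full`,
#'   `rate_limited`, `none`, each itself a list keyed by species id.
#' @return Named list keyed by species id with each species' realistic-
#'   scenario output.
#' @export
realistic_scenario <- function(meta, outputs) {
  stopifnot(all(c("species_id", "dispersal_category") %in% names(meta)))
  bad <- setdiff(unique(meta$dispersal_category),
    c("full", "rate_limited", "none"))
  if (length(bad) > 0) {
    stop("unknown dispersal category: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out <- purrr::map2(meta$species_id, meta$dispersal_category, function(sp, cat) {
    res <- outputs[[cat]][[sp]]
    if (is.null(res)) {
      stop("no `", cat, "` scenario output for species ", sp, call. = FALSE)
    }
    res
  })
  stats::setNames(out, meta$species_id)
}
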