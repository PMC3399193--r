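#' Landscape class statistics of a binary range
#'
#' Patch-level summary of a presence/absence raster in the style of classic
#' landscape class statistics: total area, patch count (connected components
#' under rook or queen connectivity), proportion of the non-nodata landscape,
#' mean patch area, and edge length (count of presence-to-absence or
#' presence-to-border cell edges, on the rook neighbourhood, times the cell
#' side).
#'
#' @param range A `binary_range`.
#' @param connectivity 4 (rook) or 8 (queen, default).
#' @return One-row tibble: `total_area_km2, n_patches, proportion_landscape,
#'   mean_patch_area_km2, edge_length_km`.
#' @export
class_stats <- function(range, connectivity = 8) {
  stopifnot(inherits(range, "binary_range"))
  if (!connectivity %in% c(4, 8)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  pres <- range$presence
  grid <- range$grid
  cell_area <- grid$cell_size_km^2
  is_pres <- !is.na(pres) & pres == 1
  n_pres <- sum(is_pres)
  n_land <- sum(!is.na(pres))
  if (n_pres == 0) {
    return(tibble::tibble(
      total_area_km2 = 0, n_patches = 0L, proportion_landscape = 0,
      mean_patch_area_km2 = 0, edge_length_km = 0
    ))
  }
  n_patches <- count_patches(is_pres, connectivity)

  # edge: rook-neighbour presence/absence (or grid border) interfaces
  nr <- grid$n_rows
  nc <- grid$n_cols
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- is_pres
  inner <- pad[2:(nr + 1), 2:(nc + 1)]
  nbr_open <- (!pad[1:nr, 2:(nc + 1)]) + (!pad[3:(nr + 2), 2:(nc + 1)]) +
    (!pad[2:(nr + 1), 1:nc]) + (!pad[2:(nr + 1), 3:(nc + 2)])
  edge_edges <- sum(nbr_open[inner])

  tibble::tibble(
    total_area_km2 = n_pres * cell_area,
    n_patches = n_patches,
    proportion_landscape = n_pres / n_land,
    mean_patch_area_km2 = n_pres * cell_area / n_patches,
    edge_length_km = edge_edges * grid$cell_size_km
  )
}

# connected components of a logical matrix via an adjacency graph
count_patches <- function(is_pres, connectivity) {
  idx <- which(is_pres, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) {
    return(0L)
  }
  nr <- nrow(is_pres)
  key <- (idx[, 2] - 1L) * nr + idx[, 1] # linear index of each presence cell
  pos <- integer(length(is_pres))
  pos[key] <- seq_len(n)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- list()
  for (o in offs) {
    r2 <- idx[, 1] + o[1]
    c2 <- idx[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(is_pres)
    ok[ok] <- is_pres[cbind(r2[ok], c2[ok])]
    if (any(ok)) {
      edges[[length(edges) + 1]] <- cbind(
        which(ok), pos[(c2[ok] - 1L) * nr + r2[ok]]
      )
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  igraph::components(g)$no
}

#' Proportional range change and its direction
#'
#' Ratio of future to current range area, with the direction classified on
#' the ratio rounded to two decimals: above 1.00 is `"Increase"`, below is
#' `"Decrease"`, exactly 1.00 is `"No change"`.
#'
#' @param area_future,area_current Range areas (same units);
#'   `area_current` must be > 0.
#' @return One-row tibble `proportion_of_current, direction`.
#' @export
proportional_change <- function(area_future, area_current) {
  if (!is.finite(area_current) || area_current <= 0) {
    stop("undefined ratio: `area_current` must be > 0", call. = FALSE)
  }
  ratio <- area_future / area_current
  r2 <- round(ratio, 2)
  tibble::tibble(
    proportion_of_current = ratio,
    direction = dplyr::case_when(
      r2 > 1 ~ "Increase",
      r2 < 1 ~ "Decrease",
      TRUE ~ "No change"
    )
  )
}

#' Assemblage-level summary of proportional range changes
#'
#' @param records Data frame with columns `proportion_of_current` and
#'   `direction` (one row per species), e.g. accumulated
#'   [proportional_change()] results.
#' @return One-row tibble with counts and percentages of
#'   increasing/decreasing/unchanged species, mean percent increase among
#'   increasers, mean percent decrease among decreasers, overall mean percent
#'   shift, the number of species changing by less than 10%, and the number
#'   increasing by at least 50%.
#' @export
assemblage_summary <- function(records) {
  stopifnot(nrow(records) >= 1)
  pct <- 100 * (records$proportion_of_current - 1)
  inc <- records$direction == "Increase"
  dec <- records$direction == "Decrease"
  tibble::tibble(
    n_species = nrow(records),
    n_increase = sum(inc),
    n_decrease = sum(dec),
    n_no_change = sum(records$direction == "No change"),
    pct_increase = 100 * mean(inc),
    pct_decrease = 100 * mean(dec),
    pct_no_change = 100 * mean(records$direction == "No change"),
    mean_pct_increase = if (any(inc)) mean(pct[inc]) else NA_real_,
    mean_pct_decrease = if (any(dec)) mean(-pct[dec]) else NA_real_,
    mean_pct_shift = mean(pct),
    n_small_change = sum(abs(pct) < 10),
    n_increase_50plus = sum(pct >= 50)
  )
}

#' Stack binary ranges into a species-richness grid
#'
#' Cell-wise count of species whose binary range includes the cell. All
#' species are stacked, including those whose models were screened out on
#' AUC, since assemblage-level richness is robust to individual weak models.
#'
#' @param ranges List of `binary_range` objects on one shared grid.
#' @param decade,scenario Labels stored on the result.
#' @return A `richness_grid`: list with `counts` (integer matrix, `NA` at
#'   nodata), `grid`, `species_ids`, `decade`, `scenario`.
#' @export
richness_stack <- function(ranges, decade = NA_real_, scenario = NA_character_) {
  stopifnot(length(ranges) >= 1)
  grid <- ranges[[1]]$grid
  for (r in ranges) {
    if (!inherits(r, "binary_range")) {
      stop("`ranges` must be a list of binary_range objects", call. = FALSE)
    }
    check_same_grid(r$grid, grid)
  }
  counts <- Reduce(`+`, lapply(ranges, function(r) {
    ifelse(is.na(r$presence), 0, r$presence)
  }))
  any_data <- Reduce(`|`, lapply(ranges, function(r) !is.na(r$presence)))
  counts[!any_data] <- NA
  structure(
    list(
      counts = counts, grid = grid,
      species_ids = vapply(ranges, function(r) {
        ifelse(is.na(r$species_id), "", r$species_id)
      }, character(1)),
      decade = decade, scenario = scenario
    ),
    class = "richness_grid"
  )
}

#' Cell-wise change in species richness between two richness grids
#'
#' @param r_start,r_end `richness_grid`s on the same grid with the same
#'   species list.
#' @return Signed integer matrix `r_end$counts - r_start$counts`.
#' @export
richness_change <- function(r_start, r_end) {
  stopifnot(inherits(r_start, "richness_grid"), inherits(r_end, "richness_grid"))
  check_same_grid(r_start$grid, r_end$grid)
  if (!setequal(r_start$species_ids, r_end$species_ids)) {
    stop("richness grids must cover the same species list", call. = FALSE)
  }
  r_end$counts - r_start$counts
}

#' Compare proportional range change across species groups
#'
#' One-way fixed-effects ANOVA of proportional change on a grouping factor
#' (movement class or biogeographic group), plus per-group quartiles for
#' boxplot-style display. Groups with fewer than 2 records are dropped with a
#' warning.
#'
#' @param records Data frame with `proportion_of_current` and the grouping
#'   column.
#' @param grouping Name of the grouping column (e.g. `"movement_class"` or
#'   `"biogeo_group"`).
#' @return List with `test` (one-row tibble `statistic, df1, df2, p_value`)
#'   and `groups` (per-group tibble `n, q1, median, q3`).
#' @export
group_comparison <- function(records, grouping) {
  stopifnot(grouping %in% names(records))
  df <- tibble::tibble(
    value = records$proportion_of_current,
    group = as.character(records[[grouping]])
  )
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning(
      "dropping group(s) with fewer than 2 records: ",
      paste(small, collapse = ", ")
    )
    df <- df[!df$group %in% small, ]
  }
  if (length(unique(df$group)) < 2) {
    stop("need at least 2 groups with >= 2 records each", call. = FALSE)
  }
  k <- length(unique(df$group))
  if (stats::var(df$value) == 0) {
    # degenerate no-variance case: define F = 0, p = 1
    test <- tibble::tibble(
      statistic = 0, df1 = k - 1, df2 = nrow(df) - k, p_value = 1
    )
  } else {
    fit <- stats::aov(value ~ group, data = df)
    tab <- summary(fit)[[1]] # row 1: group term, row 2: residuals
    test <- tibble::tibble(
      statistic = tab[1, "F value"],
      df1 = tab[1, "Df"],
      df2 = tab[2, "Df"],
      p_value = tab[1, "Pr(>F)"]
    )
  }
  groups <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = stats::quantile(.data$value, 0.25),
      median = stats::median(.data$value),
      q3 = stats::quantile(.data$value, 0.75),
      .groups = "drop"
    )
  list(test = test, groups = groups)
}
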