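#' Project a fitted model onto every future climate realization
#'
#' @param model A `maxent_model`.
#' @param future_stacks Tibble with columns `gcm_id`, `realization`, `decade`
#'   and `stack` (list-column of `climate_stack`), e.g. future series from
#'   [make_future_series()] passed through [derive_bioclim()]. Every
#'   (gcm, realization) pair must be present for every decade.
#' @return A tibble `gcm_id, realization, decade, map` (list-column of
#'   `suitability_map`), one row per key.
#' @export
project_all <- function(model, future_stacks) {
  stopifnot(inherits(model, "maxent_model"))
  req <- c("gcm_id", "realization", "decade", "stack")
  if (!all(req %in% names(future_stacks))) {
    stop("`future_stacks` must have columns ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  full <- tidyr::expand_grid(
    dplyr::distinct(future_stacks, .data$gcm_id, .data$realization),
    decade = unique(future_stacks$decade)
  )
  gaps <- dplyr::anti_join(full, future_stacks,
    by = c("gcm_id", "realization", "decade")
  )
  if (nrow(gaps) > 0) {
    stop(
      "incomplete projection set; missing (gcm, realization, decade) keys: ",
      paste(sprintf(
        "(%s, %d, %g)", gaps$gcm_id, gaps$realization, gaps$decade
      ), collapse = "; "),
      call. = FALSE
    )
  }
  dplyr::mutate(
    future_stacks,
    map = purrr::pmap(
      list(.data$stack, .data$gcm_id, .data$realization, .data$decade),
      function(stack, g, r, d) {
        predict_logistic(model, stack, provenance = sprintf("%s/r%d/%g", g, r, d))
      }
    ),
    stack = NULL
  )
}

map_values <- function(m) if (inherits(m, "suitability_map")) m$values else m

#' Realization-weighted ensemble mean for one decade
#'
#' Cell-wise mean over realizations within each circulation model, then the
#' unweighted mean across the per-model means. This weights each realization
#' by `1 / (n_gcms * n_realizations(g))`, so models with many realizations do
#' not dominate the ensemble.
#'
#' @param projections Tibble from [project_all()] (columns `gcm_id`,
#'   `realization`, `decade`, `map`).
#' @param decade Decade label to summarise.
#' @return A `suitability_map` of the two-stage mean.
#' @export
ensemble_mean <- function(projections, decade) {
  rows <- projections[projections$decade == decade, ]
  if (nrow(rows) == 0) stop("no projections for decade ", decade, call. = FALSE)
  per_gcm <- lapply(split(rows$map, rows$gcm_id), function(maps) {
    Reduce(`+`, lapply(maps, map_values)) / length(maps)
  })
  mean_vals <- Reduce(`+`, per_gcm) / length(per_gcm)
  out <- rows$map[[1]]
  out$values <- mean_vals
  out$provenance <- sprintf("ensemble-mean/%g", decade)
  out
}

#' Ensemble extremes for one decade
#'
#' Cell-wise minimum and maximum over all realizations (unweighted; min and
#' max are invariant to realization weighting).
#'
#' @inheritParams ensemble_mean
#' @return List of two `suitability_map`s, `minimum` and `maximum`.
#' @export
ensemble_extremes <- function(projections, decade) {
  rows <- projections[projections$decade == decade, ]
  if (nrow(rows) == 0) stop("no projections for decade ", decade, call. = FALSE)
  vals <- lapply(rows$map, map_values)
  lo <- Reduce(pmin, vals)
  hi <- Reduce(pmax, vals)
  mn <- rows$map[[1]]
  mx <- rows$map[[1]]
  mn$values <- lo
  mn$provenance <- sprintf("ensemble-min/%g", decade)
  mx$values <- hi
  mx$provenance <- sprintf("ensemble-max/%g", decade)
  list(minimum = mn, maximum = mx)
}

#' Climate-change map for one bioclim variable
#'
#' Summarises an ensemble of future climate stacks by the two-stage
#' (within-GCM then across-GCM) mean of the chosen variable and contrasts it
#' with the baseline: absolute difference (`future - baseline`) for the
#' temperature variables (`mat`, `ts`, `twp`), proportional change
#' (`future / baseline`, nodata where the baseline is 0) for the rainfall
#' variables (`ap`, `ps`, `pdp`).
#'
#' @param variable One of the six bioclim variable names.
#' @param baseline_stack Baseline `climate_stack`.
#' @param future_stacks Tibble `gcm_id, realization, decade, stack` restricted
#'   to (or filtered by) `decade`.
#' @param decade Decade to summarise (default: the single decade present).
#' @return A list with `values` (change matrix), `grid`, `variable`, `kind`
#'   (`"absolute"` or `"proportional"`).
#' @export
climate_change_map <- function(variable, baseline_stack, future_stacks,
                               decade = NULL) {
  if (!variable %in% bioclim_vars()) {
    stop("unknown bioclim variable `", variable, "`", call. = FALSE)
  }
  rows <- future_stacks
  if (!is.null(decade)) rows <- rows[rows$decade == decade, ]
  if (nrow(rows) == 0) stop("no future stacks to summarise", call. = FALSE)
  per_gcm <- lapply(split(rows$stack, rows$gcm_id), function(stacks) {
    Reduce(`+`, lapply(stacks, `[[`, variable)) / length(stacks)
  })
  fut <- Reduce(`+`, per_gcm) / length(per_gcm)
  base <- baseline_stack[[variable]]
  if (variable %in% c("mat", "ts", "twp")) {
    vals <- fut - base
    kind <- "absolute"
  } else {
    vals <- ifelse(!is.na(base) & base == 0, NA_real_, fut / base)
    kind <- "proportional"
  }
  list(
    values = vals, grid = baseline_stack$grid,
    variable = variable, kind = kind
  )
}
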