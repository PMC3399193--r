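#' Build a pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one (YAML-serialisable)
#' list: simulated landscape and climate, circulation-model ensemble, virtual
#' species, model fitting, and dispersal settings. Defaults reproduce the
#' bundled synthetic scenario: an 80 x 60 grid of 5-km cells, four circulation
#' models with (1, 2, 3, 2) realizations, ten decades 1990-2080 and twelve
#' virtual species spanning all dispersal categories.
#'
#' @param seed Master seed; every random draw in the run derives from it.
#' @param grid,climate,gcms,species,model,dispersal Named lists overriding
#'   individual defaults (partial lists are merged over the defaults).
#' @param decades Decade year labels (strictly increasing).
#' @param n_regions Number of subregions in the synthetic mosaic.
#' @param ts_convention Temperature-seasonality convention, see
#'   [derive_bioclim()].
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 20,
                       grid = list(),
                       climate = list(),
                       gcms = NULL,
                       decades = seq(1990, 2080, by = 10),
                       n_regions = 12,
                       species = list(),
                       model = list(),
                       dispersal = list(),
                       ts_convention = "percent_of_mean") {
  merge_over <- function(defaults, given) {
    utils::modifyList(defaults, as.list(given))
  }
  cfg <- list(
    seed = as.integer(seed),
    grid = merge_over(
      list(n_rows = 80, n_cols = 60, cell_size_km = 5),
      grid
    ),
    climate = merge_over(
      list(
        base_temp = 25, south_north_temp_gradient = -10,
        seasonal_amplitude = 4, wet_season_months = c(12, 1, 2, 3),
        mean_annual_precip = 1000, noise_sd = 0.2,
        precip_gradient_per_1000km = 1.5, precip_noise_frac = 0.03,
        baseline_year = 1990
      ),
      climate
    ),
    gcms = if (is.null(gcms)) {
      list(
        list(gcm_id = "gcm-a", n_realizations = 1, temp_trend_per_decade = 0.12,
          precip_factor_per_decade = 0.990),
        list(gcm_id = "gcm-b", n_realizations = 2, temp_trend_per_decade = 0.20,
          precip_factor_per_decade = 1.005),
        list(gcm_id = "gcm-c", n_realizations = 3, temp_trend_per_decade = 0.25,
          precip_factor_per_decade = 0.980),
        list(gcm_id = "gcm-d", n_realizations = 2, temp_trend_per_decade = 0.32,
          precip_factor_per_decade = 1.010)
      )
    } else {
      gcms
    },
    decades = as.numeric(decades),
    n_regions = as.integer(n_regions),
    species = merge_over(
      list(
        n_species = 12,
        niche_width_factor = 0.35,
        seasonal_width_factor = 4,
        prevalence_threshold = 0.10,
        n_occurrence_points = 400,
        n_presence_cells = 200,
        y_band_fraction = c(0.05, 0.70),
        n_full = 8, n_rate_limited = 3, n_none = 1
      ),
      species
    ),
    model = merge_over(
      list(
        n_background = 10000, beta_multiplier = 1, beta_scale = "presence",
        auc_threshold = 0.7
      ),
      model
    ),
    dispersal = merge_over(
      list(rate_km_per_year = 3, none_level = "cell"),
      dispersal
    ),
    ts_convention = ts_convention
  )
  if (any(diff(cfg$decades) <= 0)) {
    stop("`decades` must be strictly increasing", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Configurations round-trip unchanged through serialisation.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` invisibly; [read_run_config()] returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, list(
    seed = raw$seed, grid = raw$grid, climate = raw$climate, gcms = raw$gcms,
    decades = raw$decades, n_regions = raw$n_regions, species = raw$species,
    model = raw$model, dispersal = raw$dispersal,
    ts_convention = raw$ts_convention
  ))
}

# hash of the config fields a stage (and its upstream stages) depends on
stage_fields <- list(
  simulate = c("seed", "grid", "climate", "gcms", "decades", "n_regions",
    "species"),
  bioclim = "ts_convention",
  fit = "model",
  project = character(0),
  dispersal = "dispersal",
  summarize = character(0)
)

stage_hash <- function(config, stage) {
  stages <- names(stage_fields)
  upto <- stages[seq_len(match(stage, stages))]
  fields <- unique(unlist(stage_fields[upto]))
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config)[sort(fields)], tmp, precision = 15)
  unname(tools::md5sum(tmp))
}

cache_get <- function(cache_dir, stage, hash) {
  f <- file.path(cache_dir, paste0(stage, "-", hash, ".rds"))
  if (file.exists(f)) readRDS(f) else NULL
}

cache_put <- function(cache_dir, stage, hash, value) {
  saveRDS(value, file.path(cache_dir, paste0(stage, "-", hash, ".rds")))
  value
}

# ---- stages ----------------------------------------------------------------

simulate_stage <- function(config) {
  grid <- grid_spec(
    config$grid$n_rows, config$grid$n_cols, config$grid$cell_size_km
  )
  cl <- config$climate
  baseline <- make_monthly_climate(
    grid,
    south_north_temp_gradient = cl$south_north_temp_gradient,
    seasonal_amplitude = cl$seasonal_amplitude,
    wet_season_months = cl$wet_season_months,
    mean_annual_precip = cl$mean_annual_precip,
    noise_sd = cl$noise_sd,
    seed = derive_seed(config$seed, "baseline"),
    base_temp = cl$base_temp,
    precip_gradient_per_1000km = cl$precip_gradient_per_1000km,
    precip_noise_frac = cl$precip_noise_frac,
    year_label = cl$baseline_year
  )
  gcms <- lapply(config$gcms, function(x) do.call(gcm_spec, x))
  future <- make_future_series(
    baseline, gcms, config$decades,
    seed = derive_seed(config$seed, "future")
  )
  mosaic <- make_region_mosaic(
    grid, config$n_regions,
    seed = derive_seed(config$seed, "mosaic")
  )

  # virtual species: niche centres stratified along the meridional gradient
  stack <- derive_bioclim(baseline, ts_convention = config$ts_convention)
  env <- stack_env_matrix(stack)
  sdv <- apply(env, 2, stats::sd)
  widths <- config$species$niche_width_factor * sdv
  seas <- intersect(c("ts", "ps"), names(widths))
  widths[seas] <- config$species$seasonal_width_factor * sdv[seas]
  widths <- pmax(widths, 1e-9)
  centers <- cell_centers(grid)
  extent_y <- grid$n_rows * grid$cell_size_km
  nsp <- config$species$n_species
  y_targets <- seq(
    config$species$y_band_fraction[1] * extent_y,
    config$species$y_band_fraction[2] * extent_y,
    length.out = nsp
  )
  cats <- dispersal_category_sequence(
    nsp, config$species$n_full, config$species$n_rate_limited,
    config$species$n_none
  )
  movements <- rep(c("M", "N", "P", "S", "SN"), length.out = nsp)
  biogeos <- rep(c("arid", "CYP", "temperate", "tropical", "ubiquitous"),
    length.out = nsp
  )
  # mild longitudinal survey-effort bias, emulating atlas accessibility bias
  bias <- matrix(
    0.5 + (centers$x - min(centers$x)) /
      max(max(centers$x) - min(centers$x), 1),
    grid$n_rows, grid$n_cols
  )
  species <- list()
  occurrences <- list()
  for (i in seq_len(nsp)) {
    sp_id <- sprintf("sp%02d", i)
    col_target <- with_seed(
      derive_seed(config$seed, "niche-col", sp_id),
      stats::runif(1, 0.2, 0.8) * grid$n_cols * grid$cell_size_km
    )
    cell0 <- which.min((centers$y - y_targets[i])^2 + (centers$x - col_target)^2)
    meta <- species_meta(
      sp_id, movements[i], biogeos[i], cats[i],
      dispersal_rate_km_per_year =
        if (cats[i] == "rate_limited") config$dispersal$rate_km_per_year else NULL
    )
    vs <- make_virtual_species(
      env[cell0, ], widths, config$species$prevalence_threshold, meta, stack
    )
    species[[sp_id]] <- vs
    occurrences[[sp_id]] <- sample_occurrences(
      vs$suitability, grid, config$species$n_occurrence_points,
      bias = bias,
      seed = derive_seed(config$seed, "occ", sp_id), species_id = sp_id
    )
  }
  list(
    grid = grid, baseline_series = baseline, future_series = future,
    mosaic = mosaic, species = species,
    occurrences = dplyr::bind_rows(occurrences),
    meta = dplyr::bind_rows(lapply(species, function(s) s$meta))
  )
}

dispersal_category_sequence <- function(n, n_full, n_rate, n_none) {
  if (n_full + n_rate + n_none != n) {
    stop("dispersal category counts must sum to `n_species`", call. = FALSE)
  }
  # spread the rarer categories across the climatic gradient
  out <- rep("full", n)
  special <- c(rep("rate_limited", n_rate), rep("none", n_none))
  if (length(special) > 0) {
    spots <- unique(round(seq(2, max(n - 1, 2), length.out = length(special))))
    if (length(spots) < length(special)) {
      spots <- seq_len(length(special))
    }
    out[spots] <- special
  }
  out
}

bioclim_stage <- function(config, sim) {
  baseline_stack <- derive_bioclim(
    sim$baseline_series, ts_convention = config$ts_convention
  )
  future_stacks <- dplyr::mutate(
    sim$future_series,
    stack = purrr::map(.data$series, derive_bioclim,
      ts_convention = config$ts_convention
    ),
    series = NULL
  )
  list(baseline_stack = baseline_stack, future_stacks = future_stacks)
}

fit_stage <- function(config, sim, bc) {
  background <- build_background(
    bc$baseline_stack, config$model$n_background,
    seed = derive_seed(config$seed, "background")
  )
  models <- list()
  for (sp_id in names(sim$species)) {
    occ_cells <- unique(sim$occurrences$cell[sim$occurrences$species_id == sp_id])
    n_keep <- min(config$species$n_presence_cells, length(occ_cells))
    presence <- occ_cells[seq_len(n_keep)]
    m <- fit_maxent(
      bc$baseline_stack, presence, background,
      beta_multiplier = config$model$beta_multiplier,
      beta_scale = config$model$beta_scale,
      species_id = sp_id
    )
    map <- predict_logistic(m, bc$baseline_stack)
    m$auc <- sdm_auc(map, m$presence_cells, background)
    m$threshold_logistic <- entropy_threshold(m, bc$baseline_stack)
    models[[sp_id]] <- m
  }
  summaries <- dplyr::bind_rows(lapply(models, glance))
  screened <- screen_models(summaries, config$model$auc_threshold)
  list(
    background = background, models = models, model_summaries = summaries,
    kept = screened$kept$species_id, excluded = screened$excluded$species_id
  )
}

project_stage <- function(config, bc, fit) {
  ens <- list()
  for (sp_id in names(fit$models)) {
    proj <- project_all(fit$models[[sp_id]], bc$future_stacks)
    rows <- lapply(config$decades, function(d) {
      ext <- ensemble_extremes(proj, d)
      tibble::tibble(
        species_id = sp_id, decade = d,
        mean = list(ensemble_mean(proj, d)),
        minimum = list(ext$minimum), maximum = list(ext$maximum)
      )
    })
    ens[[sp_id]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(ens)
}

dispersal_stage <- function(config, sim, bc, fit, ensembles) {
  scen_names <- c("full", "rate_limited", "none")
  ranges <- list()
  current <- list()
  masksets <- list()
  for (sp_id in names(fit$models)) {
    model <- fit$models[[sp_id]]
    thr <- model$threshold_logistic
    base_map <- predict_logistic(model, bc$baseline_stack)
    potential <- binarize(base_map, thr,
      decade = config$climate$baseline_year, scenario = "potential"
    )
    occ <- sim$occurrences[sim$occurrences$species_id == sp_id, ]
    realized <- realized_from_potential(potential, sim$mosaic, occ)
    current[[sp_id]] <- realized
    masks <- build_masks(
      realized, config$dispersal$rate_km_per_year, length(config$decades)
    )
    masksets[[sp_id]] <- masks
    per_decade <- list()
    for (d_idx in seq_along(config$decades)) {
      d <- config$decades[d_idx]
      mean_map <- ensembles$mean[[
        which(ensembles$species_id == sp_id & ensembles$decade == d)
      ]]
      fut_pot <- binarize(mean_map, thr, decade = d, scenario = "potential")
      outs <- list(
        full = apply_scenario(fut_pot, "full"),
        rate_limited = apply_scenario(fut_pot, "rate_limited",
          masks = masks, decade_index = d_idx
        ),
        none = apply_scenario(fut_pot, "none",
          current_realized = realized,
          none_level = config$dispersal$none_level, mosaic = sim$mosaic
        )
      )
      per_decade[[as.character(d)]] <- outs
    }
    ranges[[sp_id]] <- per_decade
  }
  # realistic scenario: pick each species' category-matching output per decade
  for (d in as.character(config$decades)) {
    by_scen <- lapply(scen_names, function(sc) {
      lapply(ranges, function(pd) pd[[d]][[sc]])
    })
    names(by_scen) <- scen_names
    real <- realistic_scenario(sim$meta, by_scen)
    for (sp_id in names(real)) {
      r <- real[[sp_id]]
      r$scenario <- "realistic"
      ranges[[sp_id]][[d]]$realistic <- r
    }
  }
  list(current = current, masks = masksets, ranges = ranges)
}

summarize_stage <- function(config, sim, fit, disp) {
  scenarios <- c("full", "rate_limited", "none", "realistic")
  decades <- config$decades
  last <- as.character(max(decades))
  cell_area <- config$grid$cell_size_km^2
  area_of <- function(r) sum(r$presence == 1, na.rm = TRUE) * cell_area

  stats_rows <- list()
  for (sp_id in names(disp$ranges)) {
    for (d in as.character(decades)) {
      for (sc in scenarios) {
        r <- disp$ranges[[sp_id]][[d]][[sc]]
        cs <- class_stats(r)
        stats_rows[[length(stats_rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(
            species_id = sp_id, decade = as.numeric(d), scenario = sc
          ),
          cs
        )
      }
    }
  }
  range_stats <- dplyr::bind_rows(stats_rows)

  kept <- fit$kept
  records <- list()
  for (sp_id in names(disp$ranges)) {
    if (!sp_id %in% kept) next
    a0 <- area_of(disp$current[[sp_id]])
    if (a0 <= 0) {
      warning("species ", sp_id, " has an empty current realized range; ",
        "excluded from change records")
      next
    }
    for (sc in scenarios) {
      a1 <- area_of(disp$ranges[[sp_id]][[last]][[sc]])
      pc <- proportional_change(a1, a0)
      records[[length(records) + 1]] <- dplyr::bind_cols(
        tibble::tibble(
          species_id = sp_id, scenario = sc,
          area_1990_km2 = a0, area_2080_km2 = a1
        ),
        pc
      )
    }
  }
  change_records <- dplyr::bind_rows(records)
  change_records <- dplyr::left_join(change_records, sim$meta, by = "species_id")

  assemblage <- dplyr::bind_rows(lapply(scenarios, function(sc) {
    recs <- change_records[change_records$scenario == sc, ]
    dplyr::bind_cols(tibble::tibble(scenario = sc), assemblage_summary(recs))
  }))

  groupings <- c("movement_class", "biogeo_group")
  comps <- list()
  for (gp in groupings) {
    recs <- change_records[change_records$scenario == "realistic", ]
    res <- tryCatch(
      suppressWarnings(group_comparison(recs, gp)),
      error = function(e) NULL
    )
    if (!is.null(res)) {
      comps[[gp]] <- dplyr::bind_cols(
        tibble::tibble(grouping = gp), res$test
      )
    }
  }
  group_comparisons <- dplyr::bind_rows(comps)

  richness <- list()
  rich_change <- list()
  for (sc in scenarios) {
    r1990 <- richness_stack(
      unname(disp$current),
      decade = config$climate$baseline_year, scenario = sc
    )
    r2080 <- richness_stack(
      lapply(disp$ranges, function(pd) pd[[last]][[sc]]),
      decade = as.numeric(last), scenario = sc
    )
    richness[[sc]] <- list(start = r1990, end = r2080)
    rich_change[[sc]] <- richness_change(r1990, r2080)
  }

  list(
    range_stats = range_stats,
    change_records = change_records,
    assemblage = assemblage,
    group_comparisons = group_comparisons,
    richness = richness,
    richness_change = rich_change
  )
}

# ---- orchestrator ----------------------------------------------------------

#' Run the full range-projection pipeline
#'
#' Executes simulate -> bioclim -> fit -> project -> dispersal -> summarize
#' from one configuration. Stage results are cached in `out_dir/cache` keyed
#' by a hash of the configuration fields the stage depends on, so re-running
#' with an unchanged configuration recomputes nothing; the same seed always
#' reproduces bit-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed). Summary tables are
#'   written as CSV, richness grids and change maps as raster TSV, fitted
#'   models as JSON.
#' @param force Recompute all stages even when cached results exist.
#' @param quiet Suppress per-stage progress messages.
#' @param upto Last stage to execute (one of `"simulate"`, `"bioclim"`,
#'   `"fit"`, `"project"`, `"dispersal"`, `"summarize"`); later stages are
#'   skipped and their artifacts omitted from the manifest.
#' @return The run manifest: a tibble of produced artifacts (`file`, `stage`,
#'   `species_id`, `decade`, `scenario`), with the full stage results in
#'   `attr(, "results")` and the names of recomputed stages in
#'   `attr(, "recomputed")`.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE, quiet = FALSE,
                         upto = "summarize") {
  stopifnot(inherits(config, "run_config"))
  upto <- match.arg(upto, names(stage_fields))
  wanted <- names(stage_fields)[
    seq_len(match(upto, names(stage_fields)))
  ]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  recomputed <- character(0)

  run_stage <- function(stage, fun) {
    h <- stage_hash(config, stage)
    cached <- if (force) NULL else cache_get(cache_dir, stage, h)
    if (!is.null(cached)) {
      if (!quiet) message("[", stage, "] cached")
      return(cached)
    }
    if (!quiet) message("[", stage, "] computing ...")
    t0 <- Sys.time()
    value <- fun()
    if (!quiet) {
      message(sprintf(
        "[%s] done in %.1f s", stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs"))
      ))
    }
    recomputed <<- c(recomputed, stage)
    cache_put(cache_dir, stage, h, value)
  }

  bc <- fit <- ens <- disp <- summ <- NULL
  sim <- run_stage("simulate", function() simulate_stage(config))
  if ("bioclim" %in% wanted) {
    bc <- run_stage("bioclim", function() bioclim_stage(config, sim))
  }
  if ("fit" %in% wanted) {
    fit <- run_stage("fit", function() fit_stage(config, sim, bc))
  }
  if ("project" %in% wanted) {
    ens <- run_stage("project", function() project_stage(config, bc, fit))
  }
  if ("dispersal" %in% wanted) {
    disp <- run_stage("dispersal", function() {
      dispersal_stage(config, sim, bc, fit, ens)
    })
  }
  if ("summarize" %in% wanted) {
    summ <- run_stage("summarize", function() {
      summarize_stage(config, sim, fit, disp)
    })
  }

  # ---- write artifacts -----------------------------------------------------
  manifest <- list()
  add <- function(file, stage, species_id = NA_character_, decade = NA_real_,
                  scenario = NA_character_) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      file = file, stage = stage, species_id = species_id,
      decade = decade, scenario = scenario
    )
  }
  write_csv_stable <- function(df, file) {
    utils::write.csv(as.data.frame(df), file, row.names = FALSE)
  }

  f <- file.path(out_dir, "species_meta.csv")
  write_csv_stable(sim$meta, f)
  add(f, "simulate")
  f <- file.path(out_dir, "occurrences.csv")
  write_csv_stable(
    sim$occurrences[, c("species_id", "x", "y")], f
  )
  add(f, "simulate")

  ras_dir <- file.path(out_dir, "rasters")
  dir.create(ras_dir, showWarnings = FALSE)
  if (!is.null(fit)) {
    model_dir <- file.path(out_dir, "models")
    dir.create(model_dir, showWarnings = FALSE)
    for (sp_id in names(fit$models)) {
      f <- file.path(model_dir, paste0(sp_id, ".json"))
      write_maxent_json(fit$models[[sp_id]], f)
      add(f, "fit", species_id = sp_id)
    }
    f <- file.path(out_dir, "model_summaries.csv")
    write_csv_stable(fit$model_summaries, f)
    add(f, "fit")
  }
  if (!is.null(ens)) {
    for (i in seq_len(nrow(ens))) {
      f <- file.path(ras_dir, sprintf(
        "%s_%g_mean.tsv", ens$species_id[i], ens$decade[i]
      ))
      write_raster_tsv(ens$mean[[i]]$values, sim$grid, f)
      add(f, "project", species_id = ens$species_id[i], decade = ens$decade[i])
    }
  }
  if (!is.null(disp)) {
    for (sp_id in names(disp$ranges)) {
      for (d in names(disp$ranges[[sp_id]])) {
        for (sc in names(disp$ranges[[sp_id]][[d]])) {
          r <- disp$ranges[[sp_id]][[d]][[sc]]
          f <- file.path(ras_dir, sprintf("%s_%s_%s.tsv", sp_id, d, sc))
          write_raster_tsv(r$presence, sim$grid, f)
          add(f, "dispersal", species_id = sp_id, decade = as.numeric(d),
            scenario = sc)
        }
      }
    }
  }
  if (!is.null(summ)) {
    f <- file.path(out_dir, "range_stats.csv")
    write_csv_stable(summ$range_stats, f)
    add(f, "summarize")
    f <- file.path(out_dir, "change_records.csv")
    write_csv_stable(summ$change_records, f)
    add(f, "summarize")
    f <- file.path(out_dir, "assemblage_summary.csv")
    write_csv_stable(summ$assemblage, f)
    add(f, "summarize")
    f <- file.path(out_dir, "group_comparisons.csv")
    write_csv_stable(summ$group_comparisons, f)
    add(f, "summarize")
    for (sc in names(summ$richness_change)) {
      f <- file.path(ras_dir, sprintf("richness_change_%s.tsv", sc))
      write_raster_tsv(summ$richness_change[[sc]], sim$grid, f)
      add(f, "summarize", scenario = sc)
    }
  }

  out <- dplyr::bind_rows(manifest)
  attr(out, "results") <- list(
    sim = sim, bioclim = bc, fit = fit, ensembles = ens, dispersal = disp,
    summaries = summ
  )
  attr(out, "recomputed") <- recomputed
  out
}
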