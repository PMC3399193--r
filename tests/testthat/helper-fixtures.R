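# Shared fixtures built in code. The full synthetic scenario (12 virtual
# species, 4 GCMs, 10 decades) is expensive, so it is computed once per test
# session and memoised.

.fixture_env <- new.env(parent = emptyenv())

# run code under a local seed without disturbing the session RNG
with_seed_test <- function(seed, code) withr::with_seed(seed, code)

fixture_results <- function() {
  if (is.null(.fixture_env$res)) {
    cfg <- run_config(seed = 20)
    out <- file.path(tempdir(), "nichecast-fixture")
    man <- suppressMessages(run_pipeline(cfg, out, quiet = TRUE))
    .fixture_env$cfg <- cfg
    .fixture_env$man <- man
    .fixture_env$res <- attr(man, "results")
  }
  .fixture_env$res
}

fixture_config <- function() {
  fixture_results()
  .fixture_env$cfg
}

fixture_manifest <- function() {
  fixture_results()
  .fixture_env$man
}

# a small, quick pipeline configuration for orchestration tests
small_config <- function(seed = 7) {
  run_config(
    seed = seed,
    grid = list(n_rows = 24, n_cols = 20, cell_size_km = 5),
    gcms = list(
      list(gcm_id = "g1", n_realizations = 1, temp_trend_per_decade = 0.2,
        precip_factor_per_decade = 0.99),
      list(gcm_id = "g2", n_realizations = 2, temp_trend_per_decade = 0.3,
        precip_factor_per_decade = 1.01)
    ),
    decades = seq(1990, 2020, by = 10),
    n_regions = 4,
    species = list(
      n_species = 3, n_full = 2, n_rate_limited = 1, n_none = 0,
      n_occurrence_points = 150, n_presence_cells = 80
    )
  )
}

# build a monthly_climate object directly from per-month constants or matrices
manual_series <- function(temp_months, precip_months, grid = grid_spec(3, 3, 5),
                          year_label = 1990) {
  expand1 <- function(v, m) {
    if (is.matrix(v)) v else matrix(v, grid$n_rows, grid$n_cols)
  }
  tarr <- array(NA_real_, c(grid$n_rows, grid$n_cols, 12))
  parr <- array(NA_real_, c(grid$n_rows, grid$n_cols, 12))
  for (m in 1:12) {
    tarr[, , m] <- expand1(temp_months[[m]])
    parr[, , m] <- expand1(precip_months[[m]])
  }
  structure(
    list(temperature = tarr, precipitation = parr, grid = grid,
      year_label = year_label),
    class = "monthly_climate"
  )
}

# climate stack with specified layer values (constants or matrices)
manual_stack <- function(grid = grid_spec(3, 3, 5), mat = 25, ts = 10,
                         twp = 30, ap = 1000, ps = 100, pdp = 20) {
  as_m <- function(v) if (is.matrix(v)) v else matrix(v, grid$n_rows, grid$n_cols)
  structure(
    list(
      mat = as_m(mat), ts = as_m(ts), twp = as_m(twp), ap = as_m(ap),
      ps = as_m(ps), pdp = as_m(pdp), grid = grid
    ),
    class = "climate_stack"
  )
}

# binary_range straight from a 0/1 matrix
manual_range <- function(m, grid = NULL, species_id = "spX") {
  if (is.null(grid)) grid <- grid_spec(nrow(m), ncol(m), 5)
  nichecast:::new_binary_range(m, grid, species_id = species_id)
}

# independent flood-fill patch labelling oracle (stack-based DFS)
flood_fill_patches <- function(is_pres, connectivity) {
  nr <- nrow(is_pres)
  nc <- ncol(is_pres)
  seen <- matrix(FALSE, nr, nc)
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8) {
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  n_patches <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!is_pres[r, cc] || seen[r, cc]) next
      n_patches <- n_patches + 1L
      stack <- list(c(r, cc))
      seen[r, cc] <- TRUE
      while (length(stack) > 0) {
        cur <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(offs))) {
          r2 <- cur[1] + offs[k, 1]
          c2 <- cur[2] + offs[k, 2]
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            is_pres[r2, c2] && !seen[r2, c2]) {
            seen[r2, c2] <- TRUE
            stack[[length(stack) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  n_patches
}
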