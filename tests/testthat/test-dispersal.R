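suit_map <- function(values, grid, sp = "spX") {
  structure(
    list(values = values, grid = grid, species_id = sp,
      provenance = "test"),
    class = "suitability_map"
  )
}

test_that("binarisation uses >= threshold and preserves nodata", {
  g <- grid_spec(1, 4, 5)
  m <- suit_map(matrix(c(0.49, 0.5, 0.51, NA), 1, 4), g)
  br <- binarize(m, 0.5)
  expect_equal(as.vector(br$presence), c(0, 1, 1, NA))

  lo <- suit_map(matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4), g)
  expect_true(all(binarize(lo, 0.05)$presence == 1))
  expect_true(all(binarize(lo, 0.9)$presence == 0))
  expect_error(binarize(lo, 0), "strictly")
  expect_error(binarize(lo, 1), "strictly")
})

test_that("realized ranges keep presence only in observed subregions", {
  g <- grid_spec(2, 5, 5)
  # two vertical regions: columns 1-3 are region 1, columns 4-5 region 2
  labels <- matrix(rep(c(1, 1, 1, 2, 2), each = 2), 2, 5)
  mosaic <- structure(
    list(labels = labels, region_ids = 1:2, seed_cells = c(1, 9), grid = g),
    class = "region_mosaic"
  )
  # potential: 6 cells in region 1, 4 cells in region 2
  pot <- manual_range(matrix(c(rep(1, 6), rep(1, 4)), 2, 5), g)
  occ_r1 <- tibble::tibble(cell = c(1, 3))
  realized <- realized_from_potential(pot, mosaic, occ_r1)
  expect_equal(sum(realized$presence == 1), 6) # enumeration oracle
  expect_true(all(realized$presence[, 4:5] == 0))

  # occurrences in every region: realized equals potential
  occ_all <- tibble::tibble(cell = c(1, 8))
  expect_equal(
    realized_from_potential(pot, mosaic, occ_all)$presence,
    pot$presence
  )

  # a point on a nodata region cell is ignored with a warning
  labels_na <- labels
  labels_na[1, 1] <- NA
  mosaic_na <- structure(
    list(labels = labels_na, region_ids = 1:2, seed_cells = c(2, 9), grid = g),
    class = "region_mosaic"
  )
  expect_warning(
    r2 <- realized_from_potential(pot, mosaic_na, tibble::tibble(cell = c(1, 3))),
    "outside all regions"
  )
  # the nodata cell itself is no longer inside any occupied region
  expect_equal(sum(r2$presence[, 1:3] == 1), 5)
  expect_error(realized_from_potential(pot, mosaic, occ_all[0, ]), "non-empty")
})

test_that("dispersal masks are exact Euclidean buffers of the current range", {
  g <- grid_spec(9, 9, 5)
  cur <- matrix(0, 9, 9)
  cur[5, 5] <- 1
  rng <- manual_range(cur, g)

  masks <- build_masks(rng, rate_km_per_year = 3, n_decades = 10)
  expect_length(masks$masks, 10)
  expect_equal(masks$radii_km, seq(30, 300, by = 30))

  # brute-force distance oracle for the first mask (30 km around one cell)
  cc <- cell_centers(g)
  d <- sqrt((cc$x - cc$x[cc$row == 5 & cc$col == 5])^2 +
    (cc$y - cc$y[cc$row == 5 & cc$col == 5])^2)
  expect_equal(as.vector(masks$masks[[1]]), d <= 30)

  # nesting and base containment
  for (i in 1:9) {
    expect_true(all(masks$masks[[i + 1]][masks$masks[[i]]]))
  }
  expect_true(all(masks$masks[[1]][cur == 1]))
  # the largest radius exceeds the grid diagonal: full coverage
  expect_true(all(masks$masks[[10]]))

  # zero rate: every mask is the current range
  m0 <- build_masks(rng, 0, 5)
  for (i in 1:5) expect_equal(as.vector(m0$masks[[i]]), as.vector(cur == 1))

  expect_warning(
    empty <- build_masks(manual_range(matrix(0, 9, 9), g), 3, 3),
    "empty"
  )
  expect_true(all(!empty$masks[[3]]))
})

test_that("buffering equals the brute-force nearest-presence distance test", {
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    nr <- sample(5:30, 1)
    nc <- sample(5:30, 1)
    g <- grid_spec(nr, nc, 5)
    cur <- matrix(rbinom(nr * nc, 1, 0.08), nr, nc)
    if (sum(cur) == 0) cur[sample(nr * nc, 1)] <- 1
    rng <- manual_range(cur, g)
    masks <- build_masks(rng, 3, 4)
    cc <- cell_centers(g)
    pres <- which(as.vector(cur) == 1)
    dmin <- vapply(seq_len(nr * nc), function(i) {
      min(sqrt((cc$x[i] - cc$x[pres])^2 + (cc$y[i] - cc$y[pres])^2))
    }, numeric(1))
    for (d_idx in 1:4) {
      expect_equal(as.vector(masks$masks[[d_idx]]), dmin <= 30 * d_idx)
    }
  }
})

test_that("dispersal scenarios clip the future potential as specified", {
  # one-dimensional shifting range: cells are 5 km, current range cols 1-10,
  # suitable climate shifts so future potential is cols 9-18
  g <- grid_spec(1, 40, 5)
  cur <- matrix(0, 1, 40)
  cur[1, 1:10] <- 1
  current <- manual_range(cur, g)
  fut <- matrix(0, 1, 40)
  fut[1, 9:18] <- 1
  future_potential <- manual_range(fut, g)
  masks <- build_masks(current, 3, 10) # 30 km per decade = 6 cells

  full <- apply_scenario(future_potential, "full")
  expect_equal(full$presence, future_potential$presence)
  expect_equal(full$scenario, "full")

  rate <- apply_scenario(future_potential, "rate_limited",
    masks = masks, decade_index = 1)
  # gained cells cannot pass the 30-km buffer edge: centre distance from
  # col 10's centre reaches 30 km at col 16 (enumeration oracle)
  expect_equal(which(rate$presence[1, ] == 1), 9:16)

  none <- apply_scenario(future_potential, "none", current_realized = current)
  expect_equal(which(none$presence[1, ] == 1), 9:10)
  expect_lte(sum(none$presence, na.rm = TRUE), sum(cur))

  # an everything-mask reduces rate-limited to full dispersal
  inf_masks <- build_masks(current, 1e6, 1)
  expect_equal(
    apply_scenario(future_potential, "rate_limited",
      masks = inf_masks, decade_index = 1)$presence,
    full$presence
  )

  expect_error(apply_scenario(future_potential, "rate_limited"), "masks")
  expect_error(apply_scenario(future_potential, "none"), "current_realized")
})

test_that("scenario nesting holds cell-wise on random instances", {
  set.seed(99)
  for (rep in 1:3) {
    g <- grid_spec(12, 12, 5)
    cur <- matrix(rbinom(144, 1, 0.15), 12, 12)
    if (sum(cur) == 0) cur[70] <- 1
    fut <- matrix(rbinom(144, 1, 0.3), 12, 12)
    current <- manual_range(cur, g)
    future_potential <- manual_range(fut, g)
    masks <- build_masks(current, 3, 3)
    pn <- apply_scenario(future_potential, "none", current_realized = current)
    pr <- apply_scenario(future_potential, "rate_limited",
      masks = masks, decade_index = 2)
    pf <- apply_scenario(future_potential, "full")
    expect_true(all(pr$presence[pn$presence == 1] == 1))
    expect_true(all(pf$presence[pr$presence == 1] == 1))
  }
})

test_that("region-level no-dispersal keeps whole occupied subregions", {
  g <- grid_spec(2, 4, 5)
  labels <- matrix(rep(c(1, 1, 2, 2), each = 2), 2, 4)
  mosaic <- structure(
    list(labels = labels, region_ids = 1:2, seed_cells = c(1, 5), grid = g),
    class = "region_mosaic"
  )
  cur <- matrix(0, 2, 4)
  cur[1, 1] <- 1 # occupies region 1 only
  fut <- matrix(1, 2, 4)
  out <- apply_scenario(manual_range(fut, g), "none",
    current_realized = manual_range(cur, g),
    none_level = "region", mosaic = mosaic
  )
  expect_true(all(out$presence[, 1:2] == 1)) # whole region 1 reachable
  expect_true(all(out$presence[, 3:4] == 0))
})

test_that("the realistic scenario selects by metadata category", {
  meta <- dplyr::bind_rows(
    species_meta("s1", "M", "arid", "full"),
    species_meta("s2", "S", "tropical", "rate_limited"),
    species_meta("s3", "N", "temperate", "none")
  )
  outputs <- list(
    full = list(s1 = "F1", s2 = "F2", s3 = "F3"),
    rate_limited = list(s1 = "R1", s2 = "R2", s3 = "R3"),
    none = list(s1 = "N1", s2 = "N2", s3 = "N3")
  )
  out <- realistic_scenario(meta, outputs)
  expect_equal(out, list(s1 = "F1", s2 = "R2", s3 = "N3"))

  bad <- meta
  bad$dispersal_category[2] <- "teleport"
  expect_error(realistic_scenario(bad, outputs), "unknown dispersal category")
})
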