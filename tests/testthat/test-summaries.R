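test_that("class statistics match closed-form values on tiny ranges", {
  g <- grid_spec(2, 2, 5)
  empty <- class_stats(manual_range(matrix(0, 2, 2), g))
  expect_equal(empty$total_area_km2, 0)
  expect_equal(empty$n_patches, 0L)
  expect_equal(empty$proportion_landscape, 0)
  expect_equal(empty$edge_length_km, 0)

  single <- matrix(0, 2, 2)
  single[1, 1] <- 1
  cs <- class_stats(manual_range(single, g))
  expect_equal(cs$total_area_km2, 25) # one 5 x 5 km cell
  expect_equal(cs$n_patches, 1L)
  expect_equal(cs$proportion_landscape, 0.25)
  expect_equal(cs$mean_patch_area_km2, 25)
  expect_equal(cs$edge_length_km, 20) # 4 edges x 5 km

  diagonal <- diag(2)
  expect_equal(class_stats(manual_range(diagonal, g), connectivity = 8)$n_patches, 1L)
  expect_equal(class_stats(manual_range(diagonal, g), connectivity = 4)$n_patches, 2L)
  expect_error(class_stats(manual_range(diagonal, g), connectivity = 6), "4 or 8")
})

test_that("patch counting agrees with a flood-fill oracle on random rasters", {
  set.seed(611)
  for (rep in 1:6) {
    nr <- sample(5:20, 1)
    nc <- sample(5:20, 1)
    g <- grid_spec(nr, nc, 5)
    m <- matrix(rbinom(nr * nc, 1, runif(1, 0.2, 0.6)), nr, nc)
    rng <- manual_range(m, g)
    for (conn in c(4, 8)) {
      expect_equal(
        class_stats(rng, connectivity = conn)$n_patches,
        flood_fill_patches(m == 1, conn),
        info = sprintf("rep %d conn %d", rep, conn)
      )
    }
  }
})

test_that("proportional change classifies on the two-decimal rounded ratio", {
  inc <- proportional_change(176, 100)
  expect_equal(inc$proportion_of_current, 1.76)
  expect_equal(inc$direction, "Increase")

  expect_equal(proportional_change(100, 100)$direction, "No change")
  # 1.004 rounds to 1.00: no change despite a tiny gain
  expect_equal(proportional_change(100.4, 100)$direction, "No change")
  expect_equal(proportional_change(101, 100)$direction, "Increase")

  dec <- proportional_change(6, 100)
  expect_equal(dec$proportion_of_current, 0.06)
  expect_equal(dec$direction, "Decrease")

  expect_error(proportional_change(10, 0), "undefined ratio")
})

test_that("assemblage summaries aggregate directions and percent shifts", {
  same <- dplyr::bind_rows(lapply(1:4, function(i) proportional_change(50, 50)))
  s1 <- assemblage_summary(same)
  expect_equal(s1$pct_no_change, 100)
  expect_equal(s1$mean_pct_shift, 0)

  two <- dplyr::bind_rows(
    proportional_change(50, 100), proportional_change(150, 100)
  )
  s2 <- assemblage_summary(two)
  expect_equal(s2$n_increase, 1)
  expect_equal(s2$n_decrease, 1)
  expect_equal(s2$mean_pct_increase, 50)
  expect_equal(s2$mean_pct_decrease, 50)
  expect_equal(s2$mean_pct_shift, 0)

  # twelve-record enumeration oracle
  ratios <- c(0.2, 0.5, 0.8, 0.95, 1.0, 1.0, 1.04, 1.1, 1.3, 1.5, 1.8, 2.4)
  recs <- dplyr::bind_rows(lapply(ratios, function(r) {
    proportional_change(100 * r, 100)
  }))
  s3 <- assemblage_summary(recs)
  expect_equal(s3$n_species, 12)
  expect_equal(s3$n_decrease, 4) # 0.2, 0.5, 0.8, 0.95
  expect_equal(s3$n_no_change, 2)
  expect_equal(s3$n_increase, 6)
  expect_equal(s3$pct_increase, 50)
  expect_equal(s3$mean_pct_decrease, mean(c(80, 50, 20, 5)))
  expect_equal(s3$mean_pct_increase, mean(c(4, 10, 30, 50, 80, 140)))
  expect_equal(s3$mean_pct_shift, mean(100 * (ratios - 1)))
  expect_equal(s3$n_small_change, sum(abs(ratios - 1) < 0.1))
  expect_equal(s3$n_increase_50plus, 3) # 1.5, 1.8, 2.4
})

test_that("richness stacking is an exact cell-wise sum with conservation", {
  g <- grid_spec(4, 4, 5)
  one <- manual_range(matrix(rbinom(16, 1, 0.5), 4, 4), g, "a")
  r1 <- richness_stack(list(one))
  expect_equal(r1$counts, one$presence)

  full <- lapply(letters[1:5], function(id) {
    manual_range(matrix(1, 4, 4), g, id)
  })
  expect_true(all(richness_stack(full)$counts == 5))

  set.seed(12)
  ranges <- lapply(letters[1:5], function(id) {
    manual_range(matrix(rbinom(16, 1, 0.4), 4, 4), g, id)
  })
  stacked <- richness_stack(ranges)
  manual <- Reduce(`+`, lapply(ranges, function(r) r$presence))
  expect_equal(stacked$counts, manual)
  # conservation: total richness equals the summed per-species areas
  expect_equal(
    sum(stacked$counts),
    sum(vapply(ranges, function(r) sum(r$presence), numeric(1)))
  )

  other <- manual_range(matrix(1, 3, 3), grid_spec(3, 3, 5), "x")
  expect_error(richness_stack(c(ranges, list(other))), "grid")
})

test_that("richness change is a signed difference and orders with dispersal", {
  g <- grid_spec(4, 4, 5)
  set.seed(21)
  start_ranges <- lapply(letters[1:4], function(id) {
    manual_range(matrix(rbinom(16, 1, 0.6), 4, 4), g, id)
  })
  r0 <- richness_stack(start_ranges)
  expect_true(all(richness_change(r0, r0) == 0))

  # nested scenario futures: none <= rate <= full transfers to change maps
  nones <- list()
  rates <- list()
  fulls <- list()
  for (i in 1:4) {
    f <- matrix(rbinom(16, 1, 0.6), 4, 4)
    r <- f * matrix(rbinom(16, 1, 0.8), 4, 4)
    n <- r * matrix(rbinom(16, 1, 0.8), 4, 4)
    id <- letters[i]
    fulls[[i]] <- manual_range(f, g, id)
    rates[[i]] <- manual_range(r, g, id)
    nones[[i]] <- manual_range(n, g, id)
  }
  ch_full <- richness_change(r0, richness_stack(fulls))
  ch_rate <- richness_change(r0, richness_stack(rates))
  ch_none <- richness_change(r0, richness_stack(nones))
  expect_true(all(ch_none <= ch_rate))
  expect_true(all(ch_rate <= ch_full))

  r_other <- richness_stack(start_ranges[1:3])
  expect_error(richness_change(r0, r_other), "species list")
})

test_that("group comparison reproduces hand-computed one-way ANOVA", {
  df <- tibble::tibble(
    proportion_of_current = c(1, 2, 3, 4, 5, 6),
    grp = rep(c("a", "b"), each = 3)
  )
  out <- group_comparison(df, "grp")
  # SSB = 13.5, SSW = 4, df = (1, 4): F = 13.5 / (4/4) = 13.5
  expect_equal(out$test$statistic, 13.5, tolerance = 1e-10)
  expect_equal(out$test$df1, 1)
  expect_equal(out$test$df2, 4)
  expect_equal(out$test$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE),
    tolerance = 1e-10)
  expect_equal(out$groups$median, c(2, 5))

  flat <- tibble::tibble(
    proportion_of_current = rep(1, 6), grp = rep(c("a", "b"), 3)
  )
  out2 <- group_comparison(flat, "grp")
  expect_equal(out2$test$statistic, 0)
  expect_equal(out2$test$p_value, 1)

  tiny <- tibble::tibble(
    proportion_of_current = c(1, 2, 3, 4, 9),
    grp = c("a", "a", "b", "b", "c")
  )
  expect_warning(out3 <- group_comparison(tiny, "grp"), "fewer than 2")
  expect_setequal(out3$groups$group, c("a", "b"))

  expect_error(
    suppressWarnings(group_comparison(tiny[1:3, ], "grp")),
    "at least 2 groups"
  )
})

test_that("the F statistic's permutation distribution matches its p-value", {
  # under an exchangeable null, the ANOVA p-value and the permutation
  # p-value of the observed F must agree closely
  set.seed(812)
  df <- tibble::tibble(
    proportion_of_current = rnorm(24, 1, 0.3),
    grp = rep(c("a", "b", "c"), each = 8)
  )
  obs <- group_comparison(df, "grp")
  perm_f <- vapply(1:500, function(i) {
    d2 <- df
    d2$grp <- sample(d2$grp)
    group_comparison(d2, "grp")$test$statistic
  }, numeric(1))
  p_perm <- mean(perm_f >= obs$test$statistic)
  expect_lt(abs(p_perm - obs$test$p_value), 0.1)
})
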