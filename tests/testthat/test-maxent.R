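# small random landscape shared by several fitting tests
maxent_toy_landscape <- function(seed = 31, nr = 8, nc = 8) {
  g <- grid_spec(nr, nc, 5)
  derive_bioclim(make_monthly_climate(g, seed = seed))
}

test_that("background sampling covers, truncates and reproduces", {
  stk <- maxent_toy_landscape()
  n <- length(stk$mat)
  expect_equal(build_background(stk, n, seed = 1), seq_len(n))
  expect_message(
    bg_all <- build_background(stk, n + 100, seed = 1),
    "using all"
  )
  expect_equal(bg_all, seq_len(n))
  b1 <- build_background(stk, 20, seed = 4)
  expect_length(b1, 20)
  expect_identical(b1, build_background(stk, 20, seed = 4))
  empty <- manual_stack(grid_spec(2, 2, 5), mat = matrix(NA_real_, 2, 2))
  expect_error(build_background(empty, 4, seed = 1), "empty raster")
})

test_that("one-variable toy fit matches closed form and a grid-search oracle", {
  # landscape: only mat varies; 3 background cells with mat = 10, 15, 20
  # (normalised feature z = 0, 0.5, 1); 10 presence cells with mat
  # 10 x1, 15 x4, 20 x5, so presence means are E[z] = 0.7, E[z^2] = 0.6.
  g <- grid_spec(1, 13, 5)
  mat_vals <- c(10, 15, 20, 10, rep(15, 4), rep(20, 5))
  stk <- manual_stack(g, mat = matrix(mat_vals, 1, 13))
  fit <- fit_maxent(stk,
    presence_cells = 4:13, background_cells = 1:3,
    beta_multiplier = 0, add_presence_to_background = FALSE
  )
  # moment matching on three atoms has the closed-form optimum
  # q = (0.1, 0.4, 0.5), i.e. lambda1 = ln5 + 2ln4 - ln5 ... solved exactly:
  lam2 <- -2 * (2 * log(4) - log(5))
  lam1 <- log(5) - lam2
  expect_equal(unname(fit$lambda["mat"]), lam1, tolerance = 1e-3)
  expect_equal(unname(fit$lambda["mat^2"]), lam2, tolerance = 1e-3)
  expect_true(all(fit$lambda[setdiff(names(fit$lambda), c("mat", "mat^2"))] == 0))

  # independent oracle: two-stage grid search of the penalised log-likelihood
  ll <- function(l1, l2) {
    0.7 * l1 + 0.6 * l2 -
      log(1 + exp(0.5 * l1 + 0.25 * l2) + exp(l1 + l2))
  }
  coarse <- expand.grid(l1 = seq(-50, 50, by = 0.25),
    l2 = seq(-50, 50, by = 0.25))
  v <- ll(coarse$l1, coarse$l2)
  best <- coarse[which.max(v), ]
  fine <- expand.grid(
    l1 = seq(best$l1 - 0.3, best$l1 + 0.3, by = 0.002),
    l2 = seq(best$l2 - 0.3, best$l2 + 0.3, by = 0.002)
  )
  vf <- ll(fine$l1, fine$l2)
  bestf <- fine[which.max(vf), ]
  expect_equal(unname(fit$lambda["mat"]), bestf$l1, tolerance = 2e-3)
  expect_equal(unname(fit$lambda["mat^2"]), bestf$l2, tolerance = 2e-3)
})

test_that("the fully penalised limit is the uniform distribution", {
  stk <- maxent_toy_landscape()
  bg <- seq_len(length(stk$mat))
  pres <- c(1, 5, 9, 13, 17, 21)
  fit <- fit_maxent(stk, pres, bg, beta_multiplier = 1e6)
  expect_true(all(fit$lambda == 0))
  expect_equal(fit$H, log(fit$n_background))
})

test_that("presences distributed exactly like the background leave lambda at zero", {
  stk <- maxent_toy_landscape(seed = 55, nr = 3, nc = 3)
  cells <- 1:9
  fit <- fit_maxent(stk, cells, cells, beta_multiplier = 0)
  expect_true(all(fit$lambda == 0))
})

test_that("fits satisfy conservation, KKT conditions and objective uniqueness", {
  stk <- maxent_toy_landscape(seed = 77)
  bg <- seq_len(length(stk$mat))
  pres <- with_seed_test(101, sample(bg, 25))
  fit <- fit_maxent(stk, pres, bg)

  # raw distribution sums to one over the background
  raw <- nichecast:::raw_scores(fit, stk, fit$background_cells)
  expect_equal(sum(raw), 1, tolerance = 1e-10)

  # KKT: for active features the smooth gradient is balanced by the penalty
  env <- nichecast:::stack_env_matrix(stk)
  fb <- nichecast:::feature_matrix(fit$features, env[fit$background_cells, ])
  fp <- nichecast:::feature_matrix(fit$features, env[fit$presence_cells, ])
  u <- as.vector(fb %*% fit$lambda)
  q <- exp(u - max(u))
  q <- q / sum(q)
  grad <- as.vector(crossprod(fb, q)) - colMeans(fp)
  active <- fit$lambda != 0
  expect_true(all(abs(grad[active]) <= fit$beta[active] + 1e-5))
  expect_true(all(abs(grad[!active]) <= fit$beta[!active] + 1e-5))

  # concavity: random restarts reach the same optimum value
  objs <- vapply(1:5, function(i) {
    init <- with_seed_test(200 + i, stats::rnorm(length(fit$lambda), 0, 0.5))
    fit_maxent(stk, pres, bg, init = init)$objective
  }, numeric(1))
  expect_lt(max(objs) - min(objs), 1e-6)
})

test_that("logistic output is the entropy-calibrated monotone rescaling of raw", {
  stk <- maxent_toy_landscape(seed = 12)
  bg <- seq_len(length(stk$mat))
  # uniform raw: logistic is exactly 0.5 everywhere
  flat <- fit_maxent(stk, c(2, 6, 10, 14, 18), bg, beta_multiplier = 1e6)
  map <- predict_logistic(flat, stk)
  expect_true(all(abs(map$values - 0.5) < 1e-12))

  pres <- with_seed_test(303, sample(bg, 20))
  fit <- fit_maxent(stk, pres, bg)
  map2 <- predict_logistic(fit, stk)
  raw <- nichecast:::raw_scores(fit, stk)
  # strictly increasing in raw, strictly inside (0, 1)
  ord <- order(raw)
  expect_true(all(diff(map2$values[ord]) >= 0))
  expect_true(all(map2$values > 0 & map2$values < 1))
  # raw = exp(-H) maps to 0.5
  eta <- fit$H + log(raw)
  expect_equal(as.vector(map2$values), stats::plogis(eta), tolerance = 1e-12)
})

test_that("AUC is the Mann-Whitney statistic with half-weight ties", {
  scores <- c(rep(0.9, 10), rep(0.1, 15))
  expect_equal(sdm_auc(scores, 1:10, 11:25), 1)
  expect_equal(sdm_auc(rep(0.4, 30), 1:10, 11:30), 0.5)

  set.seed(404)
  s <- round(runif(50), 2) # rounding forces ties
  pres <- 1:20
  bg <- 21:50
  oracle <- mean(outer(s[pres], s[bg], function(a, b) {
    (a > b) + 0.5 * (a == b)
  }))
  expect_equal(sdm_auc(s, pres, bg), oracle, tolerance = 1e-12)
  expect_error(sdm_auc(s, integer(0), bg), "non-empty")
})

test_that("AUC screening keeps the 0.70 boundary and excludes below it", {
  models <- tibble::tibble(
    species_id = c("a", "b", "c"),
    auc = c(0.70, 0.69, 0.95)
  )
  out <- screen_models(models)
  expect_setequal(out$kept$species_id, c("a", "c"))
  expect_equal(out$excluded$species_id, "b")
  empty <- screen_models(models[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("entropy-equating threshold retains the entropy-matched cell count", {
  stk <- maxent_toy_landscape(seed = 91, nr = 10, nc = 10)
  bg <- seq_len(100)

  # uniform raw: k = N, threshold = the minimum logistic value
  flat <- fit_maxent(stk, c(3, 7, 11, 15, 19), bg, beta_multiplier = 1e6)
  thr <- entropy_threshold(flat, stk)
  map <- predict_logistic(flat, stk)
  expect_equal(thr, min(map$values))
  expect_true(all(map$values >= thr)) # every cell retained

  # fitted model: k minimises |log k - H| over all possible counts
  pres <- with_seed_test(505, sample(bg, 30))
  fit <- fit_maxent(stk, pres, bg)
  thr2 <- entropy_threshold(fit, stk)
  v <- sort(as.vector(predict_logistic(fit, stk)$values), decreasing = TRUE)
  k <- sum(v >= thr2)
  gaps <- abs(log(seq_along(v)) - fit$H)
  expect_lte(abs(log(k) - fit$H), min(gaps) + 1e-12)

  # degenerate point mass: only the top cell survives
  point <- fit
  point$H <- 0
  thr3 <- entropy_threshold(point, stk)
  expect_equal(thr3, max(predict_logistic(point, stk)$values))
})

test_that("too few presence cells is a hard error", {
  stk <- maxent_toy_landscape()
  expect_error(
    fit_maxent(stk, c(1, 2, 3, 3, 3), seq_len(64)),
    "too few records"
  )
})

test_that("models round-trip through JSON with identical predictions", {
  stk <- maxent_toy_landscape(seed = 17)
  bg <- seq_len(length(stk$mat))
  pres <- with_seed_test(606, sample(bg, 15))
  fit <- fit_maxent(stk, pres, bg, species_id = "json-test")
  fit$auc <- sdm_auc(predict_logistic(fit, stk), pres, bg)
  fit$threshold_logistic <- entropy_threshold(fit, stk)
  path <- tempfile(fileext = ".json")
  write_maxent_json(fit, path)
  back <- read_maxent_json(path)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$H, fit$H)
  expect_equal(back$auc, fit$auc)
  expect_equal(
    predict_logistic(back, stk)$values,
    predict_logistic(fit, stk)$values
  )
})

test_that("tidy and glance summarise fitted models", {
  stk <- maxent_toy_landscape(seed = 3)
  bg <- seq_len(length(stk$mat))
  fit <- fit_maxent(stk, c(1, 9, 17, 25, 33, 41), bg, species_id = "td")
  td <- tidy(fit)
  expect_equal(nrow(td), 27)
  expect_named(td, c("term", "estimate", "penalty", "active"))
  gl <- glance(fit)
  expect_equal(gl$species_id, "td")
  expect_true(gl$converged)
  expect_equal(gl$n_presence, 6)
})
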