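#' Sample background cells from a climate stack
#'
#' Draws a uniform sample (without replacement) of non-nodata cells to serve
#' as the landscape background of a presence-background model. If fewer cells
#' are available than requested, all non-nodata cells are used and a message
#' is emitted.
#'
#' @param stack A `climate_stack`.
#' @param n_background Number of background cells requested (default 10000).
#' @param seed Integer seed; the sample is reproducible under a fixed seed.
#' @return Sorted integer vector of cell indices.
#' @export
build_background <- function(stack, n_background = 10000, seed = 1) {
  stopifnot(inherits(stack, "climate_stack"))
  ok <- stats::complete.cases(stack_env_matrix(stack))
  avail <- which(ok)
  if (length(avail) == 0) {
    stop("empty raster: no non-nodata cells to sample background from",
      call. = FALSE
    )
  }
  if (n_background >= length(avail)) {
    if (n_background > length(avail)) {
      message(
        "requested ", n_background, " background cells but only ",
        length(avail), " non-nodata cells exist; using all of them"
      )
    }
    return(avail)
  }
  sort(with_seed(
    derive_seed(seed, "background"),
    sample(avail, n_background)
  ))
}

# environment matrix (cells x 6 bioclim variables) for a whole stack
stack_env_matrix <- function(stack) {
  vars <- bioclim_vars()
  for (v in vars) {
    if (is.null(stack[[v]])) {
      stop("climate stack is missing variable layer `", v, "`", call. = FALSE)
    }
  }
  do.call(cbind, stats::setNames(
    lapply(vars, function(v) as.vector(stack[[v]])), vars
  ))
}

env_at_cells <- function(stack, cells) {
  stack_env_matrix(stack)[cells, , drop = FALSE]
}

# Feature space: linear + quadratic + pairwise-product features of the six
# bioclim variables (27 features), min-max normalised on the background.
make_feature_space <- function(bg_env) {
  vars <- colnames(bg_env)
  rng <- apply(bg_env, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1 # constant variable: normalised feature is constant 0
  pairs <- utils::combn(vars, 2)
  structure(
    list(
      vars = vars,
      min = rng[1, ], span = span,
      terms = c(
        vars,
        paste0(vars, "^2"),
        paste0(pairs[1, ], ":", pairs[2, ])
      ),
      pairs = pairs
    ),
    class = "feature_space"
  )
}

feature_matrix <- function(fs, env) {
  z <- sweep(env[, fs$vars, drop = FALSE], 2, fs$min, "-")
  z <- sweep(z, 2, fs$span, "/")
  z <- pmin(pmax(z, 0), 1) # clamp to the training [0,1] range
  prod_cols <- z[, fs$pairs[1, ], drop = FALSE] * z[, fs$pairs[2, ], drop = FALSE]
  f <- cbind(z, z^2, prod_cols)
  colnames(f) <- fs$terms
  f
}

log_sum_exp <- function(u) {
  m <- max(u)
  m + log(sum(exp(u - m)))
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a maximum-entropy presence-background model
#'
#' Estimates feature coefficients `lambda` maximising the L1-penalised
#' presence log-likelihood
#' `mean_presence(lambda . f(x)) - log Z(lambda) - sum_j beta_j |lambda_j|`,
#' where `Z` sums `exp(lambda . f)` over the background cells. The fitted raw
#' distribution is the Gibbs distribution `exp(lambda . f(x)) / Z` over the
#' background. Features are the linear, quadratic and pairwise-product
#' features of the six bioclim variables, min-max normalised on the
#' background; per-feature penalties follow the classic error-bound form
#' `beta_j = beta_multiplier * sd_j / sqrt(m)` with `m` the number of unique
#' presence cells and `sd_j` the feature's standard deviation over the
#' presence sample (floored at 5% of its background standard deviation so no
#' feature is ever unpenalised), or over the background with
#' `beta_scale = "background"`.
#'
#' The objective is concave, so the optimum value is unique; optimisation uses
#' accelerated proximal gradient (FISTA) with backtracking and monotone
#' restarts. Convergence requires the minimal-norm subgradient's maximum
#' absolute component to drop to `grad_tol` or the objective change to drop
#' to `obj_tol`.
#'
#' @param stack A `climate_stack` providing the covariates.
#' @param presence_cells Integer cell indices of presence records (duplicates
#'   are collapsed to one per cell; at least 5 unique cells required).
#' @param background_cells Integer cell indices of the background sample, e.g.
#'   from [build_background()].
#' @param beta_multiplier Non-negative scale on the per-feature L1 penalties
#'   (default 1).
#' @param beta_scale Whether per-feature penalty scales come from the feature
#'   spread over the presence sample (`"presence"`, the classic default) or
#'   over the background (`"background"`).
#' @param add_presence_to_background Add presence cells to the background sum
#'   (standard presence-background construction; default `TRUE`).
#' @param species_id Optional species label stored in the model.
#' @param max_iter Iteration cap (error on non-convergence).
#' @param grad_tol,obj_tol Convergence tolerances (see above).
#' @param init Optional numeric start for `lambda` (default all zero).
#' @return A `maxent_model`: coefficients, penalties, `logZ`, entropy `H` of
#'   the fitted raw distribution (nats), cell sets, convergence diagnostics.
#' @export
fit_maxent <- function(stack, presence_cells, background_cells,
                       beta_multiplier = 1,
                       beta_scale = c("presence", "background"),
                       add_presence_to_background = TRUE,
                       species_id = NA_character_,
                       max_iter = 20000L, grad_tol = 1e-6, obj_tol = 1e-9,
                       init = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  if (beta_multiplier < 0) stop("`beta_multiplier` must be >= 0", call. = FALSE)
  env_all <- stack_env_matrix(stack)
  presence_cells <- unique(presence_cells)
  presence_cells <- presence_cells[
    stats::complete.cases(env_all[presence_cells, , drop = FALSE])
  ]
  if (length(presence_cells) < 5) {
    stop(
      "too few records: need >= 5 unique presence cells with climate data, got ",
      length(presence_cells),
      call. = FALSE
    )
  }
  background_cells <- unique(background_cells)
  if (add_presence_to_background) {
    background_cells <- sort(union(background_cells, presence_cells))
  }
  background_cells <- background_cells[
    stats::complete.cases(env_all[background_cells, , drop = FALSE])
  ]
  if (length(background_cells) == 0) {
    stop("background is empty after removing nodata cells", call. = FALSE)
  }

  fs <- make_feature_space(env_all[background_cells, , drop = FALSE])
  fb <- feature_matrix(fs, env_all[background_cells, , drop = FALSE])
  fp <- feature_matrix(fs, env_all[presence_cells, , drop = FALSE])
  beta_scale <- match.arg(beta_scale)
  m <- nrow(fp)
  pbar <- colMeans(fp)
  sd_b <- apply(fb, 2, stats::sd)
  sd_scale <- if (beta_scale == "presence") {
    pmax(apply(fp, 2, stats::sd), 0.05 * sd_b)
  } else {
    sd_b
  }
  beta <- beta_multiplier * sd_scale / sqrt(m)

  k <- ncol(fb)
  lambda <- if (is.null(init)) numeric(k) else {
    stopifnot(length(init) == k)
    as.numeric(init)
  }

  smooth_obj <- function(l) log_sum_exp(fb %*% l) - sum(pbar * l)
  smooth_grad <- function(l) {
    u <- as.vector(fb %*% l)
    q <- exp(u - log_sum_exp(u))
    as.vector(crossprod(fb, q)) - pbar
  }
  obj <- function(l) smooth_obj(l) + sum(beta * abs(l))
  subgrad_norm <- function(l, g) {
    s <- ifelse(l != 0, g + beta * sign(l), soft_threshold(g, beta))
    max(abs(s))
  }

  lstep <- 1 # local Lipschitz estimate for backtracking
  y <- lambda
  t_acc <- 1
  f_cur <- obj(lambda)
  converged <- FALSE
  iter <- 0L
  g_now <- smooth_grad(lambda)
  if (subgrad_norm(lambda, g_now) <= grad_tol) converged <- TRUE
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    gy <- smooth_grad(y)
    sy <- smooth_obj(y)
    repeat {
      cand <- soft_threshold(y - gy / lstep, beta / lstep)
      dl <- cand - y
      if (smooth_obj(cand) <= sy + sum(gy * dl) + lstep / 2 * sum(dl^2)) break
      lstep <- lstep * 2
    }
    f_new <- obj(cand)
    if (f_new > f_cur) { # monotone restart
      y <- lambda
      t_acc <- 1
      gy <- smooth_grad(y)
      sy <- smooth_obj(y)
      repeat {
        cand <- soft_threshold(y - gy / lstep, beta / lstep)
        dl <- cand - y
        if (smooth_obj(cand) <= sy + sum(gy * dl) + lstep / 2 * sum(dl^2)) break
        lstep <- lstep * 2
      }
      f_new <- obj(cand)
    }
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- cand + (t_acc - 1) / t_next * (cand - lambda)
    lambda_prev <- lambda
    lambda <- cand
    t_acc <- t_next
    lstep <- max(lstep / 2, 1e-8) # allow the step to grow back

    g_now <- smooth_grad(lambda)
    if (subgrad_norm(lambda, g_now) <= grad_tol ||
      abs(f_cur - f_new) <= obj_tol) {
      converged <- TRUE
    }
    f_cur <- f_new
  }
  if (!converged) {
    stop(
      "maxent fit did not converge in ", max_iter,
      " iterations (subgradient norm ",
      format(subgrad_norm(lambda, g_now), digits = 3), ")",
      call. = FALSE
    )
  }

  u <- as.vector(fb %*% lambda)
  logz <- log_sum_exp(u)
  q <- exp(u - logz)
  h <- -sum(q * log(q))

  structure(
    list(
      species_id = species_id,
      features = fs,
      lambda = stats::setNames(as.vector(lambda), fs$terms),
      beta = stats::setNames(as.vector(beta), fs$terms),
      logZ = logz,
      H = h,
      n_presence = m,
      n_background = length(background_cells),
      presence_cells = presence_cells,
      background_cells = background_cells,
      beta_multiplier = beta_multiplier,
      iterations = iter,
      converged = converged,
      log_likelihood = sum(pbar * lambda) - logz,
      objective = -f_cur,
      auc = NA_real_,
      threshold_logistic = NA_real_
    ),
    class = "maxent_model"
  )
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %s: %d features (%d active), m=%d presences, N=%d background\n",
    ifelse(is.na(x$species_id), "(unnamed)", x$species_id),
    length(x$lambda), sum(x$lambda != 0), x$n_presence, x$n_background
  ))
  cat(sprintf(
    "  logZ=%.4f  H=%.4f nats  penalised logL=%.4f  iterations=%d\n",
    x$logZ, x$H, x$objective, x$iterations
  ))
  if (!is.na(x$auc)) cat(sprintf("  AUC=%.3f", x$auc))
  if (!is.na(x$threshold_logistic)) {
    cat(sprintf("  logistic threshold=%.4f", x$threshold_logistic))
  }
  if (!is.na(x$auc) || !is.na(x$threshold_logistic)) cat("\n")
  invisible(x)
}

# raw Gibbs density (relative to the training partition function) at cells
raw_scores <- function(model, stack, cells = NULL) {
  env <- stack_env_matrix(stack)
  if (!is.null(cells)) env <- env[cells, , drop = FALSE]
  ok <- stats::complete.cases(env)
  out <- rep(NA_real_, nrow(env))
  if (any(ok)) {
    f <- feature_matrix(model$features, env[ok, , drop = FALSE])
    out[ok] <- exp(as.vector(f %*% model$lambda) - model$logZ)
  }
  out
}

#' Predict logistic suitability over a climate stack
#'
#' Applies the fitted model to every cell: features are clamped to the
#' training range and the raw Gibbs score `raw(x) = exp(lambda . f(x)) / Z`
#' is rescaled to the logistic suitability index
#' `exp(H) raw / (1 + exp(H) raw)`, which lies strictly in (0, 1) and equals
#' 0.5 where `raw` equals the typical presence score `exp(-H)`.
#'
#' @param model A `maxent_model`.
#' @param stack A `climate_stack` with all six variable layers.
#' @param provenance Label recorded with the map (e.g. `"baseline"` or a
#'   gcm/realization/decade tag).
#' @return A `suitability_map`: list with `values` (matrix in (0,1), `NA` at
#'   nodata), `grid`, `species_id`, `provenance`.
#' @export
predict_logistic <- function(model, stack, provenance = "baseline") {
  stopifnot(inherits(model, "maxent_model"), inherits(stack, "climate_stack"))
  env <- stack_env_matrix(stack)
  ok <- stats::complete.cases(env)
  vals <- rep(NA_real_, nrow(env))
  if (any(ok)) {
    f <- feature_matrix(model$features, env[ok, , drop = FALSE])
    eta <- model$H + as.vector(f %*% model$lambda) - model$logZ
    vals[ok] <- stats::plogis(eta)
  }
  structure(
    list(
      values = new_raster(vals, stack$grid),
      grid = stack$grid,
      species_id = model$species_id,
      provenance = provenance
    ),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "<suitability_map> %s [%s]: values in [%.4f, %.4f]\n",
    ifelse(is.na(x$species_id), "(unnamed)", x$species_id),
    x$provenance, rng[1], rng[2]
  ))
  invisible(x)
}

#' Area under the ROC curve for presence vs background scores
#'
#' Mann-Whitney formulation: the probability that a randomly chosen presence
#' outranks a randomly chosen background point, with ties counted one half.
#'
#' @param x A `suitability_map` (or plain score matrix/vector on the grid).
#' @param presence_cells,background_cells Non-empty integer cell index sets;
#'   cells with `NA` scores are dropped.
#' @return AUC in \[0, 1\].
#' @export
sdm_auc <- function(x, presence_cells, background_cells) {
  scores <- if (inherits(x, "suitability_map")) as.vector(x$values) else as.vector(x)
  sp <- scores[presence_cells]
  sb <- scores[background_cells]
  sp <- sp[!is.na(sp)]
  sb <- sb[!is.na(sb)]
  if (length(sp) == 0 || length(sb) == 0) {
    stop("both presence and background sets must be non-empty", call. = FALSE)
  }
  r <- rank(c(sp, sb)) # midranks: ties counted 1/2
  n <- length(sp)
  (sum(r[seq_len(n)]) - n * (n + 1) / 2) / (n * length(sb))
}

#' Screen fitted models by AUC
#'
#' Splits a model table into models kept for species-level analyses
#' (`auc >= threshold`) and excluded low performers. Excluded species are
#' retained (in the `excluded` table) because richness stacking uses all
#' species regardless of model performance.
#'
#' @param models A data frame with at least an `auc` column.
#' @param threshold AUC cut-off; models strictly below it are excluded
#'   (default 0.7).
#' @return List of two tibbles, `kept` and `excluded`.
#' @export
screen_models <- function(models, threshold = 0.7) {
  models <- tibble::as_tibble(models)
  if (nrow(models) == 0) {
    return(list(kept = models, excluded = models))
  }
  if (any(is.na(models$auc))) {
    stop("every model must have an AUC before screening", call. = FALSE)
  }
  list(
    kept = dplyr::filter(models, .data$auc >= threshold),
    excluded = dplyr::filter(models, .data$auc < threshold)
  )
}

#' Entropy-equating binarisation threshold
#'
#' Chooses the logistic threshold whose retained area has (uniform) entropy
#' closest to the fitted distribution's entropy `H`: the retained cell count
#' is `k = round(exp(H))` clipped to `[1, N]` (minimising `|log k - H|`), and
#' the threshold is the k-th largest logistic value over the landscape. The
#' threshold is computed once on the baseline landscape and reused for all
#' future projections.
#'
#' @param model A `maxent_model`.
#' @param stack Baseline `climate_stack` defining the landscape.
#' @return The logistic threshold value.
#' @export
entropy_threshold <- function(model, stack) {
  map <- predict_logistic(model, stack)
  v <- sort(as.vector(map$values), decreasing = TRUE, na.last = NA)
  n <- length(v)
  if (n == 0) stop("no non-nodata cells in the landscape", call. = FALSE)
  k <- min(max(round(exp(model$H)), 1), n)
  v[k]
}

#' Serialise / restore a fitted maxent model as JSON
#'
#' @param model A `maxent_model`.
#' @param path File path.
#' @return `path` invisibly; [read_maxent_json()] returns the restored
#'   `maxent_model`.
#' @export
write_maxent_json <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  doc <- unclass(model)
  doc$features <- list(
    vars = model$features$vars,
    min = as.list(model$features$min),
    span = as.list(model$features$span)
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_maxent_json
#' @export
read_maxent_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fs_min <- unlist(doc$features$min)
  fs_span <- unlist(doc$features$span)
  vars <- doc$features$vars
  pairs <- utils::combn(vars, 2)
  fs <- structure(
    list(
      vars = vars,
      min = stats::setNames(as.numeric(fs_min), vars),
      span = stats::setNames(as.numeric(fs_span), vars),
      terms = c(vars, paste0(vars, "^2"), paste0(pairs[1, ], ":", pairs[2, ])),
      pairs = pairs
    ),
    class = "feature_space"
  )
  model <- doc
  model$features <- fs
  model$lambda <- stats::setNames(as.numeric(doc$lambda), fs$terms)
  model$beta <- stats::setNames(as.numeric(doc$beta), fs$terms)
  for (fld in c("auc", "threshold_logistic")) {
    if (is.null(model[[fld]])) model[[fld]] <- NA_real_
  }
  class(model) <- "maxent_model"
  model
}
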