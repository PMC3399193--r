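#' Tidy a fitted maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with one row per feature: `term`, `estimate` (coefficient),
#'   `penalty` (L1 weight), `active` (non-zero coefficient).
#' @method tidy maxent_model
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(
    term = names(x$lambda),
    estimate = unname(x$lambda),
    penalty = unname(x$beta),
    active = unname(x$lambda != 0)
  )
}

#' One-row model summary of a fitted maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return One-row tibble: sample sizes, penalised log-likelihood, entropy,
#'   AUC and logistic threshold (when set), iterations, convergence flag.
#' @method glance maxent_model
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id,
    n_presence = x$n_presence,
    n_background = x$n_background,
    n_active_features = sum(x$lambda != 0),
    log_likelihood = x$log_likelihood,
    entropy = x$H,
    auc = x$auc,
    threshold_logistic = x$threshold_logistic,
    iterations = x$iterations,
    converged = x$converged
  )
}
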