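#' Tidy a shape model
#'
#' One row per principal component: singular value, variance explained and the
#' cumulative share of total centred variance.
#'
#' @param x a `shape_model`.
#' @param ... unused.
#' @return A tibble with columns `component`, `singular_value`, `variance`,
#'   `prop_variance`, `cum_variance`.
#' @export
tidy.shape_model <- function(x, ...) {
  var <- x$singular_values^2
  tibble::tibble(component = seq_along(x$singular_values),
                 singular_value = x$singular_values,
                 variance = var,
                 prop_variance = var / sum(var),
                 cum_variance = cumsum(var) / sum(var))
}

#' Glance at a shape model
#'
#' @param x a `shape_model`.
#' @param ... unused.
#' @return A one-row tibble: `n_train`, `n_comp`, `v_count`, `d`,
#'   `normalization`, `total_variance`.
#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(n_train = x$n_train, n_comp = nrow(x$components),
                 v_count = x$v_count, d = length(x$mean),
                 normalization = x$normalization,
                 total_variance = sum(x$singular_values^2))
}

#' Tidy a shape fit
#'
#' One row per optimized principal-component weight, in raw (unscaled) units.
#'
#' @param x a `pcawarp_fit`.
#' @param ... unused.
#' @return A tibble with columns `component`, `weight`.
#' @export
tidy.pcawarp_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$weights), weight = x$weights)
}

#' Glance at a shape fit
#'
#' @param x a `pcawarp_fit`.
#' @param ... unused.
#' @return A one-row tibble: `objective` (data term, mm), `penalty`,
#'   `median_residual`, `n_pcs`, `n_obj_evals`, `converged`.
#' @export
glance.pcawarp_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, penalty = x$penalty,
                 median_residual = median(x$residuals),
                 n_pcs = length(x$weights), n_obj_evals = x$n_obj_evals,
                 converged = x$converged)
}
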