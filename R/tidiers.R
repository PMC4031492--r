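#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted PLS model into a coefficient tibble
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with one row per predictor column: `term` (and `protein`,
#'   `time_h` when the model knows its labels) and `estimate` (the
#'   regression coefficient on the autoscaled scale).
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  out <- tibble::tibble(term = rownames(x$coefficients) %||%
                          paste0("x", seq_len(nrow(x$coefficients))),
                        estimate = as.numeric(x$coefficients))
  if (!is.null(x$col_info)) {
    out <- dplyr::bind_cols(x$col_info[c("protein", "time_h")], out)
  }
  out
}

#' @rdname tidy.pls_model
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_predictors = nrow(x$coefficients),
                 n_obs = x$n_obs)
}

#' Tidy a leave-one-out cross-validation result
#'
#' @param x A `pls_cv`.
#' @param ... Unused.
#' @return The per-condition prediction tibble (`measured`, `predicted`,
#'   `abs_pct_error`, plus condition labels when available).
#' @method tidy pls_cv
#' @export
tidy.pls_cv <- function(x, ...) x$predictions

#' @rdname tidy.pls_cv
#' @method glance pls_cv
#' @export
glance.pls_cv <- function(x, ...) {
  tibble::tibble(r2 = x$r2, n = x$n, ncomp = x$ncomp,
                 r2_method = x$r2_method, scaling_mode = x$scaling_mode)
}

#' Tidy a permutation-significance result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble of the randomized R-squared values (`replicate`, `r2`).
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$n_perm), r2 = x$r2_values)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(model_r2 = x$model_r2, mean_r2 = x$mean_r2, sd_r2 = x$sd_r2,
                 z = x$z, p_value = x$p_value, exceedance = x$exceedance,
                 n_perm = x$n_perm, r2_mode = x$r2_mode)
}

#' Tidy a coefficient summary
#'
#' @param x A `coef_summary`.
#' @param ... Unused.
#' @return The per-column coefficient tibble; the per-protein ranking is in
#'   `x$per_protein`.
#' @method tidy coef_summary
#' @export
tidy.coef_summary <- function(x, ...) x$per_column

#' @rdname tidy.coef_summary
#' @method glance coef_summary
#' @export
glance.coef_summary <- function(x, ...) {
  tibble::tibble(top_protein = x$ranking[[1]], n_proteins = length(x$ranking))
}

#' Tidy a response graph into its edge list
#'
#' @param x A `response_graph`.
#' @param ... Unused.
#' @return The edge tibble (`source`, `protein`, `weight`, `sign`).
#' @method tidy response_graph
#' @export
tidy.response_graph <- function(x, ...) x$edges

#' Tidy a cluster ordering
#'
#' @param x A `cluster_ordering`.
#' @param ... Unused.
#' @return Tibble of leaves in dendrogram order with their positions.
#' @method tidy cluster_ordering
#' @export
tidy.cluster_ordering <- function(x, ...) {
  tibble::tibble(position = seq_along(x$leaf_order), label = x$leaf_order)
}
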