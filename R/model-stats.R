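#' Randomization-based significance of a PLS model
#'
#' Builds a null distribution for the model R-squared by repeatedly
#' shuffling whole rows of the measurement matrix against the fixed
#' survival vector and refitting. The shuffle is of complete conditions —
#' never within columns — so the within-condition covariance structure of
#' the phosphoprotein data is preserved under the null. The observed
#' R-squared is expressed as a z-score against the null mean and SD, and a
#' one-tailed p-value is taken from the normal approximation to the null;
#' the empirical exceedance proportion is reported alongside as a
#' distribution-free cross-check.
#'
#' @param x Unscaled `design_matrix` or raw matrix.
#' @param y Raw response (ignored for a `design_matrix`).
#' @param ncomp Number of latent variables.
#' @param n_perm Number of randomized models (default 3000).
#' @param seed Integer seed for the permutation stream.
#' @param r2_mode `"cv"` (leave-one-out, default) or `"fit"` (training
#'   R-squared); applied identically to the observed model and every
#'   randomized replicate.
#' @param r2_method,scaling_mode,sd_type Passed through to the R-squared
#'   machinery.
#' @return An object of class `permutation_result` with the null
#'   `r2_values`, `mean_r2`, `sd_r2`, the observed `model_r2`, `z`,
#'   `p_value` (normal upper tail), and `exceedance` (empirical fraction of
#'   null values at or above the observed).
#' @export
permutation_significance <- function(x, y = NULL, ncomp = 3L, n_perm = 3000L,
                                     seed = 1L,
                                     r2_mode = c("cv", "fit"),
                                     r2_method = c("corr2", "one_minus_ss"),
                                     scaling_mode = c("per-fold", "global"),
                                     sd_type = c("sample", "population")) {
  r2_mode <- match.arg(r2_mode)
  r2_method <- match.arg(r2_method)
  scaling_mode <- match.arg(scaling_mode)
  sd_type <- match.arg(sd_type)
  if (inherits(x, "design_matrix")) {
    y <- x$Y; x <- x$X
  }
  X <- as.matrix(x); Y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4) stop_contract("permutation significance needs at least 4 rows")
  if (n_perm < 100) stop_contract("use at least 100 randomized models")
  if (stats::sd(Y) == 0) stop_contract("response has zero variance")

  one_r2 <- function(Xc) {
    if (r2_mode == "cv") {
      loocv(Xc, Y, ncomp = ncomp, scaling_mode = scaling_mode,
            r2_method = r2_method, sd_type = sd_type)$r2
    } else {
      fit_r2(Xc, Y, ncomp = ncomp, r2_method = r2_method, sd_type = sd_type)
    }
  }
  model_r2 <- one_r2(X)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(seed, "permutation"))
  r2_values <- vapply(seq_len(n_perm), function(b) {
    one_r2(X[sample.int(n), , drop = FALSE])
  }, numeric(1))
  mean_r2 <- mean(r2_values)
  sd_r2 <- stats::sd(r2_values)
  z <- (model_r2 - mean_r2) / sd_r2
  structure(list(n_perm = as.integer(n_perm), r2_values = r2_values,
                 mean_r2 = mean_r2, sd_r2 = sd_r2, model_r2 = model_r2,
                 z = z, p_value = stats::pnorm(z, lower.tail = FALSE),
                 exceedance = mean(r2_values >= model_r2),
                 seed = as.integer(seed), r2_mode = r2_mode,
                 r2_method = r2_method),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d randomized models (%s R^2)\n",
              x$n_perm, x$r2_mode))
  cat(sprintf("  model R^2 %.4f vs null %.4f +/- %.4f: z = %.2f, normal p = %.3g (empirical %.3g)\n",
              x$model_r2, x$mean_r2, x$sd_r2, x$z, x$p_value, x$exceedance))
  invisible(x)
}

# training (fit) R^2 under global autoscaling
fit_r2 <- function(X, Y, ncomp = 3L, r2_method = "corr2", sd_type = "sample") {
  X <- as.matrix(X); Y <- as.numeric(Y)
  xm <- colMeans(X); xs <- col_sds(X, sd_type); xs[xs == 0] <- 1
  ym <- mean(Y); ys <- vec_sd(Y, sd_type); if (ys == 0) ys <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Xs <- sweep(Xs, 2, colMeans(Xs))
  Ys <- (Y - ym) / ys; Ys <- Ys - mean(Ys)
  fit <- fit_simpls(Xs, Ys, ncomp = min(ncomp, nrow(X) - 1, ncol(X)))
  pred <- as.numeric(Xs %*% fit$coefficients) * ys + ym
  r_squared(Y, pred, r2_method)
}

#' Rank phosphoproteins by mean absolute regression coefficient
#'
#' Summarizes a fitted model's contribution per phosphoprotein: the absolute
#' value of the coefficient is taken for each of its time-point columns and
#' averaged, and proteins are ranked in descending order of that score (ties
#' broken by declared protein order).
#'
#' @param model A `pls_model` fit from a labeled `design_matrix`.
#' @return An object of class `coef_summary`: `per_column` (protein,
#'   time_h, coefficient), `per_protein` (protein, mean_abs_coef, rank),
#'   and `ranking` (character vector).
#' @export
mean_abs_coefficients <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(model$col_info))
    stop_contract("model has no column labels; fit it from a design_matrix")
  per_column <- dplyr::mutate(model$col_info,
                              coefficient = as.numeric(model$coefficients))
  protein_order <- unique(model$col_info$protein)
  per_protein <- per_column |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(mean_abs_coef = mean(abs(.data$coefficient)),
                     n_columns = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_coef),
                   match(.data$protein, protein_order)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(list(per_column = per_column, per_protein = per_protein,
                 ranking = per_protein$protein),
            class = "coef_summary")
}

#' @export
print.coef_summary <- function(x, ...) {
  cat("<coef_summary> proteins by mean |coefficient|:\n")
  print(x$per_protein)
  invisible(x)
}

#' R-squared of models built on increasing numbers of phosphoproteins
#'
#' Starting from the top-ranked protein, refits the model on the cumulative
#' union of each next protein's time-point columns and records the
#' R-squared, tracing how much each protein adds. The final step with all
#' proteins reproduces the full-model R-squared.
#'
#' @param x Unscaled `design_matrix`.
#' @param ranking Character vector of proteins in the order to add
#'   (typically from [mean_abs_coefficients()]).
#' @param ncomp Latent variables per step (capped at the available columns).
#' @param r2_mode `"cv"` (default) or `"fit"`.
#' @param r2_method,scaling_mode,sd_type Passed through.
#' @return A tibble of class `incremental_curve`: `protein`, `n_columns`,
#'   `r2` per step.
#' @export
incremental_r2 <- function(x, ranking, ncomp = 3L,
                           r2_mode = c("cv", "fit"),
                           r2_method = c("corr2", "one_minus_ss"),
                           scaling_mode = c("per-fold", "global"),
                           sd_type = c("sample", "population")) {
  r2_mode <- match.arg(r2_mode)
  r2_method <- match.arg(r2_method)
  scaling_mode <- match.arg(scaling_mode)
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(x, "design_matrix"), !isTRUE(x$scaled))
  if (length(ranking) == 0) stop_contract("ranking must name at least one protein")
  unknown <- setdiff(ranking, x$col_info$protein)
  if (length(unknown) > 0)
    stop_selection("ranking names unknown protein(s): %s", paste(unknown, collapse = ", "))
  steps <- purrr::map_dfr(seq_along(ranking), function(k) {
    cols <- which(x$col_info$protein %in% ranking[seq_len(k)])
    Xk <- x$X[, cols, drop = FALSE]
    nc <- min(ncomp, length(cols), nrow(Xk) - 2)
    r2 <- if (r2_mode == "cv") {
      loocv(Xk, x$Y, ncomp = nc, scaling_mode = scaling_mode,
            r2_method = r2_method, sd_type = sd_type)$r2
    } else {
      fit_r2(Xk, x$Y, ncomp = nc, r2_method = r2_method, sd_type = sd_type)
    }
    tibble::tibble(protein = ranking[[k]], n_columns = length(cols), r2 = r2)
  })
  class(steps) <- c("incremental_curve", class(steps))
  steps
}

#' Group cross-validation errors and compare groups
#'
#' Summarizes the absolute percent prediction error of a leave-one-out
#' result by treatment, cell line, or inhibitor, and runs two-sided Welch
#' two-sample comparisons between every pair of groups with at least two
#' conditions each. Pairwise p-values are reported unadjusted, with
#' Benjamini-Hochberg adjusted values alongside; with few groups the
#' unadjusted values are what small-study practice typically reports.
#'
#' @param cv A `pls_cv` whose predictions carry condition labels.
#' @param grouping One of `"treatment"`, `"cell_line"`, `"inhibitor"`.
#' @return A list of class `pred_error_summary`: `groups` (per-group n and
#'   mean absolute percent error) and `comparisons` (pairwise Welch tests).
#' @export
prediction_error_summary <- function(cv, grouping = c("treatment", "cell_line",
                                                      "inhibitor")) {
  stopifnot(inherits(cv, "pls_cv"))
  grouping <- match.arg(grouping)
  pred <- cv$predictions
  if (!grouping %in% names(pred))
    stop_contract("cross-validation result has no '%s' labels; run loocv() on a design_matrix",
                  grouping)
  pred$group <- as.character(pred[[grouping]])
  if (grouping == "inhibitor") pred$group[is.na(pred$group)] <- "none"
  groups <- pred |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_pct_error = mean(.data$abs_pct_error, na.rm = TRUE),
                     .groups = "drop")
  usable <- groups$group[groups$n >= 2]
  skipped <- setdiff(groups$group, usable)
  if (length(skipped) > 0)
    warn(sprintf("group(s) with < 2 conditions skipped in comparisons: %s",
                 paste(skipped, collapse = ", ")))
  comparisons <- NULL
  if (length(usable) >= 2) {
    pairs <- utils::combn(usable, 2)
    comparisons <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      g1 <- pred$abs_pct_error[pred$group == pairs[1, j]]
      g2 <- pred$abs_pct_error[pred$group == pairs[2, j]]
      p <- tryCatch(stats::t.test(g1, g2)$p.value, # Welch by default
                    error = function(e) NA_real_)  # e.g. zero-variance groups
      tibble::tibble(group_a = pairs[1, j], group_b = pairs[2, j],
                     mean_a = mean(g1, na.rm = TRUE), mean_b = mean(g2, na.rm = TRUE),
                     p_value = p)
    })
    comparisons$p_adj <- stats::p.adjust(comparisons$p_value, method = "BH")
  }
  structure(list(groups = groups, comparisons = comparisons, grouping = grouping),
            class = "pred_error_summary")
}

#' @export
print.pred_error_summary <- function(x, ...) {
  cat(sprintf("<pred_error_summary> by %s\n", x$grouping))
  print(x$groups)
  if (!is.null(x$comparisons)) {
    cat("pairwise Welch comparisons (p_adj = Benjamini-Hochberg):\n")
    print(x$comparisons)
  }
  invisible(x)
}
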