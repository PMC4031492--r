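#' Configure a full phosphoproteome-to-survival analysis
#'
#' Bundles every switch of the pipeline into one validated object. Defaults
#' follow standard practice for this kind of cue-signal-response model:
#' three latent variables, 3000 randomized models for significance, squared
#' Pearson correlation as the cross-validated R-squared convention,
#' per-fold autoscaling in leave-one-out loops, and a fixed-lambda Storey
#' q-value estimate at 0.5. Every setting in force is echoed into the
#' results manifest so reproduction attempts record their assumptions.
#'
#' @param data A [synthetic_spec()] to generate from, a
#'   [signaling_dataset()], or a path readable by [read_dataset()].
#' @param include_control Include untreated controls as regression rows?
#'   Default `FALSE`: the main model uses only the ligand treatments.
#' @param ncomp Latent variables (default 3).
#' @param r2_method `"corr2"` or `"one_minus_ss"`.
#' @param r2_mode Permutation/incremental R-squared mode: `"cv"` or
#'   `"fit"`.
#' @param scaling_mode `"per-fold"` or `"global"` for LOOCV.
#' @param sd_type SD convention for autoscaling.
#' @param n_perm Randomized models (default 3000).
#' @param seed Global seed expanded into per-stage substreams.
#' @param qvalue_lambda Storey lambda.
#' @param linkage Clustering linkage method.
#' @param output_dir Optional directory; when set, tables, graphs and the
#'   JSON manifest are written there.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(data = synthetic_spec(),
                            include_control = FALSE,
                            ncomp = 3L,
                            r2_method = c("corr2", "one_minus_ss"),
                            r2_mode = c("cv", "fit"),
                            scaling_mode = c("per-fold", "global"),
                            sd_type = c("sample", "population"),
                            n_perm = 3000L,
                            seed = 1L,
                            qvalue_lambda = 0.5,
                            linkage = c("average", "complete", "single"),
                            output_dir = NULL) {
  cfg <- list(data = data,
              include_control = isTRUE(include_control),
              ncomp = as.integer(ncomp),
              r2_method = match.arg(r2_method),
              r2_mode = match.arg(r2_mode),
              scaling_mode = match.arg(scaling_mode),
              sd_type = match.arg(sd_type),
              n_perm = as.integer(n_perm),
              seed = as.integer(seed),
              qvalue_lambda = qvalue_lambda,
              linkage = match.arg(linkage),
              output_dir = output_dir)
  if (cfg$ncomp < 1) stop_contract("ncomp must be at least 1")
  if (cfg$qvalue_lambda <= 0 || cfg$qvalue_lambda >= 1)
    stop_contract("qvalue_lambda must lie in (0, 1)")
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in setdiff(names(x), "data"))
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

resolve_dataset <- function(cfg) {
  d <- cfg$data
  if (inherits(d, "signaling_dataset")) return(d)
  if (inherits(d, "synthetic_spec"))
    return(generate_dataset(d, seed = stage_seed(cfg$seed, "dataset")))
  if (is.character(d) && length(d) == 1) return(read_dataset(d))
  stop_contract("config$data must be a synthetic_spec, signaling_dataset, or path")
}

#' Run the complete analysis pipeline
#'
#' Executes, deterministically for a given seed: design-matrix assembly for
#' the main multi-cell-line model, SIMPLS fit and leave-one-out
#' cross-validation, randomization significance, coefficient ranking and
#' the incremental-protein R-squared curve, per-cell-line models (training
#' fit R-squared, flagged as such — with ~6 conditions per line a
#' cross-validated value would be unstable), the single-cell-line model
#' including inhibitor combinations (cross-validated), prediction-error
#' grouping, per-cell-line correlation networks with Storey q-values,
#' ligand and inhibitor response graphs, and hierarchical orderings of the
#' z-scored measurement heatmap. A manifest of headline numbers and every
#' setting in force is attached (and written as JSON when `output_dir` is
#' set).
#'
#' @param config An [analysis_config()].
#' @return An object of class `analysis_result`; see `$manifest` for the
#'   headline numbers.
#' @export
run_full_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  dataset <- resolve_dataset(config)
  md <- dataset$metadata

  # --- main model: all cell lines, ligand treatments ---
  main <- select_rows(dataset, include_inhibitors = FALSE,
                      include_control = config$include_control)
  dm <- assemble_design_matrix(main)
  cv <- loocv(dm, ncomp = config$ncomp, scaling_mode = config$scaling_mode,
              r2_method = config$r2_method, sd_type = config$sd_type)
  dm_scaled <- autoscale(dm, sd_type = config$sd_type)
  model <- fit_simpls(dm_scaled, ncomp = config$ncomp)
  fitR2 <- fit_r2(dm$X, dm$Y, ncomp = config$ncomp,
                  r2_method = config$r2_method, sd_type = config$sd_type)
  coefs <- mean_abs_coefficients(model)
  curve <- incremental_r2(dm, coefs$ranking, ncomp = config$ncomp,
                          r2_mode = config$r2_mode, r2_method = config$r2_method,
                          scaling_mode = config$scaling_mode,
                          sd_type = config$sd_type)
  perm <- permutation_significance(dm, ncomp = config$ncomp,
                                   n_perm = config$n_perm,
                                   seed = stage_seed(config$seed, "permutation"),
                                   r2_mode = config$r2_mode,
                                   r2_method = config$r2_method,
                                   scaling_mode = config$scaling_mode,
                                   sd_type = config$sd_type)

  # --- per-cell-line models (training fit R^2; n is too small for CV) ---
  per_cell_line <- purrr::map_dfr(md$cell_lines, function(cl) {
    sub <- select_rows(dataset, cell_lines = cl, include_inhibitors = FALSE,
                       include_control = config$include_control)
    dmi <- assemble_design_matrix(sub)
    nc <- min(config$ncomp, nrow(dmi$X) - 1, ncol(dmi$X))
    tibble::tibble(cell_line = cl, n = nrow(dmi$X),
                   fit_r2 = fit_r2(dmi$X, dmi$Y, ncomp = nc,
                                   r2_method = config$r2_method,
                                   sd_type = config$sd_type),
                   r2_kind = "fit")
  })

  # --- designated-cell-line model including inhibitor combinations ---
  inhibitor_model <- NULL
  if (length(md$inhibitors) > 0 && !is.na(md$inhibitor_cell_line)) {
    sub <- select_rows(dataset, cell_lines = md$inhibitor_cell_line,
                       include_inhibitors = TRUE,
                       include_control = config$include_control)
    dmi <- assemble_design_matrix(sub)
    inhibitor_model <- loocv(dmi, ncomp = config$ncomp,
                             scaling_mode = config$scaling_mode,
                             r2_method = config$r2_method,
                             sd_type = config$sd_type)
  }

  # --- prediction-error grouping ---
  error_groups <- list(
    treatment = prediction_error_summary(cv, "treatment"),
    cell_line = prediction_error_summary(cv, "cell_line"))
  if (!is.null(inhibitor_model))
    error_groups$inhibitor <- prediction_error_summary(inhibitor_model, "inhibitor")

  # --- correlation networks, per cell line ---
  correlations <- purrr::map_dfr(md$cell_lines, function(cl) {
    annotate_significance(pairwise_correlations(dataset, cl),
                          lambda = config$qvalue_lambda)
  })

  # --- response graphs ---
  ligand_graphs <- stats::setNames(
    purrr::map(md$cell_lines, function(cl) build_response_graph(dataset, cl, "ligands")),
    md$cell_lines)
  inhibitor_graph <- NULL
  if (length(md$inhibitors) > 0 && !is.na(md$inhibitor_cell_line))
    inhibitor_graph <- build_response_graph(dataset, md$inhibitor_cell_line,
                                            "inhibitors")

  # --- heatmap clustering on the z-scored full matrix (all conditions) ---
  all_rows <- select_rows(dataset, include_inhibitors = length(md$inhibitors) > 0,
                          include_control = TRUE)
  dm_all <- assemble_design_matrix(all_rows)
  Z <- zscore_matrix(dm_all$X, sd_type = config$sd_type)
  clustering <- list(rows = hierarchical_order(Z, "rows", method = config$linkage),
                     columns = hierarchical_order(Z, "columns", method = config$linkage))

  settings <- unclass(config)[setdiff(names(config), c("data", "output_dir"))]
  manifest <- list(
    n_conditions_main = nrow(dm$X),
    n_columns = ncol(dm$X),
    loocv_r2 = cv$r2,
    fit_r2 = fitR2,
    perm_mean_r2 = perm$mean_r2,
    perm_sd_r2 = perm$sd_r2,
    perm_z = perm$z,
    perm_p_normal = perm$p_value,
    perm_exceedance = perm$exceedance,
    coefficient_ranking = coefs$ranking,
    top3_model_r2 = if (nrow(curve) >= 3) curve$r2[[3]] else NA_real_,
    incremental_r2 = stats::setNames(curve$r2, curve$protein),
    per_cell_line_fit_r2 = stats::setNames(per_cell_line$fit_r2,
                                           per_cell_line$cell_line),
    inhibitor_model_loocv_r2 = if (!is.null(inhibitor_model)) inhibitor_model$r2 else NA_real_,
    n_inhibitor_rows = if (!is.null(inhibitor_model)) inhibitor_model$n else 0L,
    min_q_per_cell_line = correlations |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::summarise(min_q = min(.data$q, na.rm = TRUE), .groups = "drop") |>
      (\(d) stats::setNames(d$min_q, d$cell_line))(),
    settings = settings)

  result <- structure(
    list(dataset = dataset, design_matrix = dm, cv = cv, model = model,
         coefficients = coefs, incremental = curve, permutation = perm,
         per_cell_line = per_cell_line, inhibitor_model = inhibitor_model,
         error_groups = error_groups, correlations = correlations,
         ligand_graphs = ligand_graphs, inhibitor_graph = inhibitor_graph,
         clustering = clustering, manifest = manifest, config = config),
    class = "analysis_result")

  if (!is.null(config$output_dir)) write_analysis_outputs(result, config$output_dir)
  result
}

#' @export
print.analysis_result <- function(x, ...) {
  m <- x$manifest
  cat("<analysis_result>\n")
  cat(sprintf("  main model: %d conditions x %d columns, %d component(s)\n",
              m$n_conditions_main, m$n_columns, x$model$n_components))
  cat(sprintf("  LOOCV R^2 (%s) = %.4f; fit R^2 = %.4f\n",
              x$cv$r2_method, m$loocv_r2, m$fit_r2))
  cat(sprintf("  randomized models: mean R^2 %.4f +/- %.4f -> z = %.2f, p = %.3g\n",
              m$perm_mean_r2, m$perm_sd_r2, m$perm_z, m$perm_p_normal))
  cat(sprintf("  coefficient ranking: %s\n",
              paste(utils::head(m$coefficient_ranking, 4), collapse = ", ")))
  if (!is.na(m$inhibitor_model_loocv_r2))
    cat(sprintf("  inhibitor-line model LOOCV R^2 = %.4f (%d conditions)\n",
                m$inhibitor_model_loocv_r2, m$n_inhibitor_rows))
  invisible(x)
}

# write CSV/JSON/GraphML outputs of a finished analysis
write_analysis_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(tidy(result$cv), file.path(dir, "cv_predictions.csv"))
  readr::write_csv(tidy(result$model), file.path(dir, "coefficients.csv"))
  readr::write_csv(result$coefficients$per_protein,
                   file.path(dir, "coefficient_ranking.csv"))
  readr::write_csv(tibble::as_tibble(result$incremental),
                   file.path(dir, "incremental_r2.csv"))
  readr::write_csv(result$correlations, file.path(dir, "correlations.csv"))
  jsonlite::write_json(glance(result$permutation),
                       file.path(dir, "permutation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (cl in names(result$ligand_graphs))
    export_graph(result$ligand_graphs[[cl]],
                 file.path(dir, sprintf("response_%s.graphml", cl)))
  if (!is.null(result$inhibitor_graph))
    export_graph(result$inhibitor_graph, file.path(dir, "response_inhibitors.graphml"))
  write_cluster_ordering(result$clustering$rows, file.path(dir, "cluster_rows.json"))
  write_cluster_ordering(result$clustering$columns, file.path(dir, "cluster_columns.json"))
  invisible(dir)
}
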