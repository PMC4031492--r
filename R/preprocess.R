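#' Percent change of a treated value over its untreated control
#'
#' `100 * (treated - control) / control`; the sign is preserved for
#' decreases, so a halving is -50%. This is the edge weight used by the
#' ligand-response graphs.
#'
#' @param treated,control Numeric vectors (recycled); `control` must be
#'   strictly positive.
#' @return Percent change, same length as the longer input.
#' @export
#' @examples
#' percent_change(33, 1)   # a 3200% activation spike
#' percent_change(0.5, 1)  # -50%
percent_change <- function(treated, control) {
  if (any(control <= 0))
    stop_contract("percent change is undefined for non-positive control values")
  100 * (treated - control) / control
}

#' Normalize raw viability readings to percent of control
#'
#' @param raw Numeric vector of raw MTT viability values.
#' @param control Mean viability of the untreated control (> 0).
#' @return `100 * raw / control`.
#' @export
normalize_survival <- function(raw, control) {
  if (length(control) != 1 || control <= 0)
    stop_contract("control viability must be a single positive value")
  100 * raw / control
}

#' Select the conditions entering a regression model
#'
#' Filters a dataset down to the rows a particular model uses: e.g. the main
#' three-cell-line model uses every ligand treatment but excludes untreated
#' controls and inhibitor combinations, while the single-cell-line inhibitor
#' model keeps all inhibitor-by-treatment combinations of one line.
#'
#' @param dataset A [signaling_dataset()].
#' @param cell_lines Cell lines to keep (default: all).
#' @param include_inhibitors Keep inhibitor-combination conditions?
#' @param include_control Keep the untreated control condition?
#' @param treatments Treatments to keep (default: all non-control).
#' @return A filtered [signaling_dataset()] (completeness preserved).
#' @export
select_rows <- function(dataset, cell_lines = NULL, include_inhibitors = FALSE,
                        include_control = FALSE, treatments = NULL) {
  stopifnot(inherits(dataset, "signaling_dataset"))
  md <- dataset$metadata
  cell_lines <- cell_lines %||% md$cell_lines
  unknown <- setdiff(cell_lines, md$cell_lines)
  if (length(unknown) > 0)
    stop_selection("unknown cell line(s): %s", paste(unknown, collapse = ", "))
  treatments <- treatments %||% md$treatments
  keep_tr <- treatments
  if (include_control) keep_tr <- c(md$control, keep_tr)

  keep <- function(df) {
    ok <- df$cell_line %in% cell_lines & df$treatment %in% keep_tr
    if (!include_inhibitors) ok <- ok & is.na(df$inhibitor)
    df[ok, , drop = FALSE]
  }
  survival <- keep(dataset$survival)
  if (nrow(survival) == 0) stop_selection("selection matched no conditions")
  phospho <- keep(dataset$phospho)
  md$cell_lines <- intersect(md$cell_lines, cell_lines)
  md$treatments <- intersect(md$treatments, treatments)
  if (!include_inhibitors) md$inhibitors <- character()
  out <- signaling_dataset(phospho, survival, metadata = md)
  attr(out, "ground_truth") <- attr(dataset, "ground_truth")
  out
}

#' Assemble the regression-ready design matrix
#'
#' Builds the conditions-by-(protein x time) matrix `X` and the survival
#' vector `Y` from a (typically pre-selected) dataset. Columns are ordered
#' protein-major with time ascending, matching the 8-proteins-by-3-times =
#' 24-column layout of the modeling approach; rows are ordered by declared
#' cell-line order, then treatment order, then inhibitor order (no-inhibitor
#' first), so assembly is deterministic and invariant to the order of the
#' input records.
#'
#' @param dataset A [signaling_dataset()] with complete blocks.
#' @return An unscaled `design_matrix`: list with `X`, `Y`, `row_info`,
#'   `col_info`, `scaling = NULL`, `scaled = FALSE`.
#' @export
assemble_design_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "signaling_dataset"))
  md <- dataset$metadata
  inhib_levels <- c(NA_character_, md$inhibitors)
  surv <- dataset$survival |>
    dplyr::arrange(match(.data$cell_line, md$cell_lines),
                   match(.data$treatment, c(md$control, md$treatments)),
                   match(.data$inhibitor, inhib_levels))
  col_info <- tibble::tibble(
    protein = rep(md$proteins, each = length(md$time_points)),
    time_h = rep(sort(md$time_points), length(md$proteins)))
  col_info$label <- paste(col_info$protein, col_info$time_h, sep = "_")

  ph <- dataset$phospho
  key <- paste(ph$cell_line, ph$treatment, ph$inhibitor, ph$protein, ph$time_h,
               sep = "\r")
  if (anyDuplicated(key) > 0)
    stop_schema("duplicated measurement rows in the dataset")
  lookup <- stats::setNames(ph$value, key)
  rows_key <- function(i) paste(surv$cell_line[[i]], surv$treatment[[i]],
                                surv$inhibitor[[i]], col_info$protein,
                                col_info$time_h, sep = "\r")
  X <- t(vapply(seq_len(nrow(surv)), function(i) {
    v <- lookup[rows_key(i)]
    if (anyNA(v))
      stop_schema("condition '%s / %s' is missing measurement cells",
                  surv$cell_line[[i]], surv$treatment[[i]])
    unname(v)
  }, numeric(nrow(col_info))))
  colnames(X) <- col_info$label
  rownames(X) <- paste(surv$cell_line, surv$treatment,
                       ifelse(is.na(surv$inhibitor), "", paste0("+", surv$inhibitor)),
                       sep = ".")
  structure(list(X = X, Y = surv$survival_pct,
                 row_info = surv[c("cell_line", "treatment", "inhibitor")],
                 col_info = col_info, scaling = NULL, scaled = FALSE),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d conditions x %d (protein, time) columns%s\n",
              nrow(x$X), ncol(x$X), if (x$scaled) ", autoscaled" else ""))
  invisible(x)
}

#' Autoscale a design matrix (mean-center, unit variance)
#'
#' Column-wise z-scoring of `X` and of the survival vector `Y`. The scaling
#' parameters are stored on the result so they can be applied to held-out
#' rows (cross-validation) and inverted to return predictions to survival
#' units. Zero-variance columns are centered but divided by 1 instead of 0,
#' with a message, so degenerate inputs do not propagate NaN.
#'
#' @param dm A `design_matrix` from [assemble_design_matrix()].
#' @param sd_type `"sample"` (n-1 divisor, default) or `"population"`.
#' @return The scaled `design_matrix` with `scaling` filled in.
#' @export
autoscale <- function(dm, sd_type = c("sample", "population")) {
  stopifnot(inherits(dm, "design_matrix"))
  sd_type <- match.arg(sd_type)
  if (nrow(dm$X) < 2) stop_contract("autoscaling needs at least 2 rows")
  x_mean <- colMeans(dm$X)
  x_sd <- col_sds(dm$X, sd_type)
  zero_var <- x_sd == 0
  if (any(zero_var)) {
    inform(sprintf("autoscale: %d zero-variance column(s) centered only: %s",
                   sum(zero_var),
                   paste(colnames(dm$X)[zero_var], collapse = ", ")))
    x_sd[zero_var] <- 1
  }
  y_mean <- mean(dm$Y)
  y_sd <- vec_sd(dm$Y, sd_type)
  if (y_sd == 0) {
    inform("autoscale: zero-variance response centered only")
    y_sd <- 1
  }
  scaling <- list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                  sd_type = sd_type, zero_var = zero_var)
  dm$X <- apply_scaling_x(dm$X, scaling)
  dm$Y <- (dm$Y - y_mean) / y_sd
  dm$scaling <- scaling
  dm$scaled <- TRUE
  dm
}

# apply stored column scaling to (possibly held-out) raw rows
apply_scaling_x <- function(X, scaling) {
  sweep(sweep(X, 2, scaling$x_mean), 2, scaling$x_sd, "/")
}

#' Invert autoscaling
#'
#' @param dm A scaled `design_matrix`.
#' @return The `design_matrix` on the original measurement/survival scale.
#' @export
unscale <- function(dm) {
  stopifnot(inherits(dm, "design_matrix"), isTRUE(dm$scaled))
  s <- dm$scaling
  dm$X <- sweep(sweep(dm$X, 2, s$x_sd, "*"), 2, s$x_mean, "+")
  dm$Y <- dm$Y * s$y_sd + s$y_mean
  dm$scaling <- NULL
  dm$scaled <- FALSE
  dm
}

#' Export a design matrix as plain CSV tables
#'
#' Writes `X.csv` (with row labels), `Y.csv` and `columns.csv` under `path`
#' for inspection or cross-implementation comparison.
#'
#' @param dm A `design_matrix`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "design_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xdf <- dplyr::bind_cols(dm$row_info, tibble::as_tibble(dm$X))
  readr::write_csv(xdf, file.path(path, "X.csv"))
  readr::write_csv(dplyr::bind_cols(dm$row_info,
                                    tibble::tibble(survival_pct = dm$Y)),
                   file.path(path, "Y.csv"))
  readr::write_csv(dm$col_info, file.path(path, "columns.csv"))
  invisible(path)
}
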