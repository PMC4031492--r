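#' Construct and validate a signaling dataset
#'
#' The long-form container of a cue-signal-response study: one table of
#' phosphoprotein measurements (ng per 20 ug total protein lysate) and one
#' table of relative survival per experimental condition, where a condition
#' is a (cell line, treatment, inhibitor) triple and the inhibitor is `NA`
#' for plain ligand/control conditions.
#'
#' Validation enforces the completeness invariant the regression requires:
#' every condition present in the survival table has a full protein-by-time
#' block of measurements, and vice versa.
#'
#' @param phospho Data frame with columns `cell_line`, `treatment`,
#'   `inhibitor`, `protein`, `time_h`, `value` and optionally `rep1`, `rep2`
#'   (raw duplicates; when present, `value` is expected to be their mean).
#' @param survival Data frame with columns `cell_line`, `treatment`,
#'   `inhibitor`, `survival_pct`.
#' @param metadata Optional list with `cell_lines`, `treatments`, `control`,
#'   `inhibitors`, `inhibitor_cell_line`, `proteins`, `time_points`; derived
#'   from the tables when omitted.
#' @return An object of class `signaling_dataset`.
#' @export
signaling_dataset <- function(phospho, survival, metadata = NULL) {
  phospho <- tibble::as_tibble(phospho)
  survival <- tibble::as_tibble(survival)
  need_p <- c("cell_line", "treatment", "inhibitor", "protein", "time_h", "value")
  need_s <- c("cell_line", "treatment", "inhibitor", "survival_pct")
  miss <- setdiff(need_p, names(phospho))
  if (length(miss) > 0)
    stop_schema("phospho table is missing column(s): %s", paste(miss, collapse = ", "))
  miss <- setdiff(need_s, names(survival))
  if (length(miss) > 0)
    stop_schema("survival table is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(phospho$value < 0, na.rm = TRUE))
    stop_schema("phosphoprotein values must be non-negative")
  if (any(survival$survival_pct < 0, na.rm = TRUE))
    stop_schema("survival percentages must be non-negative")

  if (is.null(metadata)) {
    controls <- unique(survival$treatment[abs(survival$survival_pct - 100) < 1e-9])
    metadata <- list(
      cell_lines = unique(phospho$cell_line),
      treatments = setdiff(unique(phospho$treatment), "control"),
      control = if ("control" %in% phospho$treatment) "control" else controls[1] %||% NA_character_,
      inhibitors = setdiff(unique(phospho$inhibitor[!is.na(phospho$inhibitor)]), character()),
      inhibitor_cell_line = unique(phospho$cell_line[!is.na(phospho$inhibitor)])[1] %||% NA_character_,
      proteins = unique(phospho$protein),
      time_points = sort(unique(phospho$time_h)))
  }

  bad_time <- setdiff(unique(phospho$time_h), metadata$time_points)
  if (length(bad_time) > 0)
    stop_schema("unknown time point(s): %s", paste(bad_time, collapse = ", "))

  block_size <- length(metadata$proteins) * length(metadata$time_points)
  counts <- phospho |>
    dplyr::count(.data$cell_line, .data$treatment, .data$inhibitor)
  key <- function(df) paste(df$cell_line, df$treatment, df$inhibitor, sep = "\r")
  surv_keys <- key(survival)
  meas_keys <- key(counts)
  if (anyDuplicated(surv_keys) > 0)
    stop_schema("duplicated condition(s) in the survival table")
  only_surv <- setdiff(surv_keys, meas_keys)
  if (length(only_surv) > 0)
    stop_schema("condition '%s' has survival but no measurements",
                gsub("\r", " / ", only_surv[[1]]))
  only_meas <- setdiff(meas_keys, surv_keys)
  if (length(only_meas) > 0)
    stop_schema("condition '%s' has measurements but no survival",
                gsub("\r", " / ", only_meas[[1]]))
  short <- counts[counts$n != block_size, , drop = FALSE]
  if (nrow(short) > 0)
    stop_schema("condition '%s / %s' has %d measurements, expected a complete %d-cell block",
                short$cell_line[[1]], short$treatment[[1]], short$n[[1]], block_size)

  structure(list(phospho = phospho, survival = survival, metadata = metadata),
            class = "signaling_dataset")
}

#' @export
print.signaling_dataset <- function(x, ...) {
  cat("<signaling_dataset>\n")
  cat(sprintf("  %d conditions (%d cell lines), %d proteins x %d time points\n",
              nrow(x$survival), length(x$metadata$cell_lines),
              length(x$metadata$proteins), length(x$metadata$time_points)))
  cat(sprintf("  %d measurement rows, %d survival rows\n",
              nrow(x$phospho), nrow(x$survival)))
  invisible(x)
}

#' @rdname signaling_dataset
#' @param x A `signaling_dataset`.
#' @param ... Unused.
#' @method tidy signaling_dataset
#' @export
tidy.signaling_dataset <- function(x, ...) x$phospho

#' Write a signaling dataset to a directory of tidy text files
#'
#' Serializes losslessly to `phospho.csv`, `survival.csv` and
#' `metadata.json` under `path`; [read_dataset()] inverts the operation
#' exactly. Column order is fixed so repeated writes are byte-stable.
#'
#' @param dataset A [signaling_dataset()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "signaling_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cols <- intersect(c("cell_line", "treatment", "inhibitor", "protein",
                      "time_h", "value", "rep1", "rep2"), names(dataset$phospho))
  readr::write_csv(dataset$phospho[cols], file.path(path, "phospho.csv"))
  readr::write_csv(dataset$survival[c("cell_line", "treatment", "inhibitor", "survival_pct")],
                   file.path(path, "survival.csv"))
  jsonlite::write_json(dataset$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a signaling dataset written by [write_dataset()]
#'
#' @param path Directory containing `phospho.csv`, `survival.csv` and
#'   optionally `metadata.json`.
#' @return A validated [signaling_dataset()].
#' @export
read_dataset <- function(path) {
  pfile <- file.path(path, "phospho.csv")
  sfile <- file.path(path, "survival.csv")
  if (!file.exists(pfile))
    stop_schema("no phosphoprotein table at %s", pfile)
  if (!file.exists(sfile))
    stop_schema("dataset at %s is missing its survival block (survival.csv)", path)
  coltypes_p <- readr::cols(cell_line = "c", treatment = "c", inhibitor = "c",
                            protein = "c", time_h = "d", value = "d",
                            .default = "d")
  phospho <- readr::read_csv(pfile, col_types = coltypes_p, progress = FALSE)
  survival <- readr::read_csv(sfile,
                              col_types = readr::cols(cell_line = "c", treatment = "c",
                                                      inhibitor = "c", survival_pct = "d"),
                              progress = FALSE)
  mfile <- file.path(path, "metadata.json")
  metadata <- NULL
  if (file.exists(mfile)) {
    metadata <- jsonlite::read_json(mfile, simplifyVector = TRUE)
    metadata$time_points <- as.numeric(metadata$time_points)
  }
  signaling_dataset(phospho, survival, metadata = metadata)
}

#' Convert a wide per-condition layout to the tidy long schema
#'
#' Supplementary tables in this field are often laid out with one column per
#' experimental condition. Given a declarative mapping from column name to
#' (cell line, treatment, inhibitor), this reshapes such a table into the
#' long `phospho` schema used throughout the package.
#'
#' @param wide Data frame with columns `protein`, `time_h`, plus one numeric
#'   column per condition.
#' @param mapping Data frame with columns `column`, `cell_line`, `treatment`,
#'   `inhibitor` describing each condition column.
#' @return A tibble in the long phospho schema.
#' @export
wide_to_long <- function(wide, mapping) {
  need <- setdiff(c("column", "cell_line", "treatment", "inhibitor"), names(mapping))
  if (length(need) > 0)
    stop_schema("mapping is missing column(s): %s", paste(need, collapse = ", "))
  missing_cols <- setdiff(mapping$column, names(wide))
  if (length(missing_cols) > 0)
    stop_schema("wide table lacks mapped column(s): %s",
                paste(missing_cols, collapse = ", "))
  wide |>
    tidyr::pivot_longer(dplyr::all_of(mapping$column),
                        names_to = "column", values_to = "value") |>
    dplyr::inner_join(tibble::as_tibble(mapping), by = "column") |>
    dplyr::select("cell_line", "treatment", "inhibitor", "protein", "time_h", "value")
}

#' Fit an eight-point ELISA standard curve
#'
#' Least-squares fit of a second-order polynomial
#' `absorbance = a * concentration^2 + b * concentration + d` to standard
#' points, as used to calibrate sandwich-ELISA absorbance readings to
#' ng per 20 ug lysate. A fitted curve that is not monotone over the
#' standard's concentration range cannot be inverted uniquely and is
#' rejected.
#'
#' @param points Data frame with columns `concentration` and `absorbance`
#'   (typically 8 rows).
#' @return An object of class `standard_curve` with elements `coeffs`
#'   (named `a`, `b`, `d`), `points`, `valid_range`, and `rss` (residual sum
#'   of squares).
#' @export
fit_standard_curve <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("concentration", "absorbance") %in% names(points)))
  if (length(unique(points$concentration)) < 3)
    stop_calibration("need at least 3 distinct concentrations to fit a quadratic")
  fit <- stats::lm(absorbance ~ concentration + I(concentration^2), data = points)
  cf <- stats::coef(fit)
  coeffs <- c(a = unname(cf[["I(concentration^2)"]]),
              b = unname(cf[["concentration"]]),
              d = unname(cf[["(Intercept)"]]))
  if (anyNA(coeffs)) stop_calibration("standard-curve fit is rank deficient")
  rng <- range(points$concentration)
  # derivative 2ac + b must not change sign on [rng] (endpoint zeros allowed)
  dlo <- 2 * coeffs[["a"]] * rng[[1]] + coeffs[["b"]]
  dhi <- 2 * coeffs[["a"]] * rng[[2]] + coeffs[["b"]]
  dtol <- 1e-9 * max(abs(dlo), abs(dhi), 1)
  if ((dlo < -dtol && dhi > dtol) || (dlo > dtol && dhi < -dtol) ||
      (abs(dlo) <= dtol && abs(dhi) <= dtol))
    stop_calibration("fitted standard curve is not monotone over [%g, %g]",
                     rng[[1]], rng[[2]])
  structure(list(coeffs = coeffs, points = points, valid_range = rng,
                 rss = sum(stats::residuals(fit)^2)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> absorbance = %.4g c^2 + %.4g c + %.4g on [%g, %g], RSS %.3g\n",
              x$coeffs[["a"]], x$coeffs[["b"]], x$coeffs[["d"]],
              x$valid_range[[1]], x$valid_range[[2]], x$rss))
  invisible(x)
}

# forward evaluation of a fitted curve
eval_standard_curve <- function(curve, concentration) {
  cf <- curve$coeffs
  cf[["a"]] * concentration^2 + cf[["b"]] * concentration + cf[["d"]]
}

#' Invert a standard curve: absorbance to concentration
#'
#' Solves the fitted quadratic for concentration, returning the unique root
#' inside the curve's valid concentration range (uniqueness is guaranteed by
#' the monotonicity invariant of [fit_standard_curve()]).
#'
#' @param absorbance Numeric vector of measured absorbances.
#' @param curve A `standard_curve`.
#' @param clamp If `TRUE`, absorbances outside the achievable range are
#'   clamped to the range endpoint instead of raising an error.
#' @param tol Relative tolerance on the achievable absorbance range.
#' @return Concentrations in ng per 20 ug lysate.
#' @export
invert_standard_curve <- function(absorbance, curve, clamp = FALSE, tol = 1e-8) {
  stopifnot(inherits(curve, "standard_curve"))
  rng <- curve$valid_range
  ends <- eval_standard_curve(curve, rng)
  alo <- min(ends); ahi <- max(ends)
  span <- max(ahi - alo, .Machine$double.eps)
  out <- absorbance < alo - tol * span | absorbance > ahi + tol * span
  if (any(out)) {
    if (!clamp)
      stop_calibration("absorbance %.4g outside achievable range [%.4g, %.4g]",
                       absorbance[out][[1]], alo, ahi)
    absorbance <- pmin(pmax(absorbance, alo), ahi)
  } else {
    absorbance <- pmin(pmax(absorbance, alo), ahi)
  }
  a <- curve$coeffs[["a"]]
  b <- curve$coeffs[["b"]]
  d <- curve$coeffs[["d"]]
  vapply(absorbance, function(y) {
    if (abs(a) < 1e-14) return((y - d) / b)
    disc <- b^2 - 4 * a * (d - y)
    disc <- max(disc, 0)
    roots <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    inside <- roots[roots >= rng[[1]] - 1e-9 & roots <= rng[[2]] + 1e-9]
    if (length(inside) == 0) {
      # numerically just outside: take the nearest root clamped to the range
      inside <- roots[which.min(pmin(abs(roots - rng[[1]]), abs(roots - rng[[2]])))]
      inside <- pmin(pmax(inside, rng[[1]]), rng[[2]])
    }
    inside[[1]]
  }, numeric(1))
}
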