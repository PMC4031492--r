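#' Specify a synthetic phosphoprotein/survival study
#'
#' Describes the design and generative parameters of a synthetic signaling
#' dataset: which cell lines, ligand treatments, inhibitors, phosphoproteins
#' and time points are measured, and the statistical structure tying scaled
#' phosphoprotein levels to relative cell survival through a known linear map.
#'
#' The defaults emulate a three-cell-line prostate cancer signaling study:
#' an untreated control plus six ligand/drug treatments per cell line, five
#' kinase inhibitors combined with each ligand treatment on one designated
#' cell line, eight phosphoproteins, and lysate collection at 0.5, 4 and
#' 24 hours. Biological duplicates differ by about 20% in mean absolute
#' relative terms, matching typical phospho-ELISA replicate error.
#'
#' Measurements are generated as
#' `baseline * max(1 + latent factors %*% loadings, rel_floor)` times
#' log-normal measurement noise, which keeps concentrations strictly
#' positive while the centered measurement matrix stays low-rank
#' (`latent_rank` dimensions). The latent factors are signaling *modules*:
#' each protein is assigned round-robin to one module with a deterministic
#' within-module loading (the first protein of a module is its flagship,
#' loading 1), each module has its own time-course profile (early-, late-
#' or mid-peaking), cell lines differ by fixed shifts of their module
#' activities (so between-line differences stay inside the factor space),
#' and each inhibitor suppresses the activity of its target module.
#' Survival for treated conditions is
#' `100 * (1 + scaled_X %*% true_beta + noise)`, clipped below at a small
#' positive floor; untreated controls are defined as 100%.
#'
#' @param cell_lines Character vector of cell-line labels.
#' @param treatments Character vector of ligand/drug treatment labels.
#' @param control Label used for the untreated control condition.
#' @param inhibitors Character vector of inhibitor labels (may be empty);
#'   each inhibitor is combined with every treatment on `inhibitor_cell_line`.
#' @param inhibitor_cell_line Cell line receiving the inhibitor combinations.
#' @param proteins Character vector of phosphoprotein labels.
#' @param time_points Numeric vector of collection times in hours.
#' @param latent_rank Number of latent signaling modules generating the
#'   measurement matrix; 3 matches the number of latent variables used
#'   downstream, so at the defaults the planted map is fully representable
#'   by the three-component model.
#' @param true_beta Named or unnamed numeric vector of regression
#'   coefficients on the scaled-X scale, one per (protein, time) column in
#'   protein-major, time-ascending order. The default plants signal on three
#'   proteins (0.12, 0.05, -0.035 per time column) so one protein clearly
#'   dominates the coefficient ranking and survival spans a realistic range
#'   (SD about 30% of control).
#' @param noise_sd_x Log-scale SD of condition-level measurement noise.
#' @param noise_sd_y SD of additive noise on the scaled survival signal.
#' @param replicate_cv Target mean absolute relative difference between
#'   biological duplicates (fraction; 0.204 emulates a 20.4% replicate error).
#' @param baseline Matrix of positive baseline concentrations
#'   (ng per 20 ug lysate), cell lines in rows, proteins in columns. The
#'   default spans roughly 0.2-5 ng with per-cell-line multiplicative offsets.
#' @param effect_sd SD of the relative treatment effect carried by the
#'   latent factors (0.45 means typical responses of a few tens of percent
#'   over untreated control; occasional near-complete suppression is
#'   clipped at `rel_floor`).
#' @param rel_floor Lower clip for the relative effect `1 + F L`, keeping
#'   condition means strictly positive.
#' @param cell_shift Scale of the fixed per-cell-line shifts of module
#'   activity; 2.5 makes between-line separation dominate within-line
#'   treatment variation, as heatmap clustering of real multi-line panels
#'   shows.
#' @param survival_floor Lower clip for generated survival, in percent.
#' @param seed Default integer seed used when `generate_dataset()` is called
#'   without one.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [true_parameters()]
#' @export
#' @examples
#' spec <- synthetic_spec()
#' spec$proteins
synthetic_spec <- function(cell_lines = c("line1", "line2", "line3"),
                           treatments = c("EGF", "IGF1", "IL6", "TNFa",
                                          "DHT", "docetaxel"),
                           control = "control",
                           inhibitors = c("LY294002", "U0126", "wedelolactone",
                                          "temsirolimus", "SB202190"),
                           inhibitor_cell_line = cell_lines[[1]],
                           proteins = c("Erk", "RPS6", "JNK", "Stat3",
                                        "Akt", "p38", "HSP27", "GSK3"),
                           time_points = c(0.5, 4, 24),
                           latent_rank = 3L,
                           true_beta = NULL,
                           noise_sd_x = 0.1,
                           noise_sd_y = 0.05,
                           replicate_cv = 0.204,
                           baseline = NULL,
                           effect_sd = 0.45,
                           rel_floor = 0.02,
                           cell_shift = 2.5,
                           survival_floor = 1,
                           seed = 1L) {
  n_cols <- length(proteins) * length(time_points)
  if (!is.null(true_beta) && length(true_beta) != n_cols)
    stop_contract("true_beta has length %d but the design has %d (protein, time) columns",
                  length(true_beta), n_cols)
  if (is.null(true_beta)) {
    beta_per_protein <- c(0.12, 0.05, -0.035, rep(0, max(0, length(proteins) - 3)))
    beta_per_protein <- beta_per_protein[seq_along(proteins)]
    true_beta <- rep(beta_per_protein, each = length(time_points))
  }
  names(true_beta) <- paste(rep(proteins, each = length(time_points)),
                            rep(time_points, length(proteins)), sep = "_")
  if (is.null(baseline)) {
    # same basal concentrations for every line; between-line differences
    # arise through shifted module activities, inside the latent space
    protein_base <- exp(seq(log(0.3), log(5), length.out = length(proteins)))
    baseline <- matrix(protein_base, nrow = length(cell_lines),
                       ncol = length(proteins), byrow = TRUE)
    dimnames(baseline) <- list(cell_lines, proteins)
  }
  spec <- structure(
    list(cell_lines = cell_lines, treatments = treatments, control = control,
         inhibitors = inhibitors, inhibitor_cell_line = inhibitor_cell_line,
         proteins = proteins, time_points = sort(time_points),
         latent_rank = as.integer(latent_rank), true_beta = true_beta,
         noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
         replicate_cv = replicate_cv, baseline = baseline,
         effect_sd = effect_sd, rel_floor = rel_floor,
         cell_shift = cell_shift, survival_floor = survival_floor,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (length(spec$proteins) == 0 || length(spec$time_points) == 0)
    stop_contract("synthetic spec is degenerate: proteins and time points must be non-empty")
  if (length(spec$cell_lines) == 0 || length(spec$treatments) == 0)
    stop_contract("synthetic spec is degenerate: cell lines and treatments must be non-empty")
  n_cols <- length(spec$proteins) * length(spec$time_points)
  if (length(spec$true_beta) != n_cols)
    stop_contract("true_beta has length %d but the design has %d (protein, time) columns",
                  length(spec$true_beta), n_cols)
  if (any(spec$baseline <= 0)) stop_contract("all baseline concentrations must be positive")
  if (spec$replicate_cv < 0) stop_contract("replicate_cv must be non-negative")
  if (spec$latent_rank < 1) stop_contract("latent_rank must be at least 1")
  if (spec$survival_floor <= 0) stop_contract("survival_floor must be positive")
  if (spec$rel_floor <= 0) stop_contract("rel_floor must be positive")
  if (length(spec$inhibitors) > 0 &&
      !spec$inhibitor_cell_line %in% spec$cell_lines)
    stop_contract("inhibitor_cell_line '%s' is not among the cell lines",
                  spec$inhibitor_cell_line)
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat(sprintf("  %d cell lines x (control + %d treatments); %d inhibitors on %s\n",
              length(x$cell_lines), length(x$treatments), length(x$inhibitors),
              x$inhibitor_cell_line))
  cat(sprintf("  %d proteins x %d time points (%s h); latent rank %d\n",
              length(x$proteins), length(x$time_points),
              paste(x$time_points, collapse = ", "), x$latent_rank))
  cat(sprintf("  replicate_cv %.3f, noise_sd_x %.2f, noise_sd_y %.2f\n",
              x$replicate_cv, x$noise_sd_x, x$noise_sd_y))
  invisible(x)
}

#' Deterministic module structure of a synthetic spec
#'
#' Describes how the latent signaling modules load on the (protein, time)
#' columns: proteins are assigned round-robin to the `latent_rank` modules,
#' the first protein of each module is its flagship (loading 1, subsequent
#' members 0.6, 0.45, 0.35, ...), and each module follows one of three
#' canonical time-course shapes (early-, late-, or mid-peaking), cycled
#' when there are more modules than shapes.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `module` (module index per protein), `member_loading`
#'   (per protein), `time_profile` (module x time matrix), and `loadings`
#'   (the full `latent_rank` x (protein x time) loading matrix, including
#'   the `effect_sd` scale).
#' @export
module_structure <- function(spec) {
  k <- spec$latent_rank
  P <- length(spec$proteins)
  Tn <- length(spec$time_points)
  module <- ((seq_len(P) - 1L) %% k) + 1L
  within_pos <- stats::ave(seq_len(P), module, FUN = seq_along)
  member_weights <- c(1, 0.6, 0.45, 0.35, 0.3, 0.25)
  member_loading <- member_weights[pmin(within_pos, length(member_weights))]
  shape <- function(kind) {
    if (Tn == 1) return(1)
    switch(kind,
           early = seq(1, 0.3, length.out = Tn),
           late = seq(0.3, 1, length.out = Tn),
           mid = 1 - 0.5 * abs(seq(-1, 1, length.out = Tn)))
  }
  kinds <- rep(c("early", "late", "mid"), length.out = k)
  time_profile <- do.call(rbind, lapply(kinds, shape))
  loadings <- matrix(0, k, P * Tn)
  for (p in seq_len(P)) {
    f <- module[[p]]
    cols <- (p - 1L) * Tn + seq_len(Tn)
    loadings[f, cols] <- member_loading[[p]] * time_profile[f, ] * spec$effect_sd
  }
  list(module = stats::setNames(module, spec$proteins),
       member_loading = stats::setNames(member_loading, spec$proteins),
       time_profile = time_profile, loadings = loadings)
}

# fixed per-cell-line shifts of module activity (kept inside the latent
# space so the centered measurement matrix stays rank latent_rank); the
# 1.5 scale makes between-line separation dominate within-line treatment
# variation, the grouping hierarchical clustering is expected to find
cell_line_shifts <- function(spec) {
  nl <- length(spec$cell_lines)
  k <- spec$latent_rank
  spec$cell_shift * outer(seq_len(nl), seq_len(k), function(l, f) cos(l * f))
}

# all experimental conditions implied by a spec, in deterministic order
spec_conditions <- function(spec) {
  base <- tidyr::expand_grid(cell_line = spec$cell_lines,
                             treatment = c(spec$control, spec$treatments),
                             inhibitor = NA_character_)
  if (length(spec$inhibitors) > 0) {
    inhib <- tidyr::expand_grid(cell_line = spec$inhibitor_cell_line,
                                treatment = spec$treatments,
                                inhibitor = spec$inhibitors)
    base <- dplyr::bind_rows(base, inhib)
  }
  base
}

#' Generate a synthetic signaling dataset with known ground truth
#'
#' Draws a complete phosphoprotein/survival dataset from the generative model
#' described in [synthetic_spec()]. Every downstream stage of the pipeline
#' (design-matrix assembly, SIMPLS regression, cross-validation, coefficient
#' ranking) can be validated against the planted coefficients because
#' survival is an exact linear function of the scaled measurement values plus
#' known noise.
#'
#' Duplicate measurements are two log-normal draws around the condition mean
#' whose log-scale SD is calibrated through the half-normal relation
#' `E|d1 - d2| / mean = 2 * sigma / sqrt(pi)` so that the mean absolute
#' relative difference between duplicates converges to `replicate_cv`.
#' The stored `value` is the duplicate mean, and the survival signal is
#' computed from these stored values, so the planted linear map holds exactly
#' for the data a user sees.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. Fixing the seed fixes
#'   the dataset bit-for-bit.
#' @return A [signaling_dataset()] carrying a `ground_truth` attribute:
#'   a list with the planted `true_beta`, the per-condition scaled signal,
#'   `noise_sd_y`, and which survival values were clipped at the floor.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(), seed = 7)
#' ds
generate_dataset <- function(spec, seed = spec$seed) {
  validate_synthetic_spec(spec)
  conditions <- spec_conditions(spec)
  n_cond <- nrow(conditions)
  P <- length(spec$proteins)
  Tn <- length(spec$time_points)
  n_cols <- P * Tn

  withr_seed <- stage_seed(seed, "synthesis")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  # latent module activities: controls carry no treatment effect
  is_control <- conditions$treatment == spec$control & is.na(conditions$inhibitor)
  ms <- module_structure(spec)
  shifts <- cell_line_shifts(spec)
  Fmat <- matrix(stats::rnorm(n_cond * spec$latent_rank), n_cond, spec$latent_rank)
  Fmat <- Fmat + shifts[match(conditions$cell_line, spec$cell_lines), , drop = FALSE]
  inh_idx <- which(!is.na(conditions$inhibitor))
  if (length(inh_idx) > 0) {
    target <- (match(conditions$inhibitor[inh_idx], spec$inhibitors) - 1L) %%
      spec$latent_rank + 1L
    Fmat[cbind(inh_idx, target)] <- Fmat[cbind(inh_idx, target)] - 1.5
  }
  Fmat[is_control, ] <- 0
  effect <- Fmat %*% ms$loadings # relative effect over baseline

  base_vals <- spec$baseline[conditions$cell_line, , drop = FALSE]
  base_vals <- base_vals[, rep(seq_len(P), each = Tn), drop = FALSE]
  n_rel_clipped <- sum(1 + effect < spec$rel_floor)
  rel <- pmax(1 + effect, spec$rel_floor)
  noise_mult <- if (spec$noise_sd_x == 0) 1 else
    exp(matrix(stats::rnorm(n_cond * n_cols, sd = spec$noise_sd_x), n_cond, n_cols) -
          spec$noise_sd_x^2 / 2)
  M <- base_vals * rel * noise_mult # condition means, strictly positive

  # duplicates: log-normal around the condition mean; half-normal calibration
  sigma_rep <- spec$replicate_cv * sqrt(pi) / 2
  draw_rep <- function() {
    if (sigma_rep == 0) return(M)
    M * exp(matrix(stats::rnorm(n_cond * n_cols, sd = sigma_rep), n_cond, n_cols) -
              sigma_rep^2 / 2)
  }
  rep1 <- draw_rep()
  rep2 <- draw_rep()
  V <- (rep1 + rep2) / 2 # the stored measurement values

  # survival from the *stored* values so the linear map is exact
  treated <- !is_control
  Vs <- V[treated, , drop = FALSE]
  mu <- colMeans(Vs)
  sds <- col_sds(Vs, "sample")
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(Vs, 2, mu), 2, sds, "/")
  signal <- as.numeric(Xs %*% spec$true_beta)
  # the part of the signal carried by the low-rank condition-level structure
  # (pre-noise, pre-replicate), on the same scaling as the observed values
  Ms <- (base_vals * rel)[treated, , drop = FALSE]
  signal_struct <- as.numeric(sweep(sweep(Ms, 2, mu), 2, sds, "/") %*% spec$true_beta)
  signal_struct <- signal_struct - mean(signal_struct) + mean(signal)
  eps_y <- stats::rnorm(sum(treated), sd = spec$noise_sd_y)
  surv_treated <- 100 * (1 + signal + eps_y)
  clipped <- surv_treated < spec$survival_floor
  surv_treated[clipped] <- spec$survival_floor

  survival_pct <- numeric(n_cond)
  survival_pct[is_control] <- 100
  survival_pct[treated] <- surv_treated
  signal_all <- struct_all <- rep(NA_real_, n_cond)
  signal_all[treated] <- signal
  struct_all[treated] <- signal_struct
  clipped_all <- rep(FALSE, n_cond)
  clipped_all[which(treated)[clipped]] <- TRUE

  col_protein <- rep(spec$proteins, each = Tn)
  col_time <- rep(spec$time_points, P)
  phospho <- tidyr::expand_grid(conditions, tibble::tibble(protein = col_protein,
                                                           time_h = col_time))
  phospho$value <- as.numeric(t(V))
  phospho$rep1 <- as.numeric(t(rep1))
  phospho$rep2 <- as.numeric(t(rep2))

  survival <- dplyr::mutate(conditions, survival_pct = survival_pct)

  ds <- signaling_dataset(phospho, survival,
                          metadata = list(cell_lines = spec$cell_lines,
                                          treatments = spec$treatments,
                                          control = spec$control,
                                          inhibitors = spec$inhibitors,
                                          inhibitor_cell_line = spec$inhibitor_cell_line,
                                          proteins = spec$proteins,
                                          time_points = spec$time_points))
  attr(ds, "ground_truth") <- list(
    true_beta = spec$true_beta,
    signal = dplyr::mutate(conditions, signal = signal_all,
                           signal_struct = struct_all,
                           survival_pct = survival_pct, clipped = clipped_all),
    modules = ms$module,
    n_rel_clipped = n_rel_clipped,
    noise_sd_y = spec$noise_sd_y,
    seed = as.integer(seed))
  ds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Ground-truth coefficient summary implied by a synthetic spec
#'
#' Deterministic function of the spec alone: the planted per-column
#' coefficients, the per-protein mean absolute coefficient, and the implied
#' protein ranking (ties broken by declared protein order and flagged).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `per_column` (tibble: protein, time_h, beta),
#'   `per_protein` (tibble: protein, mean_abs_beta, sorted descending), and
#'   `ranking` (character vector).
#' @export
true_parameters <- function(spec) {
  validate_synthetic_spec(spec)
  Tn <- length(spec$time_points)
  per_column <- tibble::tibble(
    protein = rep(spec$proteins, each = Tn),
    time_h = rep(spec$time_points, length(spec$proteins)),
    beta = unname(spec$true_beta))
  per_protein <- per_column |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(mean_abs_beta = mean(abs(.data$beta)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_beta),
                   match(.data$protein, spec$proteins))
  list(per_column = per_column,
       per_protein = per_protein,
       ranking = per_protein$protein,
       tied = length(unique(per_protein$mean_abs_beta)) < nrow(per_protein))
}

#' Analytic signal fraction of a synthetic dataset
#'
#' The fraction of scaled-survival variance carried by the generator's
#' low-rank condition-level structure over a given subset of treated
#' conditions: `var(signal_struct) / (var(signal) + noise_sd_y^2)`. The
#' total planted signal splits into a structured part (module activities
#' acting through the loading matrix, representable by a model with as many
#' latent variables as the generator has modules) and a part borne by
#' measurement/replicate noise in the stored values, which no low-rank
#' model can attribute coefficients to; the structured fraction is the
#' generator's own reference for what a well-specified cross-validated
#' regression recovers on that subset.
#'
#' @param dataset A dataset from [generate_dataset()].
#' @param cell_lines Optional cell-line subset.
#' @param include_inhibitors Include inhibitor-combination conditions?
#' @return A single number, typically in (0, 1]; sampling variation in the
#'   noise-borne signal can push an individual realization slightly above 1.
#' @export
signal_fraction <- function(dataset, cell_lines = NULL, include_inhibitors = FALSE) {
  gt <- attr(dataset, "ground_truth")
  if (is.null(gt)) stop_contract("dataset carries no ground truth; was it generated by generate_dataset()?")
  sig <- gt$signal
  sig <- sig[!is.na(sig$signal), , drop = FALSE]
  if (!is.null(cell_lines)) sig <- sig[sig$cell_line %in% cell_lines, , drop = FALSE]
  if (!include_inhibitors) sig <- sig[is.na(sig$inhibitor), , drop = FALSE]
  stats::var(sig$signal_struct) / (stats::var(sig$signal) + gt$noise_sd_y^2)
}

#' Generate a synthetic ELISA standard curve
#'
#' Produces (concentration, absorbance) pairs following a second-order
#' polynomial `absorbance = a * c^2 + b * c + d` plus optional Gaussian
#' noise, for exercising the calibration fit/inversion round trip. The
#' noiseless curve must be monotone over the concentration range, as a real
#' usable standard curve would be.
#'
#' @param quad_coeffs Numeric length-3 vector `c(a, b, d)`.
#' @param n_points Number of standard points (default 8).
#' @param noise_sd SD of absorbance noise.
#' @param seed Integer seed.
#' @param concentrations Optional strictly increasing concentrations;
#'   defaults to `seq_len(n_points)`.
#' @return A tibble with columns `concentration` and `absorbance`.
#' @export
generate_standard_curve <- function(quad_coeffs, n_points = 8L, noise_sd = 0,
                                    seed = 1L, concentrations = NULL) {
  stopifnot(length(quad_coeffs) == 3)
  if (is.null(concentrations)) concentrations <- as.numeric(seq_len(n_points))
  if (any(diff(concentrations) <= 0))
    stop_contract("concentrations must be strictly increasing")
  a <- quad_coeffs[[1]]; b <- quad_coeffs[[2]]; d <- quad_coeffs[[3]]
  clean <- a * concentrations^2 + b * concentrations + d
  if (!(all(diff(clean) > 0) || all(diff(clean) < 0)))
    stop_calibration("noiseless standard curve is not monotone over the concentration range")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(seed, "standard_curve"))
  absorbance <- clean + stats::rnorm(length(clean), sd = noise_sd)
  tibble::tibble(concentration = concentrations, absorbance = absorbance)
}
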