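test_that("permutation summary obeys its z and p identities exactly", {
  ds <- generate_dataset(synthetic_spec(), seed = 14)
  dm <- assemble_design_matrix(select_rows(ds))
  pr <- permutation_significance(dm, n_perm = 120, seed = 2, r2_mode = "fit")
  expect_equal(pr$mean_r2, mean(pr$r2_values))
  expect_equal(pr$sd_r2, sd(pr$r2_values))
  expect_equal(pr$z, (pr$model_r2 - pr$mean_r2) / pr$sd_r2)
  expect_equal(pr$p_value, pnorm(pr$z, lower.tail = FALSE))
  expect_equal(pr$exceedance, mean(pr$r2_values >= pr$model_r2))
  # a model exactly at the null mean would sit at z = 0, p = 0.5
  expect_equal(pnorm(0, lower.tail = FALSE), 0.5)
})

test_that("permutation streams are seeded independently of the model fit", {
  ds <- generate_dataset(synthetic_spec(), seed = 14)
  dm <- assemble_design_matrix(select_rows(ds))
  a <- permutation_significance(dm, n_perm = 110, seed = 5, r2_mode = "fit")
  b <- permutation_significance(dm, n_perm = 110, seed = 5, r2_mode = "fit")
  expect_identical(a$r2_values, b$r2_values)
  c <- permutation_significance(dm, n_perm = 110, seed = 6, r2_mode = "fit")
  expect_false(identical(a$r2_values, c$r2_values))
  expect_error(permutation_significance(dm$X, rep(1, 18), n_perm = 110),
               class = "signalpls_contract_error")
})

test_that("randomization is calibrated: null data give z centred at zero", {
  zs <- vapply(1:30, function(s) {
    set.seed(4000 + s)
    X <- matrix(rnorm(18 * 8), 18, 8)
    y <- rnorm(18, mean = 100, sd = 30)
    permutation_significance(X, y, ncomp = 3, n_perm = 100, seed = s,
                             r2_mode = "fit")$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("coefficient ranking summarises mean absolute contributions", {
  ds <- generate_dataset(synthetic_spec(), seed = 15)
  dm <- assemble_design_matrix(select_rows(ds))
  model <- fit_simpls(autoscale(dm), ncomp = 3)
  cs <- mean_abs_coefficients(model)
  # brute-force recomputation per protein
  B <- as.numeric(model$coefficients)
  for (i in seq_along(ds$metadata$proteins)) {
    manual <- mean(abs(B[(i - 1) * 3 + 1:3]))
    got <- cs$per_protein$mean_abs_coef[cs$per_protein$protein ==
                                          ds$metadata$proteins[[i]]]
    expect_equal(got, manual)
  }
  expect_equal(cs$ranking, cs$per_protein$protein)
  expect_true(all(diff(cs$per_protein$mean_abs_coef) <= 1e-15))
})

test_that("a model with one active protein puts it alone on top", {
  model <- structure(list(
    coefficients = matrix(c(0, 0, 0, 0.4, -0.2, 0.1, 0, 0, 0), ncol = 1),
    col_info = tibble::tibble(protein = rep(c("P1", "P2", "P3"), each = 3),
                              time_h = rep(c(0.5, 4, 24), 3),
                              label = paste0("c", 1:9)),
    n_components = 1L, n_obs = 10L), class = "pls_model")
  cs <- mean_abs_coefficients(model)
  expect_identical(cs$ranking[[1]], "P2")
  # zero-score ties fall back to declared protein order
  expect_identical(cs$ranking[2:3], c("P1", "P3"))
})

test_that("the incremental curve ends at the full model and plateaus after the signal", {
  spec <- synthetic_spec(noise_sd_x = 0.02, noise_sd_y = 0.02, replicate_cv = 0.02)
  ds <- generate_dataset(spec, seed = 16)
  dm <- assemble_design_matrix(select_rows(ds))
  model <- fit_simpls(autoscale(dm), ncomp = 3)
  ranking <- mean_abs_coefficients(model)$ranking
  curve <- suppressWarnings(incremental_r2(dm, ranking, ncomp = 3))
  full <- loocv(dm, ncomp = 3)$r2
  expect_equal(curve$r2[[length(ranking)]], full, tolerance = 1e-12)
  expect_equal(curve$n_columns, seq_along(ranking) * 3)
})

test_that("the curve plateaus once the signal-bearing proteins are included", {
  beta <- rep(0, 24); beta[1:3] <- 0.1; beta[4:6] <- 0.06 # two active proteins
  spec <- synthetic_spec(true_beta = beta, noise_sd_x = 0.02, noise_sd_y = 0.02,
                         replicate_cv = 0.02)
  gains <- sapply(1:5, function(s) {
    ds <- generate_dataset(spec, seed = 300 + s)
    dm <- assemble_design_matrix(select_rows(ds))
    ranking <- spec$proteins # true signal proteins first
    curve <- suppressWarnings(incremental_r2(dm, ranking, ncomp = 3))
    max(diff(curve$r2)[-1]) # step gains after the two signal proteins
  })
  expect_lt(mean(gains), 0.02)
})

test_that("a lone noiseless signal protein reaches R-squared 1 in one step", {
  beta <- rep(0, 24); beta[1:3] <- 0.1
  spec <- noiseless_spec(true_beta = beta)
  ds <- generate_dataset(spec, seed = 17)
  dm <- assemble_design_matrix(select_rows(ds))
  curve <- suppressWarnings(incremental_r2(dm, spec$proteins[[1]], ncomp = 3))
  expect_equal(curve$r2[[1]], 1, tolerance = 1e-6)
  expect_error(incremental_r2(dm, character()), class = "signalpls_contract_error")
  expect_error(incremental_r2(dm, "unknown"), class = "signalpls_selection_error")
})

test_that("error grouping averages within groups and skips singletons", {
  cv <- structure(list(
    predictions = tibble::tibble(
      treatment = c("a", "a", "b", "b", "c"),
      cell_line = "x", inhibitor = NA_character_,
      measured = rep(100, 5), predicted = c(100, 100, 110, 90, 130),
      abs_pct_error = c(0, 0, 10, 10, 30)),
    r2 = 0.9, ncomp = 3L, scaling_mode = "per-fold",
    r2_method = "corr2", sd_type = "sample", n = 5L), class = "pls_cv")
  expect_warning(s <- prediction_error_summary(cv, "treatment"), "skipped")
  expect_equal(s$groups$mean_abs_pct_error[s$groups$group == "a"], 0)
  expect_equal(s$groups$mean_abs_pct_error[s$groups$group == "b"], 10)
  expect_equal(nrow(s$comparisons), 1) # only a vs b have >= 2 conditions
  # a single usable group yields no comparisons
  cv$predictions$treatment <- c("a", "a", "a", "a", "a")
  s2 <- prediction_error_summary(cv, "treatment")
  expect_null(s2$comparisons)
  expect_equal(s2$groups$mean_abs_pct_error, 10)
})

test_that("an error-inflated group is flagged by the Welch comparison", {
  hits <- vapply(1:100, function(s) {
    set.seed(700 + s)
    errs <- c(abs(rnorm(6, 10, 3)), abs(rnorm(6, 50, 15)))
    cv <- structure(list(
      predictions = tibble::tibble(
        treatment = rep(c("ctrl_like", "inflated"), each = 6),
        cell_line = "x", inhibitor = NA_character_,
        measured = 100, predicted = 100 + errs, abs_pct_error = errs),
      r2 = 0.5, ncomp = 3L, scaling_mode = "per-fold",
      r2_method = "corr2", sd_type = "sample", n = 12L), class = "pls_cv")
    s <- prediction_error_summary(cv, "treatment")
    s$comparisons$p_value[[1]] < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
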