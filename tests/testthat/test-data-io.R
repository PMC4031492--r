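test_that("dataset serialization round-trips exactly", {
  ds <- generate_dataset(synthetic_spec(), seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back$phospho), as.data.frame(ds$phospho))
  expect_equal(as.data.frame(back$survival), as.data.frame(ds$survival))
  expect_equal(back$metadata$proteins, ds$metadata$proteins)
  # writes are byte-stable
  dir2 <- withr::local_tempdir()
  write_dataset(ds, dir2)
  expect_identical(readLines(file.path(dir, "phospho.csv")),
                   readLines(file.path(dir2, "phospho.csv")))
})

test_that("file row count matches record count plus header", {
  ds <- generate_dataset(synthetic_spec(inhibitors = character()), seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_length(readLines(file.path(dir, "phospho.csv")), nrow(ds$phospho) + 1)
  expect_length(readLines(file.path(dir, "survival.csv")), nrow(ds$survival) + 1)
})

test_that("a dataset without its survival block is rejected by name", {
  ds <- generate_dataset(synthetic_spec(), seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  unlink(file.path(dir, "survival.csv"))
  expect_error(read_dataset(dir), class = "signalpls_schema_error")
  expect_error(read_dataset(dir), "survival")
})

test_that("the default design without inhibitors has the expected row counts", {
  # 3 cell lines x (control + 6 treatments) x 8 proteins x 3 time points
  ds <- generate_dataset(synthetic_spec(inhibitors = character()), seed = 1)
  expect_equal(nrow(ds$phospho), 3 * 7 * 8 * 3) # 504
  expect_equal(nrow(ds$survival), 21)
})

test_that("incomplete measurement blocks are rejected with the offending condition", {
  ds <- generate_dataset(small_spec(), seed = 1)
  broken <- ds$phospho[-5, ]
  err <- expect_error(signaling_dataset(broken, ds$survival, ds$metadata),
                      class = "signalpls_schema_error")
  expect_match(conditionMessage(err), "complete")
})

test_that("wide condition layouts convert to the long schema", {
  wide <- tibble::tibble(protein = rep(c("P1", "P2"), each = 2),
                         time_h = rep(c(0.5, 4), 2),
                         cond_a = 1:4, cond_b = 5:8)
  mapping <- tibble::tibble(column = c("cond_a", "cond_b"),
                            cell_line = "A",
                            treatment = c("EGF", "control"),
                            inhibitor = NA_character_)
  long <- wide_to_long(wide, mapping)
  expect_equal(nrow(long), 8)
  expect_equal(long$value[long$treatment == "EGF" & long$protein == "P1" &
                            long$time_h == 0.5], 1)
  expect_error(wide_to_long(wide[-(3:4)], mapping), class = "signalpls_schema_error")
})

test_that("standard-curve fitting recovers exact quadratics and flags degeneracy", {
  conc <- 1:8
  pts <- tibble::tibble(concentration = conc, absorbance = 2 * conc^2 + 3 * conc + 1)
  sc <- fit_standard_curve(pts)
  expect_equal(unname(sc$coeffs), c(2, 3, 1), tolerance = 1e-9)
  # straight line: leading coefficient ~ 0
  lin <- fit_standard_curve(tibble::tibble(concentration = conc,
                                           absorbance = 0.4 * conc + 0.05))
  expect_lt(abs(lin$coeffs[["a"]]), 1e-12)
  # non-monotone fit over the range is rejected
  expect_error(fit_standard_curve(tibble::tibble(concentration = conc,
                                                 absorbance = (conc - 4.5)^2)),
               class = "signalpls_calibration_error")
  expect_error(fit_standard_curve(pts[1:2, ]), class = "signalpls_calibration_error")
})

test_that("noisy standard-curve residuals equal the normal-equations solution", {
  pts <- generate_standard_curve(c(0.1, 0.6, 0.3), noise_sd = 0.08, seed = 12)
  sc <- fit_standard_curve(pts)
  A <- cbind(pts$concentration^2, pts$concentration, 1)
  beta <- solve(crossprod(A), crossprod(A, pts$absorbance))
  rss_oracle <- sum((pts$absorbance - A %*% beta)^2)
  expect_equal(sc$rss, rss_oracle, tolerance = 1e-10)
})

test_that("standard-curve inversion returns the in-range root", {
  conc <- 0:8
  ident <- fit_standard_curve(tibble::tibble(concentration = conc, absorbance = conc))
  expect_equal(invert_standard_curve(0.7, ident), 0.7, tolerance = 1e-9)
  sq <- fit_standard_curve(tibble::tibble(concentration = conc, absorbance = conc^2))
  expect_equal(invert_standard_curve(4, sq), 2, tolerance = 1e-9) # negative root rejected
  # out-of-range absorbance: error unless clamped
  expect_error(invert_standard_curve(100, ident), class = "signalpls_calibration_error")
  expect_equal(invert_standard_curve(100, ident, clamp = TRUE), 8)
})

test_that("forward evaluation then inversion is the identity across random curves", {
  set.seed(77)
  for (rep in 1:25) {
    a <- runif(1, 0.01, 0.3)
    b <- runif(1, 0.2, 2)
    d <- runif(1, -0.5, 0.5)
    pts <- generate_standard_curve(c(a, b, d), noise_sd = 0.02, seed = rep)
    sc <- fit_standard_curve(pts)
    c_true <- runif(5, min(pts$concentration), max(pts$concentration))
    y <- sc$coeffs[["a"]] * c_true^2 + sc$coeffs[["b"]] * c_true + sc$coeffs[["d"]]
    expect_equal(invert_standard_curve(y, sc), c_true, tolerance = 1e-9)
  }
})
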