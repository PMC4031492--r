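test_that("a single predictor equal to the response is fit exactly with one component", {
  set.seed(1)
  y <- rnorm(10)
  y <- y - mean(y)
  X <- matrix(y, ncol = 1)
  fit <- fit_simpls(X, y, ncomp = 1)
  expect_equal(as.numeric(X %*% fit$coefficients), y, tolerance = 1e-12)
})

test_that("SIMPLS at full rank equals ordinary least squares", {
  for (seed in 1:5) {
    prob <- make_centered_problem(n = 15, p = 6, noise_sd = 0.3, seed = seed)
    fit <- fit_simpls(prob$X, prob$y, ncomp = 6)
    expect_equal(as.numeric(prob$X %*% fit$coefficients),
                 ols_predict(prob$X, prob$y), tolerance = 1e-8)
  }
})

test_that("SIMPLS matches an independently coded NIPALS-PLS1 oracle at every A", {
  for (seed in 1:5) {
    prob <- make_centered_problem(n = 14, p = 8, noise_sd = 0.5, seed = seed + 10)
    for (A in 1:5) {
      B_nipals <- nipals_pls1(prob$X, prob$y, A)
      fit <- fit_simpls(prob$X, prob$y, ncomp = A)
      expect_equal(as.numeric(prob$X %*% fit$coefficients),
                   as.numeric(prob$X %*% B_nipals), tolerance = 1e-8)
    }
  }
})

test_that("model invariants hold: orthogonal scores and B = R Q'", {
  prob <- make_centered_problem(n = 20, p = 10, noise_sd = 0.4, seed = 3)
  fit <- fit_simpls(prob$X, prob$y, ncomp = 4)
  gram <- crossprod(fit$scores)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  expect_equal(fit$coefficients,
               fit$x_weights %*% t(fit$y_loadings), tolerance = 1e-10)
})

test_that("training fit R-squared is non-decreasing in the number of components", {
  prob <- make_centered_problem(n = 16, p = 10, noise_sd = 0.6, seed = 7)
  r2s <- vapply(1:8, function(A) {
    fit <- fit_simpls(prob$X, prob$y, ncomp = A)
    pred <- as.numeric(prob$X %*% fit$coefficients)
    1 - sum((prob$y - pred)^2) / sum(prob$y^2)
  }, numeric(1))
  expect_true(all(diff(r2s) >= -1e-10))
})

test_that("contract violations are rejected", {
  prob <- make_centered_problem(n = 10, p = 4, seed = 2)
  expect_error(fit_simpls(prob$X, prob$y, ncomp = 0), class = "signalpls_contract_error")
  expect_error(fit_simpls(prob$X, prob$y, ncomp = 10), class = "signalpls_contract_error")
  expect_error(fit_simpls(prob$X + 5, prob$y, ncomp = 2), class = "signalpls_contract_error")
  expect_error(fit_simpls(prob$X, prob$y + 3, ncomp = 2), class = "signalpls_contract_error")
})

test_that("component extraction stops early when covariance is exhausted", {
  prob <- make_centered_problem(n = 12, p = 6, rank = 2, noise_sd = 0, seed = 4)
  expect_warning(fit <- fit_simpls(prob$X, prob$y, ncomp = 5), "exhausted|degenerate")
  expect_lte(fit$n_components, 2)
  pred <- as.numeric(prob$X %*% fit$coefficients)
  expect_equal(pred, prob$y, tolerance = 1e-8) # beta is in the rank-2 row space
})

test_that("prediction applies stored scaling and inverts to survival units", {
  ds <- generate_dataset(noiseless_spec(), seed = 9)
  dm <- assemble_design_matrix(select_rows(ds))
  model <- fit_simpls(autoscale(dm), ncomp = 3)
  # training rows of a noiseless rank-3 system reproduce Y
  expect_equal(predict(model, dm$X), dm$Y, tolerance = 1e-6)
  # a row at the training column means predicts the training mean survival
  at_mean <- matrix(model$scaling$x_mean, nrow = 1,
                    dimnames = list(NULL, colnames(dm$X)))
  expect_equal(predict(model, at_mean), mean(dm$Y), tolerance = 1e-10)
  expect_error(predict(model, dm$X[, 1:5]), class = "signalpls_contract_error")
})

test_that("out-of-fold predictions agree with the OLS oracle at full rank", {
  set.seed(21)
  prob <- make_centered_problem(n = 20, p = 4, noise_sd = 0.5, seed = 21)
  train <- 1:15; test <- 16:20
  Xtr <- sweep(prob$X[train, ], 2, colMeans(prob$X[train, ]))
  ytr <- prob$y[train] - mean(prob$y[train])
  fit <- fit_simpls(Xtr, ytr, ncomp = 4)
  Xte <- sweep(prob$X[test, ], 2, colMeans(prob$X[train, ]))
  expect_equal(as.numeric(Xte %*% fit$coefficients),
               ols_predict(Xtr, ytr, Xte), tolerance = 1e-8)
})

test_that("leave-one-out R-squared is 1 on a noiseless linear system", {
  set.seed(5)
  scores <- matrix(rnorm(12 * 3), 12, 3)
  X <- scores %*% matrix(rnorm(3 * 7), 3, 7)
  y <- as.numeric(X %*% rnorm(7)) + 100
  cv <- loocv(X, y, ncomp = 3)
  expect_equal(cv$r2, 1, tolerance = 1e-6)
  expect_equal(cv$predictions$predicted, y, tolerance = 1e-4)
})

test_that("cross-validated R-squared stays small when the response is pure noise", {
  r2s <- vapply(1:10, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(50 * 5), 50, 5)
    y <- rnorm(50)
    loocv(X, y, ncomp = 3)$r2
  }, numeric(1))
  expect_lt(mean(r2s), 0.2)
})

test_that("per-fold scaling never sees the held-out row", {
  ds <- generate_dataset(synthetic_spec(), seed = 12)
  dm <- assemble_design_matrix(select_rows(ds))
  cv <- loocv(dm, ncomp = 3)
  # corrupt one condition's survival: its own out-of-fold prediction is unchanged
  i <- 7
  y2 <- dm$Y
  y2[i] <- y2[i] * 50
  cv2 <- loocv(dm$X, y2, ncomp = 3)
  expect_equal(cv2$predictions$predicted[i], cv$predictions$predicted[i],
               tolerance = 1e-10)
  expect_error(loocv(dm$X[1:4, ], dm$Y[1:4], ncomp = 3),
               class = "signalpls_contract_error")
})

test_that("per-row absolute percent errors follow their definition", {
  ds <- generate_dataset(synthetic_spec(), seed = 13)
  dm <- assemble_design_matrix(select_rows(ds))
  cv <- loocv(dm, ncomp = 3)
  manual <- 100 * abs(cv$predictions$predicted - cv$predictions$measured) /
    cv$predictions$measured
  expect_equal(cv$predictions$abs_pct_error, manual)
})

test_that("both R-squared conventions match their formulas", {
  set.seed(17)
  y <- rnorm(20); yhat <- y + rnorm(20, sd = 0.5)
  expect_equal(r_squared(y, yhat, "corr2"), cor(y, yhat)^2)
  expect_equal(r_squared(y, yhat, "one_minus_ss"),
               1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  expect_equal(r_squared(y, y, "corr2"), 1)
  expect_equal(r_squared(y, y, "one_minus_ss"), 1)
  # predicting the mean scores zero under the sum-of-squares convention
  expect_equal(r_squared(y, rep(mean(y), 20), "one_minus_ss"), 0)
  expect_error(r_squared(y, rep(1, 20), "corr2"), class = "signalpls_contract_error")
})
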