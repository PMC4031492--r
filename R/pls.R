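#' Fit a partial least squares regression model by SIMPLS
#'
#' A from-scratch implementation of the SIMPLS algorithm (covariance
#' deflation) for a univariate response. At each step the weight vector
#' maximizing covariance with the response is taken from the current
#' cross-product vector, scores are normalized, X/Y loadings computed, and
#' the cross-product is deflated by an orthonormalized basis of the X
#' loadings, which makes the score vectors mutually orthogonal. Regression
#' coefficients on the scaled scale are `B = R %*% t(Q)`.
#'
#' Both `X` and `Y` must already be column-centered (normally via
#' [autoscale()]); passing uncentered data is a contract error, not silently
#' corrected, because centering choices interact with cross-validation.
#'
#' @param x Either a scaled `design_matrix` or a centered numeric matrix.
#' @param y Centered numeric response vector (ignored when `x` is a
#'   `design_matrix`).
#' @param ncomp Number of latent variables `A`, `1 <= A <= min(n-1, p)`.
#'   Extraction stops early, with a warning, if the residual covariance is
#'   numerically exhausted.
#' @param tol Threshold (relative to the initial covariance norm) for
#'   declaring the residual covariance exhausted.
#' @return An object of class `pls_model`: `n_components`, `x_weights` (R),
#'   `x_loadings` (P), `y_loadings` (Q), `scores` (T), `coefficients` (B),
#'   plus `scaling`/`col_info` when fit from a `design_matrix`.
#' @references de Jong, S. (1993) SIMPLS: an alternative approach to partial
#'   least squares regression. Chemometrics and Intelligent Laboratory
#'   Systems 18, 251-263.
#' @export
fit_simpls <- function(x, y = NULL, ncomp = 3L, tol = 1e-12) {
  scaling <- NULL; col_info <- NULL; row_info <- NULL
  if (inherits(x, "design_matrix")) {
    if (!isTRUE(x$scaled))
      stop_contract("fit_simpls() requires an autoscaled design matrix")
    scaling <- x$scaling; col_info <- x$col_info; row_info <- x$row_info
    y <- x$Y; x <- x$X
  }
  X <- as.matrix(x)
  Y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(Y) != n) stop_contract("X has %d rows but Y has %d values", n, length(Y))
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop_contract("ncomp = %d out of range [1, %d]", ncomp, min(n - 1, p))
  if (max(abs(colMeans(X))) > 1e-6 || abs(mean(Y)) > 1e-6)
    stop_contract("fit_simpls() requires centered X and Y (max |column mean| = %.3g)",
                  max(max(abs(colMeans(X))), abs(mean(Y))))

  ncomp <- as.integer(ncomp)
  R <- matrix(0, p, ncomp) # X weights (applied to original scaled X)
  P <- matrix(0, p, ncomp) # X loadings
  Q <- numeric(ncomp)      # Y loadings
  TT <- matrix(0, n, ncomp)
  V <- matrix(0, p, ncomp) # orthonormal basis of X loadings, for deflation

  s <- crossprod(X, Y) # p x 1 cross-product (covariance direction)
  s0 <- sqrt(sum(s^2))
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(s^2)) <= tol * max(s0, .Machine$double.eps)) {
      warn(sprintf("SIMPLS: residual covariance exhausted after %d component(s); requested %d",
                   a_done, ncomp))
      break
    }
    r <- s # univariate Y: the dominant covariance direction is s itself
    t_a <- as.numeric(X %*% r) # centered because X is centered
    normt <- sqrt(sum(t_a^2))
    if (normt <= tol * max(s0, .Machine$double.eps)) {
      warn(sprintf("SIMPLS: degenerate score at component %d; stopping at %d", a, a_done))
      break
    }
    t_a <- t_a / normt
    r <- r / normt
    p_a <- crossprod(X, t_a)
    q_a <- sum(Y * t_a)
    v <- p_a
    if (a_done > 0) {
      Vd <- V[, seq_len(a_done), drop = FALSE]
      v <- v - Vd %*% crossprod(Vd, p_a)
      v <- v - Vd %*% crossprod(Vd, v) # re-orthogonalize to limit drift
    }
    nv <- sqrt(sum(v^2))
    if (nv <= tol * max(s0, .Machine$double.eps)) {
      warn(sprintf("SIMPLS: loading basis degenerate at component %d; stopping at %d",
                   a, a_done))
      break
    }
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    a_done <- a
    R[, a] <- r; P[, a] <- p_a; Q[a] <- q_a; TT[, a] <- t_a; V[, a] <- v
  }
  if (a_done == 0L) stop_contract("SIMPLS extracted no components (X'Y is numerically zero)")
  keep <- seq_len(a_done)
  R <- R[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Q <- Q[keep]; TT <- TT[, keep, drop = FALSE]
  B <- R %*% matrix(Q, ncol = 1)
  rownames(B) <- colnames(X)
  structure(list(n_components = a_done, x_weights = R, x_loadings = P,
                 y_loadings = matrix(Q, nrow = 1), scores = TT,
                 coefficients = B, scaling = scaling, col_info = col_info,
                 n_obs = n),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> SIMPLS, %d component(s), %d predictors, %d observations\n",
              x$n_components, nrow(x$coefficients), x$n_obs))
  invisible(x)
}

#' Predict survival for new conditions from a fitted PLS model
#'
#' When the model was fit from an autoscaled `design_matrix`, `newdata` is
#' taken on the raw measurement scale: the stored training scaling is
#' applied, scaled predictions `X_s %*% B` computed, and the result
#' inverse-transformed to survival units. When the model was fit from bare
#' centered matrices, `newdata` must already be on that centered scale and
#' centered predictions are returned.
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix (or `design_matrix`) whose columns match
#'   the training columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "design_matrix")) {
    if (isTRUE(newdata$scaled))
      stop_contract("pass the unscaled design matrix; the model applies its own training scaling")
    newdata <- newdata$X
  }
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$coefficients))
    stop_contract("newdata has %d columns; model expects %d", ncol(X),
                  nrow(object$coefficients))
  if (!is.null(colnames(X)) && !is.null(rownames(object$coefficients)) &&
      !identical(colnames(X), rownames(object$coefficients)))
    stop_contract("newdata column labels do not match the model's training columns")
  if (is.null(object$scaling)) {
    return(as.numeric(X %*% object$coefficients))
  }
  s <- object$scaling
  Xs <- apply_scaling_x(X, s)
  as.numeric(Xs %*% object$coefficients) * s$y_sd + s$y_mean
}

#' Coefficient of determination between measured and predicted values
#'
#' Two conventions are exposed because published cross-validated R-squared
#' values do not always state which was used: `"corr2"` is the squared
#' Pearson correlation of measured and predicted values (always in
#' \[0, 1\]); `"one_minus_ss"` is `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' which can be negative for predictions worse than the mean.
#'
#' @param measured,predicted Numeric vectors of equal length >= 2.
#' @param method `"corr2"` (default) or `"one_minus_ss"`.
#' @return A single number.
#' @export
r_squared <- function(measured, predicted, method = c("corr2", "one_minus_ss")) {
  method <- match.arg(method)
  if (length(measured) != length(predicted) || length(measured) < 2)
    stop_contract("measured and predicted must be equal-length vectors of length >= 2")
  if (method == "corr2") {
    if (stats::sd(measured) == 0 || stats::sd(predicted) == 0)
      stop_contract("squared-correlation R^2 is undefined for zero-variance input")
    return(stats::cor(measured, predicted)^2)
  }
  1 - sum((measured - predicted)^2) / sum((measured - mean(measured))^2)
}

#' Leave-one-out cross-validation of a SIMPLS model
#'
#' For each condition in turn: drop it, autoscale the remaining rows
#' (`scaling_mode = "per-fold"`, the default, so held-out data never leaks
#' into the scaling), fit SIMPLS, and predict the held-out condition's
#' survival in original units. The cross-validated R-squared compares the
#' measured survival vector with the assembled out-of-fold predictions.
#'
#' `scaling_mode = "global"` scales once on all rows before leaving rows
#' out, matching descriptions in which the data were scaled before the
#' leave-one-out loop.
#'
#' @param x Unscaled `design_matrix`, or raw numeric matrix.
#' @param y Raw response vector (ignored when `x` is a `design_matrix`).
#' @param ncomp Number of latent variables (per-fold mode requires
#'   `ncomp <= n - 2`).
#' @param scaling_mode `"per-fold"` (default) or `"global"`.
#' @param r2_method Passed to [r_squared()].
#' @param sd_type Passed to [autoscale()]'s convention.
#' @return An object of class `pls_cv`: tibble-backed predictions
#'   (`measured`, `predicted`, `abs_pct_error` per condition), the
#'   cross-validated `r2`, and the settings used.
#' @export
loocv <- function(x, y = NULL, ncomp = 3L,
                  scaling_mode = c("per-fold", "global"),
                  r2_method = c("corr2", "one_minus_ss"),
                  sd_type = c("sample", "population")) {
  scaling_mode <- match.arg(scaling_mode)
  r2_method <- match.arg(r2_method)
  sd_type <- match.arg(sd_type)
  row_info <- NULL
  if (inherits(x, "design_matrix")) {
    if (isTRUE(x$scaled))
      stop_contract("loocv() takes the unscaled design matrix and scales inside each fold")
    row_info <- x$row_info
    y <- x$Y; x <- x$X
  }
  X <- as.matrix(x); Y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop_contract("leave-one-out cross-validation needs at least 3 rows")
  if (scaling_mode == "per-fold" && ncomp >= n - 1)
    stop_contract("per-fold LOOCV with n = %d supports at most %d components", n, n - 2)

  predicted <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; Ytr <- Y[-i]
    if (scaling_mode == "per-fold") {
      xm <- colMeans(Xtr); xs <- col_sds(Xtr, sd_type); xs[xs == 0] <- 1
      ym <- mean(Ytr); ys <- vec_sd(Ytr, sd_type); if (ys == 0) ys <- 1
    } else {
      xm <- colMeans(X); xs <- col_sds(X, sd_type); xs[xs == 0] <- 1
      ym <- mean(Y); ys <- vec_sd(Y, sd_type); if (ys == 0) ys <- 1
    }
    Xtr_s <- sweep(sweep(Xtr, 2, xm), 2, xs, "/")
    # guard exact centering for the contract check in fit_simpls
    Xtr_s <- sweep(Xtr_s, 2, colMeans(Xtr_s))
    Ytr_s <- (Ytr - ym) / ys
    Ytr_s <- Ytr_s - mean(Ytr_s)
    fit <- fit_simpls(Xtr_s, Ytr_s, ncomp = min(ncomp, nrow(Xtr) - 1, ncol(Xtr)))
    Xi_s <- (X[i, ] - xm) / xs
    predicted[[i]] <- sum(Xi_s * fit$coefficients) * ys + ym
  }
  abs_pct_error <- ifelse(Y > 0, 100 * abs(predicted - Y) / Y, NA_real_)
  pred <- tibble::tibble(measured = Y, predicted = predicted,
                         abs_pct_error = abs_pct_error)
  if (!is.null(row_info)) pred <- dplyr::bind_cols(row_info, pred)
  structure(list(predictions = pred, r2 = r_squared(Y, predicted, r2_method),
                 ncomp = as.integer(ncomp), scaling_mode = scaling_mode,
                 r2_method = r2_method, sd_type = sd_type, n = n),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> leave-one-out, %d conditions, %d component(s): R^2 (%s) = %.4f\n",
              x$n, x$ncomp, x$r2_method, x$r2))
  invisible(x)
}
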