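# Independent oracles, deliberately written with none of the package's
# internals so they can arbitrate against the SIMPLS implementation.

# Classical NIPALS PLS1: X-deflation with regression coefficients recovered
# through B = W (P'W)^-1 q.
nipals_pls1 <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  p <- ncol(X)
  n <- nrow(X)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(X, y)
    w <- w / sqrt(sum(w^2))
    t_a <- as.numeric(X %*% w)
    tt <- sum(t_a^2)
    p_a <- crossprod(X, t_a) / tt
    q[a] <- sum(y * t_a) / tt
    X <- X - tcrossprod(t_a, p_a)
    y <- y - q[a] * t_a
    W[, a] <- w
    P[, a] <- p_a
  }
  B <- W %*% solve(crossprod(P, W), q)
  as.numeric(B)
}

# ordinary least squares predictions via the normal equations
ols_predict <- function(X, y, X_new = X) {
  B <- solve(crossprod(X), crossprod(X, as.numeric(y)))
  as.numeric(as.matrix(X_new) %*% B)
}

# centered random regression problem with exact low-rank structure
make_centered_problem <- function(n, p, rank = p, noise_sd = 0, seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n, rank)
  load <- matrix(rnorm(rank * p), rank, p)
  X <- scores %*% load
  X <- sweep(X, 2, colMeans(X))
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = noise_sd)
  y <- y - mean(y)
  list(X = X, y = y, beta = beta)
}

# a compact synthetic study used where full size is not needed
small_spec <- function(...) {
  synthetic_spec(cell_lines = c("A", "B"),
                 treatments = c("t1", "t2", "t3", "t4"),
                 inhibitors = c("i1", "i2"),
                 proteins = c("P1", "P2", "P3", "P4"),
                 ...)
}

# noise-free generator settings gentle enough that the relative-effect floor
# never engages, so the planted map is exactly linear and rank latent_rank
noiseless_spec <- function(...) {
  synthetic_spec(noise_sd_x = 0, noise_sd_y = 0, replicate_cv = 0,
                 effect_sd = 0.15, cell_shift = 0.8, ...)
}
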