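# Independent oracles used across the suite. These deliberately take a
# different computational route from the package (power iteration instead of
# svd; explicit normal equations; literal fold loops) so agreement is
# evidence, not tautology.

# Dominant left singular vector of S via power iteration on S S'.
oracle_weight <- function(S, iters = 2000, tol = 1e-14) {
  v <- rep(1, nrow(S)) / sqrt(nrow(S))
  M <- S %*% t(S)
  for (i in seq_len(iters)) {
    v_new <- drop(M %*% v)
    v_new <- v_new / sqrt(sum(v_new^2))
    if (sum(abs(v_new - v)) < tol) break
    v <- v_new
  }
  imax <- which.max(abs(v))
  if (v[imax] < 0) v <- -v
  v
}

# Least-squares fit of Y on X (with intercept) via explicit normal equations.
oracle_ols_predict <- function(X, Y, X_new = X) {
  X1 <- cbind(1, X)
  coef <- solve(crossprod(X1), crossprod(X1, Y))
  cbind(1, X_new) %*% coef
}

# Literal leave-one-out PRESS: refit and predict each held-out row by hand.
oracle_press <- function(X, Y, h, y_scale) {
  total <- 0
  for (i in seq_len(nrow(X))) {
    fit <- fit_plsr(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], h = h)
    e <- (predict(fit, X[i, , drop = FALSE]) - Y[i, , drop = FALSE]) / y_scale
    total <- total + sum(e^2)
  }
  total
}

# Small random regression instance with controllable latent rank.
random_instance <- function(n, m, p, rank = min(m, p), noise = 0.2) {
  Tm <- matrix(rnorm(n * rank), n, rank)
  list(X = Tm %*% matrix(rnorm(rank * m), rank, m) + noise * matrix(rnorm(n * m), n, m),
       Y = Tm %*% matrix(rnorm(rank * p), rank, p) + noise * matrix(rnorm(n * p), n, p))
}

# Strictly positive dataset from a random instance (shift above zero).
positive_dataset <- function(n = 12, seed = 1) {
  set.seed(seed)
  inst <- random_instance(n, 5, 7)
  X <- sweep(inst$X, 2, abs(apply(inst$X, 2, min)) + 1, "+")
  Y <- sweep(inst$Y, 2, abs(apply(inst$Y, 2, min)) + 5, "+")
  fitness_dataset(X, Y)
}
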