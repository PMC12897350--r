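# Independent brute-force oracles, deliberately naive: each recomputes from
# scratch with textbook constructions, never calling the implementation paths
# they check.

# Stepwise selection re-derived at every step by explicit re-orthogonalization:
# regress every remaining column (and y) on ALL previously selected original
# columns via qr residuals, then take the plain correlation argmax.
oracle_select <- function(Xs, y, k_max) {
  p <- ncol(Xs)
  selected <- integer(0)
  weights <- numeric(0)
  for (t in seq_len(k_max)) {
    remaining <- setdiff(seq_len(p), selected)
    if (!length(remaining)) break
    if (length(selected)) {
      B <- cbind(1, Xs[, selected, drop = FALSE])
      resid_of <- function(v) qr.resid(qr(B), v)
    } else {
      resid_of <- function(v) v - mean(v)
    }
    yr <- resid_of(y)
    if (sd(yr) < 1e-12) break
    r <- vapply(remaining, function(j) {
      xr <- resid_of(Xs[, j])
      if (sd(xr) < 1e-8) return(0)
      cor(xr, yr)
    }, 0)
    best <- which.max(abs(r))
    if (abs(r[best]) < 0.05) break
    selected <- c(selected, remaining[best])
    weights <- c(weights, abs(r[best]))
  }
  list(indices = selected, weights = weights)
}

# Normal-equations OLS (explicitly the numerically naive construction).
oracle_ols <- function(X, y) {
  D <- cbind(1, X)
  as.numeric(solve(t(D) %*% D, t(D) %*% y))
}

# Explicit leave-one-out refits with scaling fixed once on all rows.
oracle_loo_fixed <- function(X, y, idx) {
  Xs <- scale(X)
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    D <- cbind(1, Xs[-i, idx, drop = FALSE])
    cf <- qr.coef(qr(D), y[-i])
    y[i] - sum(c(1, Xs[i, idx]) * cf)
  }, 0)
}

random_instance <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  list(X = X, Xs = applyAutoscale(X, fitAutoscale(X)), y = y,
       grid = nirGrid(1100, 2, p))
}
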