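# Brute-force OLS oracles, written against the normal equations directly so
# they share no code path with the package's lsfit/lm.fit implementations.

ols_residuals <- function(X, y) {
  beta <- solve(crossprod(X), crossprod(X, y))
  drop(y - X %*% beta)
}

# |partial Spearman correlation| of covariate values with t^2 given t,
# positions t = 1..n, ties as mid-ranks.
oracle_quadratic <- function(values) {
  n <- length(values)
  t <- seq_len(n)
  r <- rank(values, ties.method = "average")
  X <- cbind(1, t)
  er <- ols_residuals(X, r)
  eq <- ols_residuals(X, t^2)
  abs(sum(er * eq) / sqrt(sum(er^2) * sum(eq^2)))
}

# sqrt of the partial R^2 of the season-indicator block given the linear
# trend, seasons assigned from the actual crossover times.
oracle_seasonal <- function(values, times = seq_along(values) + 1, cycle = 4) {
  r <- rank(values, ties.method = "average")
  season <- ((times - 1) %% cycle) + 1
  Xr <- cbind(1, times)
  Xf <- Xr
  for (s in sort(unique(season))[-1]) Xf <- cbind(Xf, as.numeric(season == s))
  sse <- function(X) sum(ols_residuals(X, r)^2)
  sse_red <- sse(Xr)
  sqrt((sse_red - sse(Xf)) / sse_red)
}

# All permutations of 1:n by simple recursion (independent of the package's
# lexicographic generator).
all_perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms_oracle(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Random site sequences for property tests: ordinal or continuous draws.
random_sequences <- function(n_cases, sizes = c(5, 6, 8, 12), seed = 404) {
  set.seed(seed)
  lapply(seq_len(n_cases), function(i) {
    n <- sample(sizes, 1)
    if (runif(1) < 0.5) sample(0:2, n, replace = TRUE) else rnorm(n)
  })
}
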