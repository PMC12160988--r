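# Independent reference implementations used as oracles; deliberately naive
# and kept apart from the package's fitting path.

# Logistic regression by raw Newton-Raphson on the full design matrix.
oracle_logistic <- function(X, y, tol = 1e-10, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    g <- t(X) %*% (y - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H, g)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# Closed-form OLS via the normal equations.
oracle_ols <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))

# Population-SD z-scores (the package's standardization convention).
zpop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# Design matrix mirroring the package's model frame for a toy table with
# columns: measure, age, sexfemale (0/1), hyp (0/1).
toy_design <- function(d) {
  cbind(1, zpop(d$measure), zpop(d$age), d$sexfemale, d$hyp)
}

make_toy_glm_table <- function(n = 30, seed = 42) {
  set.seed(seed)
  d <- data.frame(measure = rnorm(n, 1.3, 0.25),
                  age = rnorm(n, 62, 5),
                  sexfemale = rbinom(n, 1, 0.4),
                  hyp = rbinom(n, 1, 0.3))
  lp <- -0.2 + 0.8 * zpop(d$measure) + 0.3 * d$sexfemale
  d$case <- runif(n) < 1 / (1 + exp(-lp))
  # ensure both outcome levels
  d$case[1] <- TRUE; d$case[2] <- FALSE
  d
}
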