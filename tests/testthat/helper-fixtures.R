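# Small synthetic fixtures shared across test files. Everything is built in
# code under fixed seeds; no data files are read.

small_cohort <- function(n = 40, seed = 11) generate_cohort(n, seed = seed)

small_features <- function(cohort, m = 60, seed = 12, noise_sd = 0.1, ...) {
  spec <- plant_trajectories(m, noise_sd = noise_sd, seed = seed, ...)
  list(spec = spec,
       features = generate_feature_matrix(cohort, spec, seed = seed + 1))
}

scan_ages <- function(features, cohort)
  cohort$age[match(features$subject_id, cohort$subject_id)]

# brute-force OLS oracle: normal equations via solve()
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(t(X) %*% X)))
  list(beta = drop(beta), se = se, t = drop(beta) / se, df = df,
       rss = sum(res^2))
}

# brute-force ridge oracle on standardised inputs with unpenalised intercept
ridge_oracle <- function(Z, y, lambda) {
  Z <- as.matrix(Z)
  zm <- colMeans(Z)
  zs <- apply(Z, 2, sd)
  zs[zs == 0] <- 1
  Zs <- sweep(sweep(Z, 2, zm), 2, zs, "/")
  ws <- solve(t(Zs) %*% Zs + diag(lambda, ncol(Z)), t(Zs) %*% (y - mean(y)))
  function(Znew) {
    Zn <- sweep(sweep(as.matrix(Znew), 2, zm), 2, zs, "/")
    drop(Zn %*% ws) + mean(y)
  }
}
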