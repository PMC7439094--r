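# Independent oracle implementations used to cross-check the package.
# Deliberately written with different code paths than the package internals.

# One-component PLS1-DA, fitted and predicted the textbook way: autoscale X
# by training statistics, regress the centered class vector on the single
# latent score. Returns predictions on the raw +1/-1 scale.
oracle_pls1_predict <- function(Xtrain, ytrain, Xnew) {
  mu <- apply(Xtrain, 2, mean)
  sdv <- apply(Xtrain, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- t((t(Xtrain) - mu) / sdv)
  u <- ifelse(ytrain == sort(unique(ytrain))[2], 1, -1)
  uc <- u - mean(u)
  w <- as.numeric(t(Z) %*% uc)
  w <- w / sqrt(sum(w^2))
  tt <- as.numeric(Z %*% w)
  q <- sum(tt * uc) / sum(tt * tt)
  Znew <- t((t(Xnew) - mu) / sdv)
  as.numeric(Znew %*% w) * q + mean(u)
}

# Exhaustive hypergeometric upper tail: P(overlap >= k) summed term by term
# from binomial coefficients.
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Tukey-Kramer pairwise p-value from first principles: group means, pooled
# within-group mean square, studentized-range distribution.
oracle_tukey_p <- function(groups, i, j) {
  ni <- lengths(groups)
  k <- length(groups)
  means <- vapply(groups, mean, 0)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) /
    (sum(ni) - k)
  se <- sqrt((mse / 2) * (1 / ni[i] + 1 / ni[j]))
  q <- abs(means[i] - means[j]) / se
  ptukey(q, k, sum(ni) - k, lower.tail = FALSE)
}

# Convenience: a small preprocessed + strain-corrected simulated study.
small_corrected_study <- function(seed, n_metabolites = 60,
                                  config = synthetic_config(
                                    n_metabolites = n_metabolites,
                                    n_diet_responsive =
                                      min(10, n_metabolites %/% 3),
                                    seed = seed)) {
  sim <- simulate_study(config)
  pp <- preprocess_abundance(sim$abundance)
  adj <- fit_and_correct(pp, sim$design, baseline = "CC011")
  list(sim = sim, pp = pp, adj = adj)
}
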