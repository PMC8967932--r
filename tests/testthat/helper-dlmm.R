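# Shared fixtures: everything is generated in code at test time.

rel_err <- function(a, b, floor = 1e-10) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# The worked 3-row site: X = [1 0; 1 1; 1 2], y = (1, 2, 3).
tiny_site <- function() {
  tibble::tibble(x1 = c(0, 1, 2), y = c(1, 2, 3))
}

# A randomized multi-site instance with continuous covariates; returns the
# simulation, its aggregates and the configuration.
random_instance <- function(seed, K = 4, n = 12, p = 3, q = 2,
                            re_var = NULL, sigma2 = 1) {
  stopifnot(q <= p)
  if (is.null(re_var)) re_var <- rep(0.5, q)
  beta <- seq(-1, 1, length.out = p)
  sim <- simulate_sites(
    n_sites = K, n_per_site = n, beta = beta,
    re_columns = seq_len(q), re_variances = re_var,
    sigma2 = sigma2, seed = seed
  )
  list(sim = sim, ads = aggregate_sites(sim$data),
       beta = beta, re_var = re_var, sigma2 = sigma2)
}

# Dense evaluation of one site's Gamma^{-1} products from raw X, y —
# independent of both package code paths (explicit inverse, base solve).
dense_products_raw <- function(X, y, re_idx, theta) {
  Z <- X[, re_idx, drop = FALSE]
  G <- Z %*% diag(theta, length(theta)) %*% t(Z) + diag(nrow(X))
  Gi <- solve(G)
  list(
    xgx = t(X) %*% Gi %*% X,
    xgy = drop(t(X) %*% Gi %*% y),
    ygy = drop(t(y) %*% Gi %*% y),
    zgx = t(Z) %*% Gi %*% X,
    zgy = drop(t(Z) %*% Gi %*% y),
    zgz = t(Z) %*% Gi %*% Z,
    logdet = as.numeric(determinant(G, logarithm = TRUE)$modulus)
  )
}

# Raw design matrix and outcome for one site of a simulation.
site_matrices <- function(sim, id, outcome = "y") {
  d <- sim$data[sim$data$site == id, , drop = FALSE]
  covs <- setdiff(names(d), c("site", outcome))
  X <- cbind(`(Intercept)` = 1, as.matrix(d[, covs, drop = FALSE]))
  list(X = X, y = d[[outcome]])
}
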