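test_that("theta = 0 reduces the Gamma products to the raw aggregates", {
  inst <- random_instance(seed = 1, K = 1, n = 10, p = 3, q = 2)
  ad <- inst$ads[[1]]
  gp <- gamma_products(ad, re = c(1, 2), theta = c(0, 0))
  expect_equal(unname(gp$xgx), unname(ad$sx), tolerance = 1e-14)
  expect_equal(unname(gp$xgy), unname(ad$sxy), tolerance = 1e-14)
  expect_equal(gp$ygy, ad$sy, tolerance = 1e-14)
  expect_equal(gp$logdet, 0)
})

test_that("random-intercept products match their scalar closed forms", {
  inst <- random_instance(seed = 2, K = 1, n = 15, p = 2, q = 1)
  ad <- inst$ads[[1]]
  theta <- 0.8
  n <- ad$n
  sum_y <- ad$sxy[["(Intercept)"]]
  gp <- gamma_products(ad, re = "(Intercept)", theta = theta)
  expect_equal(gp$logdet, log(1 + n * theta), tolerance = 1e-12)
  expect_equal(gp$ygy, ad$sy - theta / (1 + n * theta) * sum_y^2,
               tolerance = 1e-12)
})

test_that("Woodbury reconstruction equals dense inversion, zeros included", {
  # random 5 x 3 sites; includes boundary components theta_k = 0
  thetas <- list(c(0.5, 1.2), c(0, 0.7), c(0.3, 0), c(0, 0))
  for (s in 1:3) {
    inst <- random_instance(seed = 100 + s, K = 1, n = 5, p = 3, q = 2)
    ad <- inst$ads[[1]]
    m <- site_matrices(inst$sim, "site1")
    for (theta in thetas) {
      dense <- dense_products_raw(m$X, m$y, c(1, 2), theta)
      got <- gamma_products(ad, re = c(1, 2), theta = theta)
      for (f in c("xgx", "xgy", "ygy", "zgx", "zgy", "zgz")) {
        expect_lt(rel_err(unname(got[[f]]), unname(dense[[f]])), 1e-9)
      }
      expect_lt(abs(got$logdet - dense$logdet), 1e-9)
    }
  }
})

test_that("profiled beta reduces to pooled OLS and matches dense GLS", {
  inst <- random_instance(seed = 3, K = 3, n = 20, p = 3, q = 0)
  b0 <- profile_beta(inst$ads)
  sum_sx <- Reduce(`+`, lapply(inst$ads, `[[`, "sx"))
  sum_sxy <- Reduce(`+`, lapply(inst$ads, `[[`, "sxy"))
  expect_equal(unname(b0), unname(solve(sum_sx, sum_sxy)),
               tolerance = 1e-12)

  # exact-fit 3-row site: y = 1 + x
  expect_equal(unname(profile_beta(aggregate_site(tiny_site()))),
               c(1, 1), tolerance = 1e-12)

  # dense generalized least squares on stacked records at theta = 0.7
  theta <- 0.7
  bt <- profile_beta(inst$ads, re = "(Intercept)", theta = theta)
  A <- matrix(0, 3, 3); v <- numeric(3)
  for (id in names(inst$ads)) {
    m <- site_matrices(inst$sim, id)
    Gi <- solve(tcrossprod(rep(1, nrow(m$X))) * theta + diag(nrow(m$X)))
    A <- A + t(m$X) %*% Gi %*% m$X
    v <- v + drop(t(m$X) %*% Gi %*% m$y)
  }
  expect_lt(rel_err(unname(bt), drop(solve(A, v))), 1e-10)
})

test_that("profiled residual variance matches dense evaluation", {
  inst <- random_instance(seed = 4, K = 4, n = 10, p = 3, q = 2)
  theta <- c(0.3, 1.2)
  bt <- profile_beta(inst$ads, re = c(1, 2), theta = theta)
  s2 <- profile_sigma2(inst$ads, re = c(1, 2), theta = theta,
                       method = "ml")
  rss <- 0
  for (id in names(inst$ads)) {
    m <- site_matrices(inst$sim, id)
    Z <- m$X[, 1:2]
    Gi <- solve(Z %*% diag(theta) %*% t(Z) + diag(nrow(Z)))
    r <- m$y - drop(m$X %*% bt)
    rss <- rss + drop(t(r) %*% Gi %*% r)
  }
  expect_lt(rel_err(s2, rss / 40), 1e-10)

  # OLS reduction at theta = 0
  s20 <- profile_sigma2(inst$ads, method = "ml")
  X <- NULL; y <- NULL
  for (id in names(inst$ads)) {
    m <- site_matrices(inst$sim, id)
    X <- rbind(X, m$X); y <- c(y, m$y)
  }
  expect_lt(rel_err(s20, sum(stats::lm.fit(X, y)$residuals^2) / 40), 1e-10)

  # exact-fit data hit the degenerate-variance error path
  expect_error(profile_sigma2(aggregate_site(tiny_site())), "degenerate")
})

test_that("profile log-likelihood equals the dense pooled likelihood", {
  # direct evaluation of the marginal normal density on stacked records
  inst <- random_instance(seed = 5, K = 4, n = 8, p = 3, q = 2)
  for (theta in list(c(0.4, 0.9), c(0, 0.5))) {
    lp <- profile_loglik(inst$ads, re = c(1, 2), theta = theta,
                         method = "ml")
    bt <- profile_beta(inst$ads, re = c(1, 2), theta = theta)
    s2 <- profile_sigma2(inst$ads, re = c(1, 2), theta = theta,
                         method = "ml")
    ll <- 0
    for (id in names(inst$ads)) {
      m <- site_matrices(inst$sim, id)
      Z <- m$X[, 1:2]
      S <- s2 * (Z %*% diag(theta) %*% t(Z) + diag(nrow(Z)))
      r <- m$y - drop(m$X %*% bt)
      ll <- ll - 0.5 * (nrow(Z) * log(2 * pi) +
                          as.numeric(determinant(S)$modulus) +
                          drop(t(r) %*% solve(S) %*% r))
    }
    expect_lt(abs(lp - ll) / abs(ll), 1e-9)
  }

  # single site, theta = 0, ML: the OLS profile log-likelihood
  one <- random_instance(seed = 6, K = 1, n = 25, p = 2, q = 0)
  m <- site_matrices(one$sim, "site1")
  rss <- sum(stats::lm.fit(m$X, m$y)$residuals^2)
  expect_equal(profile_loglik(one$ads, method = "ml"),
               -0.5 * (25 * log(2 * pi) + 25 * log(rss / 25) + 25),
               tolerance = 1e-10)

  # invariance to site order
  inst2 <- random_instance(seed = 7, K = 5, n = 10, p = 3, q = 1)
  l1 <- profile_loglik(inst2$ads, re = 1, theta = 0.6)
  l2 <- profile_loglik(rev(inst2$ads), re = 1, theta = 0.6)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("balanced one-way REML fit equals the ANOVA closed forms", {
  K <- 30; n <- 20
  sim <- simulate_sites(n_sites = K, n_per_site = n, beta = 2,
                        re_columns = 1, re_variances = 0.5, sigma2 = 1,
                        seed = 5)
  fit <- dlmm(aggregate_sites(sim$data), re = "(Intercept)",
              method = "reml")
  d <- sim$data
  m_i <- tapply(d$y, d$site, mean)
  msb <- n * sum((m_i - mean(d$y))^2) / (K - 1)
  msw <- sum((d$y - m_i[d$site])^2) / (K * (n - 1))
  expect_equal(unname(fit$vc), (msb - msw) / n, tolerance = 1e-8)
  expect_equal(fit$sigma2, msw, tolerance = 1e-8)
})

test_that("homogeneous data drive theta to zero and beta to pooled OLS", {
  sim <- simulate_sites(n_sites = 20, n_per_site = 200, beta = c(1, 0.5),
                        re_columns = 1, re_variances = 0, sigma2 = 1,
                        seed = 17)
  ads <- aggregate_sites(sim$data)
  fit <- dlmm(ads, re = "(Intercept)", method = "reml")
  expect_lt(unname(fit$theta), 1e-6)
  ols <- solve(Reduce(`+`, lapply(ads, `[[`, "sx")),
               Reduce(`+`, lapply(ads, `[[`, "sxy")))
  expect_lt(max(abs(fit$beta - ols)), 1e-6)
})

test_that("aggregated fit equals the stacked-records fit (lossless)", {
  for (cfg in list(list(seed = 51, K = 2, n = 15, p = 3, q = 1,
                        method = "reml"),
                   list(seed = 52, K = 5, n = 12, p = 4, q = 2,
                        method = "ml"))) {
    inst <- random_instance(cfg$seed, K = cfg$K, n = cfg$n, p = cfg$p,
                            q = cfg$q)
    fd <- dlmm(inst$ads, re = seq_len(cfg$q), method = cfg$method)
    fp <- fit_pooled(inst$sim$data, re = seq_len(cfg$q),
                     method = cfg$method)
    expect_lt(rel_err(fd$beta, fp$beta), 1e-6)
    expect_lt(rel_err(fd$sigma2, fp$sigma2), 1e-6)
    expect_lt(max(abs(fd$vc - fp$vc)), 1e-6 * max(abs(fp$vc), 1))
    expect_lt(abs(fd$loglik - fp$loglik), 1e-6 * abs(fp$loglik))
  }
})

test_that("estimates agree with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  inst <- random_instance(seed = 61, K = 8, n = 30, p = 3, q = 2,
                          re_var = c(0.5, 0.3))
  for (method in c("reml", "ml")) {
    fit <- dlmm(inst$ads, re = c(1, 2), method = method)
    m <- lme4::lmer(y ~ x1 + x2 + (1 | site) + (0 + x1 | site),
                    data = inst$sim$data, REML = method == "reml")
    expect_equal(unname(fit$beta), unname(lme4::fixef(m)),
                 tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(m))$vcov
    expect_equal(unname(c(fit$vc, fit$sigma2)), vc, tolerance = 1e-3)
    expect_equal(fit$loglik, as.numeric(stats::logLik(m)),
                 tolerance = 1e-6)
  }
})

test_that("the literal per-site restricted objective is available", {
  inst <- random_instance(seed = 71, K = 4, n = 10, p = 2, q = 1)
  l_joint <- profile_loglik(inst$ads, re = 1, theta = 0.5,
                            method = "reml", reml_variant = "joint")
  l_lit <- profile_loglik(inst$ads, re = 1, theta = 0.5,
                          method = "reml", reml_variant = "per_site")
  expect_false(isTRUE(all.equal(l_joint, l_lit)))
  fit <- dlmm(inst$ads, re = 1, method = "reml",
              reml_variant = "per_site")
  fp <- fit_pooled(inst$sim$data, re = 1, method = "reml",
                   reml_variant = "per_site")
  expect_lt(rel_err(fit$vc, fp$vc, floor = 1e-6), 1e-6)
})

test_that("adding a site never shrinks the information matrix", {
  inst <- random_instance(seed = 81, K = 5, n = 10, p = 3, q = 1)
  theta <- 0.4
  min_eig <- function(ads) {
    prods <- lapply(ads, gamma_products, re = 1, theta = theta)
    s <- Reduce(`+`, lapply(prods, `[[`, "xgx"))
    min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  }
  eigs <- vapply(seq_along(inst$ads),
                 function(k) min_eig(inst$ads[seq_len(k)]), numeric(1))
  expect_true(all(diff(eigs) >= -1e-10))
})

test_that("the one-way profile likelihood is unimodal on a grid", {
  sim <- simulate_sites(n_sites = 25, n_per_site = 15, beta = 1,
                        re_columns = 1, re_variances = 0.6, sigma2 = 1,
                        seed = 91)
  ads <- aggregate_sites(sim$data)
  grid <- exp(seq(log(1e-4), log(50), length.out = 80))
  ll <- vapply(grid, function(th) {
    profile_loglik(ads, re = 1, theta = th, method = "ml")
  }, numeric(1))
  s <- sign(diff(ll))
  # once the likelihood starts decreasing it never rises again
  expect_lte(sum(diff(s) != 0), 1)
})

test_that("aggregates with permuted or mismatched columns are handled", {
  inst <- random_instance(seed = 95, K = 3, n = 12, p = 3, q = 1)
  ads <- inst$ads
  perm <- ads[[2]]
  o <- c(2, 1, 3)
  perm$sx <- perm$sx[o, o]
  perm$sxy <- perm$sxy[o]
  perm$columns <- perm$columns[o]
  mixed <- list(ads[[1]], perm, ads[[3]])
  expect_equal(profile_beta(mixed), profile_beta(ads), tolerance = 1e-12)

  alien <- ads[[2]]
  alien$columns <- c("(Intercept)", "x1", "zz")
  dimnames(alien$sx) <- list(alien$columns, alien$columns)
  names(alien$sxy) <- alien$columns
  expect_error(dlmm(list(ads[[1]], alien)), "column set")
})

test_that("rank-deficient pooled designs name the collinear columns", {
  d <- tibble::tibble(x1 = c(1, 2, 3, 4), x2 = c(2, 4, 6, 8),
                      y = c(1, 3, 2, 5))
  ad <- aggregate_site(d)
  expect_error(profile_beta(list(ad)), "collinear|rank deficient")
})
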