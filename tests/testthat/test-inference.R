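test_that("fixed-effect covariance reduces to OLS and matches dense algebra", {
  # single site, no random effects: sigma2 * (X'X)^{-1}
  inst <- random_instance(seed = 201, K = 1, n = 30, p = 3, q = 0)
  fit <- dlmm(inst$ads, re = integer(), method = "ml")
  v <- vcov_fixed(fit, "model")
  expect_lt(rel_err(v, fit$sigma2 * solve(inst$ads[[1]]$sx)), 1e-10)

  # random instance: both estimators against dense stacked-records algebra
  inst <- random_instance(seed = 202, K = 4, n = 12, p = 3, q = 2)
  fit <- dlmm(inst$ads, re = c(1, 2), method = "reml")
  theta <- unname(fit$theta)
  A <- matrix(0, 3, 3)
  meat <- matrix(0, 3, 3)
  for (id in names(inst$ads)) {
    m <- site_matrices(inst$sim, id)
    Z <- m$X[, 1:2]
    Gi <- solve(Z %*% diag(theta, 2) %*% t(Z) + diag(nrow(Z)))
    A <- A + t(m$X) %*% Gi %*% m$X
    sc <- drop(t(m$X) %*% Gi %*% (m$y - drop(m$X %*% fit$beta)))
    meat <- meat + tcrossprod(sc)
  }
  expect_lt(rel_err(unname(vcov_fixed(fit, "model")),
                    fit$sigma2 * solve(A)), 1e-8)
  expect_lt(rel_err(unname(vcov_fixed(fit, "sandwich")),
                    solve(A) %*% meat %*% solve(A)), 1e-8)
})

test_that("covariances are invariant to site order and theta-0 splits", {
  inst <- random_instance(seed = 203, K = 4, n = 15, p = 3, q = 1)
  f1 <- dlmm(inst$ads, re = 1, method = "ml")
  f2 <- dlmm(rev(inst$ads), re = 1, method = "ml")
  for (est in c("model", "sandwich")) {
    expect_lt(rel_err(vcov_fixed(f1, est), vcov_fixed(f2, est)), 1e-9)
  }

  # with no random effects, splitting one site's rows changes nothing
  d <- dplyr::filter(inst$sim$data, site == "site1")
  d$site[1:7] <- "site1a"
  whole <- dlmm(aggregate_sites(dplyr::filter(inst$sim$data,
                                              site == "site1")),
                re = integer(), method = "ml")
  split2 <- dlmm(aggregate_sites(d), re = integer(), method = "ml")
  expect_lt(rel_err(vcov_fixed(whole, "model"),
                    vcov_fixed(split2, "model")), 1e-10)
})

test_that("the Wald table applies the 1.96 convention exactly", {
  inst <- random_instance(seed = 204, K = 3, n = 20, p = 2, q = 1)
  fit <- dlmm(inst$ads, re = 1)
  td <- tidy(fit)
  expect_equal(td$conf.low, td$estimate - 1.96 * td$std.error,
               tolerance = 1e-15)
  expect_equal(td$conf.high, td$estimate + 1.96 * td$std.error,
               tolerance = 1e-15)
  # the two-sided normal p at z = 1.96 is 0.05 to 4 decimals
  expect_equal(round(2 * stats::pnorm(-1.96), 4), 0.05)
  expect_equal(td$p.value, 2 * stats::pnorm(-abs(td$statistic)),
               tolerance = 1e-15)
  expect_true(all(td$std.error > 0))
})

test_that("boundary LRT returns lr = 0, p = 1 when the candidate is inert", {
  # variance truly zero and large n: H1 collapses onto H0
  sim <- simulate_sites(n_sites = 10, n_per_site = 100, beta = c(1, 0.5),
                        re_columns = 1, re_variances = 0.5, sigma2 = 1,
                        seed = 205)
  t <- lrt_variance_component(aggregate_sites(sim$data), "x1",
                              method = "ml")
  if (t$lr < 1e-8) {
    expect_equal(t$p_value, 1)
  } else {
    expect_equal(t$p_value, 0.5 * stats::pchisq(t$lr, 1,
                                                lower.tail = FALSE))
  }
  expect_gte(t$lr, 0)
})

test_that("mixture p-value arithmetic matches the chi-square tail", {
  # lr = 3.841 is the 95th percentile of chi^2_1: mixture p = 0.025
  lr <- stats::qchisq(0.95, df = 1)
  p <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  expect_equal(p, 0.025, tolerance = 1e-10)
})

test_that("a strong variance component is detected with high power", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_sites(n_sites = 40, n_per_site = 50, beta = c(1, 0.5),
                          re_columns = c(1, 2), re_variances = c(0.5, 2),
                          sigma2 = 1, seed = 3000 + s)
    t <- lrt_variance_component(aggregate_sites(sim$data), "x1",
                                method = "ml")
    if (t$p_value < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("forward selection recovers the heterogeneous covariate", {
  # x2 carries a site-level random slope; x1 and x3 do not
  first_pick <- character(20)
  for (s in 1:20) {
    sim <- simulate_sites(n_sites = 40, n_per_site = 100,
                          beta = c(1, 0.5, -0.5, 0.25),
                          re_columns = c(1, 3), re_variances = c(0.5, 1),
                          sigma2 = 1, seed = 4000 + s)
    sel <- forward_select(aggregate_sites(sim$data),
                          candidate_columns = c("x1", "x2", "x3"),
                          alpha = 0.05, method = "ml")
    acc <- sel$trace[sel$trace$step == 1 & sel$trace$accepted, ]
    first_pick[s] <- if (nrow(acc)) acc$candidate else ""
  }
  expect_gte(mean(first_pick == "x2"), 0.9)
})

test_that("selection handles empty candidate sets and rejects intercept", {
  inst <- random_instance(seed = 206, K = 3, n = 20, p = 3, q = 1)
  sel <- forward_select(inst$ads, candidate_columns = character())
  expect_equal(nrow(sel$trace), 0)
  expect_identical(sel$final_re, "(Intercept)")
  expect_error(forward_select(inst$ads, candidate_columns = "(Intercept)"),
               "intercept")
})
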