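# Dense pooled-data reference implementation. This module works from the
# stacked individual records and evaluates every Gamma_i term by explicit
# n_i x n_i inversion — it deliberately shares none of the aggregated-data
# reconstruction (no Woodbury, no determinant lemma), so agreement between
# the two routes is evidence that the reconstruction is exact, not a
# tautology. It is a correctness instrument, O(sum n_i^3) by design.

pooled_design <- function(data, outcome, site, covariates = NULL,
                          intercept = TRUE) {
  data <- tibble::as_tibble(data)
  if (!site %in% names(data)) {
    stop("grouping column \"", site, "\" not found", call. = FALSE)
  }
  if (!outcome %in% names(data)) {
    stop("outcome column \"", outcome, "\" not found", call. = FALSE)
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c(outcome, site))
  }
  ids <- unique(as.character(data[[site]]))
  lapply(ids, function(id) {
    d <- data[data[[site]] == id, , drop = FALSE]
    X <- as.matrix(d[, covariates, drop = FALSE])
    storage.mode(X) <- "double"
    if (intercept) X <- cbind(`(Intercept)` = 1, X)
    list(site_id = id, X = X, y = as.numeric(d[[outcome]]))
  })
}

# One site's Gamma^{-1} products by explicit dense inversion.
dense_site_products <- function(X, y, re_idx, theta) {
  n <- nrow(X)
  q <- length(re_idx)
  Z <- X[, re_idx, drop = FALSE]
  if (q == 0L || all(theta == 0)) {
    return(list(
      xgx = crossprod(X), xgy = drop(crossprod(X, y)), ygy = sum(y^2),
      zgx = crossprod(Z, X), zgy = drop(crossprod(Z, y)),
      zgz = crossprod(Z), logdet = 0
    ))
  }
  G <- Z %*% (theta * t(Z)) + diag(n)
  Ginv <- solve(G)
  logdet <- as.numeric(determinant(G, logarithm = TRUE)$modulus)
  GX <- Ginv %*% X
  list(
    xgx = crossprod(X, GX),
    xgy = drop(crossprod(GX, y)),
    ygy = drop(crossprod(y, Ginv %*% y)),
    zgx = crossprod(Z, GX),
    zgy = drop(crossprod(Z, Ginv %*% y)),
    zgz = crossprod(Z, Ginv %*% Z),
    logdet = logdet
  )
}

pooled_objective <- function(sites, re_idx, theta, method, reml_variant) {
  p <- ncol(sites[[1L]]$X)
  n_i <- vapply(sites, function(s) length(s$y), numeric(1))
  N <- sum(n_i)
  prods <- lapply(sites, function(s) {
    dense_site_products(s$X, s$y, re_idx, theta)
  })
  s <- list(
    sum_xgx = Reduce(`+`, lapply(prods, `[[`, "xgx")),
    sum_xgy = Reduce(`+`, lapply(prods, `[[`, "xgy")),
    sum_ygy = Reduce(`+`, vapply(prods, `[[`, numeric(1), "ygy")),
    sum_logdet = Reduce(`+`, vapply(prods, `[[`, numeric(1), "logdet"))
  )
  persite <- NULL
  if (method == "reml" && reml_variant == "per_site") {
    persite <- vapply(prods, function(gp) {
      2 * sum(log(diag(chol(gp$xgx))))
    }, numeric(1))
  }
  res <- objective_from_sums(s, N, p, n_i, method, reml_variant, persite)
  res$prods <- prods
  res$sum_xgx <- s$sum_xgx
  res
}

#' Fit the pooled-data linear mixed model (dense reference)
#'
#' Direct maximum-likelihood / REML fit on the stacked individual records,
#' evaluating every \eqn{\Gamma_i^{-1}} and \eqn{\log|\Gamma_i|} by dense
#' \eqn{n_i \times n_i} linear algebra. Shares the optimizer and the
#' profiling algebra with [dlmm()] but none of the aggregated-data
#' reconstruction, so equality between the two fits demonstrates the
#' lossless property. Intended for verification at small problem sizes.
#'
#' @param data stacked records: a data frame with a site column, covariate
#'   columns and the outcome.
#' @param outcome,site column names (defaults `"y"`, `"site"`).
#' @param covariates optional covariate selection/order.
#' @inheritParams dlmm
#' @return An object of class `dlmm_pooled_fit` (also usable with
#'   [vcov_fixed()], [tidy.dlmm_fit()], [dlmm_blup()]), with the same
#'   fields as a `dlmm_fit`.
#' @examples
#' sim <- simulate_sites(n_sites = 4, n_per_site = 15, beta = c(1, -1),
#'                       re_columns = 1, re_variances = 0.3, sigma2 = 1,
#'                       seed = 3)
#' fp <- fit_pooled(sim$data, re = "(Intercept)")
#' fd <- dlmm(aggregate_sites(sim$data), re = "(Intercept)")
#' all.equal(fp$beta, fd$beta, tolerance = 1e-8)
#' @export
fit_pooled <- function(data, outcome = "y", site = "site",
                       covariates = NULL, re = "(Intercept)",
                       method = c("reml", "ml"),
                       reml_variant = c("joint", "per_site")) {
  method <- match.arg(method)
  reml_variant <- match.arg(reml_variant)
  sites <- pooled_design(data, outcome, site, covariates)
  columns <- colnames(sites[[1L]]$X)
  idx <- resolve_re(re, columns)
  q <- length(idx)
  n_i <- vapply(sites, function(s) length(s$y), numeric(1))
  N <- sum(n_i)
  p <- length(columns)
  if (N <= p) stop("need more observations than fixed effects",
                   call. = FALSE)

  if (q == 0L) {
    res <- pooled_objective(sites, idx, numeric(), method, reml_variant)
    opt <- list(theta = numeric(), value = -res$ll, converged = TRUE)
  } else {
    negobj <- function(theta) {
      -pooled_objective(sites, idx, theta, method, reml_variant)$ll
    }
    neggrad <- if (method == "ml" || reml_variant == "joint") {
      function(theta) {
        res <- pooled_objective(sites, idx, theta, method, reml_variant)
        cc <- if (method == "reml") N - p else N
        bread <- if (method == "reml") chol2inv(chol(res$sum_xgx))
        -grad_from_products(res$prods, res$beta, res$rss, cc, bread)
      }
    }
    opt <- optimize_theta(negobj, q, neggrad)
    res <- pooled_objective(sites, idx, opt$theta, method, reml_variant)
    if (!opt$converged) {
      warning("pooled optimizer did not report convergence", call. = FALSE)
    }
  }
  products <- purrr::map2(res$prods, seq_along(sites), function(gp, i) {
    gp$site_id <- sites[[i]]$site_id
    gp$n <- n_i[i]
    gp
  })
  re_names <- columns[idx]
  structure(
    list(
      products = products,
      sum_xgx = res$sum_xgx,
      beta = stats::setNames(res$beta, columns),
      sigma2 = res$sigma2,
      theta = stats::setNames(opt$theta, re_names),
      vc = stats::setNames(res$sigma2 * opt$theta, re_names),
      loglik = res$ll,
      method = method,
      reml_variant = reml_variant,
      converged = opt$converged,
      n_total = N,
      n_sites = length(sites),
      re = re_names,
      re_idx = idx,
      columns = columns
    ),
    class = c("dlmm_pooled_fit", "dlmm_fit")
  )
}

#' Brute-force BLUP oracle by joint-Gaussian conditioning
#'
#' Builds, per site, the joint normal distribution of \eqn{(u_i, y_i)} at
#' the fitted parameters —
#' \eqn{y_i \sim N(X_i\hat\beta, \hat\sigma^2\Gamma_i)},
#' \eqn{\mathrm{Cov}(u_i, y_i) = \hat V Z_i'} — and returns the
#' conditional mean \eqn{E[u_i \mid y_i]} and conditional covariance
#' \eqn{\mathrm{Var}(u_i \mid y_i)} by block conditioning. The conditional
#' mean is an independent derivation of the BLUP; the conditional
#' covariance treats \eqn{\hat\beta} as known (it omits the
#' fixed-effect-estimation term that the prediction covariance of
#' [dlmm_blup()] includes).
#'
#' @param data stacked records, as in [fit_pooled()].
#' @param fit a fitted model (`dlmm_fit` or `dlmm_pooled_fit`).
#' @inheritParams fit_pooled
#' @return Named list per site: `mean` (length q), `cov` (q x q).
#' @export
brute_force_blup <- function(data, fit, outcome = "y", site = "site",
                             covariates = NULL) {
  sites <- pooled_design(data, outcome, site, covariates)
  columns <- colnames(sites[[1L]]$X)
  stopifnot(identical(columns, fit$columns))
  idx <- fit$re_idx
  theta <- unname(fit$theta)
  sigma2 <- fit$sigma2
  Vhat <- diag(sigma2 * theta, length(theta))
  beta <- unname(fit$beta)
  out <- lapply(sites, function(s) {
    Z <- s$X[, idx, drop = FALSE]
    n <- nrow(Z)
    Sy <- sigma2 * (Z %*% (theta * t(Z)) + diag(n))
    Cuy <- Vhat %*% t(Z)
    Syi <- tryCatch(solve(Sy), error = function(e) {
      stop("singular marginal covariance for site ", s$site_id,
           call. = FALSE)
    })
    r <- s$y - drop(s$X %*% beta)
    list(
      mean = stats::setNames(drop(Cuy %*% Syi %*% r), fit$re),
      cov = Vhat - Cuy %*% Syi %*% t(Cuy)
    )
  })
  names(out) <- vapply(sites, `[[`, character(1), "site_id")
  out
}
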