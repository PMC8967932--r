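#' Best linear unbiased predictors of the site random effects
#'
#' Computes, for every site, the BLUP
#' \eqn{\hat u_i = \hat\Theta Z_i' \Gamma_i(\hat\Theta)^{-1}
#' (y_i - X_i\hat\beta)}, assembled purely from the aggregated products as
#' \eqn{\hat\Theta\{Z_i'\Gamma_i^{-1}y_i -
#' (Z_i'\Gamma_i^{-1}X_i)\hat\beta\}}, together with two covariances:
#' \describe{
#'   \item{`cond_cov`}{\eqn{\mathrm{Var}(\hat u_i \mid X_i)} — the
#'     variance of the predictor itself,
#'     \eqn{\hat\sigma^2\{\hat\Theta Z_i'\Gamma_i^{-1}Z_i\hat\Theta -
#'     \hat\Theta Z_i'\Gamma_i^{-1}X_i
#'     (\sum_j X_j'\Gamma_j^{-1}X_j)^{-1}
#'     X_i'\Gamma_i^{-1}Z_i\hat\Theta\}}.}
#'   \item{`pred_cov`}{\eqn{\mathrm{Var}(\hat u_i - u_i) =
#'     \hat V - \mathrm{Var}(\hat u_i \mid X_i)} — the prediction-error
#'     covariance, the appropriate width for intervals about the realised
#'     \eqn{u_i}.}
#' }
#' The reported site-specific effect is the fixed effect plus the BLUP for
#' each random-effect column, with 95% prediction intervals
#' `site_effect +/- 1.96 * sqrt(diag(pred_cov))`.
#'
#' A variance component estimated as exactly zero yields zero predictions
#' and zero covariance rows for that component. Note that BLUPs are
#' site-identifying by construction: treat them as sensitive output when
#' the random-effect covariates are sensitive characteristics.
#'
#' @param fit a converged `dlmm_fit` with at least one random effect.
#' @return An object of class `dlmm_blup`: a list with `sites` (named list
#'   per site of `u_hat`, `cond_cov`, `pred_cov`, `site_effect`,
#'   `pi_low`, `pi_high`), plus `re`, `vc`, `fixed`. Use [tidy.dlmm_blup()]
#'   for a flat table and [autoplot.dlmm_blup()] for a caterpillar plot.
#' @examples
#' sim <- simulate_sites(n_sites = 8, n_per_site = 30, beta = c(1, 0.5),
#'                       re_columns = 1, re_variances = 0.4, sigma2 = 1,
#'                       seed = 11)
#' fit <- dlmm(aggregate_sites(sim$data), re = "(Intercept)")
#' head(tidy(dlmm_blup(fit)))
#' @export
dlmm_blup <- function(fit) {
  stopifnot(inherits(fit, c("dlmm_fit", "dlmm_pooled_fit")))
  q <- length(fit$theta)
  if (q == 0L) {
    stop("fit has no random effects; nothing to predict", call. = FALSE)
  }
  theta <- unname(fit$theta)
  sigma2 <- fit$sigma2
  Vhat <- diag(sigma2 * theta, q)
  bread <- chol2inv(chol(fit$sum_xgx))
  beta <- unname(fit$beta)
  fixed_part <- beta[fit$re_idx]

  sites <- lapply(fit$products, function(gp) {
    u_hat <- theta * drop(gp$zgy - gp$zgx %*% beta)
    TZ <- theta * gp$zgz * rep(theta, each = q)     # Theta zgz Theta
    TX <- theta * gp$zgx                            # Theta zgx (q x p)
    cond_cov <- sigma2 * (TZ - TX %*% bread %*% t(TX))
    cond_cov <- (cond_cov + t(cond_cov)) / 2
    pred_cov <- Vhat - cond_cov
    pred_cov <- (pred_cov + t(pred_cov)) / 2
    site_effect <- fixed_part + u_hat
    pe <- sqrt(pmax(diag(pred_cov), 0))
    list(u_hat = stats::setNames(u_hat, fit$re),
         cond_cov = cond_cov, pred_cov = pred_cov,
         site_effect = stats::setNames(site_effect, fit$re),
         pi_low = site_effect - 1.96 * pe,
         pi_high = site_effect + 1.96 * pe)
  })
  names(sites) <- vapply(fit$products, `[[`, character(1), "site_id")
  structure(
    list(sites = sites, re = fit$re,
         vc = stats::setNames(sigma2 * theta, fit$re),
         fixed = stats::setNames(fixed_part, fit$re)),
    class = "dlmm_blup"
  )
}

#' Tidy per-site random-effect predictions
#'
#' @param x a `dlmm_blup`.
#' @param ... unused.
#' @return A tibble with one row per site and random-effect term:
#'   `site`, `term`, `u_hat`, `site_effect`, `cond.se`, `pred.se`,
#'   `pi.low`, `pi.high`.
#' @method tidy dlmm_blup
#' @export
tidy.dlmm_blup <- function(x, ...) {
  purrr::imap(x$sites, function(s, id) {
    tibble::tibble(
      site = id,
      term = x$re,
      u_hat = unname(s$u_hat),
      site_effect = unname(s$site_effect),
      cond.se = sqrt(pmax(diag(s$cond_cov), 0)),
      pred.se = sqrt(pmax(diag(s$pred_cov), 0)),
      pi.low = unname(s$pi_low),
      pi.high = unname(s$pi_high)
    )
  }) |>
    dplyr::bind_rows()
}

#' @export
print.dlmm_blup <- function(x, ...) {
  cat("Per-site BLUPs for", length(x$re), "random effect(s) across",
      length(x$sites), "sites\n")
  cat("(site-identifying output; handle according to your data-sharing",
      "protocol)\n\n")
  print(tidy.dlmm_blup(x))
  invisible(x)
}
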