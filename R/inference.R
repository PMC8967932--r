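#' Covariance of the estimated fixed effects
#'
#' Model-based estimator
#' \eqn{\hat\sigma^2 (\sum_i X_i'\Gamma_i^{-1}X_i)^{-1}}, or the
#' cluster-robust sandwich estimator
#' \deqn{(\textstyle\sum_i X_i'\Gamma_i^{-1}X_i)^{-1}
#'   \{\textstyle\sum_i (X_i'\Gamma_i^{-1}r_i)(X_i'\Gamma_i^{-1}r_i)'\}
#'   (\textstyle\sum_i X_i'\Gamma_i^{-1}X_i)^{-1},}
#' with \eqn{r_i = y_i - X_i\hat\beta}. Both are assembled purely from the
#' per-site aggregated products: the site score is
#' \eqn{X_i'\Gamma_i^{-1}r_i = X_i'\Gamma_i^{-1}y_i -
#' (X_i'\Gamma_i^{-1}X_i)\hat\beta}.
#'
#' @param fit a `dlmm_fit` (or pooled reference fit).
#' @param estimator `"model"` or `"sandwich"`.
#' @return p x p symmetric positive-definite matrix with dimnames.
#' @export
vcov_fixed <- function(fit, estimator = c("model", "sandwich")) {
  estimator <- match.arg(estimator)
  stopifnot(!is.null(fit$products))
  bread <- chol2inv(chol(fit$sum_xgx))
  v <- if (estimator == "model") {
    fit$sigma2 * bread
  } else {
    meat <- Reduce(`+`, lapply(fit$products, function(gp) {
      score <- gp$xgy - drop(gp$xgx %*% fit$beta)
      tcrossprod(score)
    }))
    bread %*% meat %*% bread
  }
  v <- (v + t(v)) / 2
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("fixed-effect covariance is not positive semi-definite",
         call. = FALSE)
  }
  dimnames(v) <- list(fit$columns, fit$columns)
  v
}

#' Tidy the fixed effects of a fitted model
#'
#' One row per fixed effect with the Wald machinery: standard error, 95%
#' confidence interval `estimate +/- 1.96 * std.error`, z statistic and
#' two-sided normal p-value.
#'
#' @param x a `dlmm_fit`.
#' @param estimator covariance estimator passed to [vcov_fixed()].
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `statistic`, `p.value`, `estimator`.
#' @method tidy dlmm_fit
#' @export
tidy.dlmm_fit <- function(x, estimator = c("model", "sandwich"), ...) {
  estimator <- match.arg(estimator)
  v <- vcov_fixed(x, estimator)
  se <- sqrt(diag(v))
  z <- x$beta / se
  tibble::tibble(
    term = x$columns,
    estimate = unname(x$beta),
    std.error = unname(se),
    conf.low = unname(x$beta - 1.96 * se),
    conf.high = unname(x$beta + 1.96 * se),
    statistic = unname(z),
    p.value = unname(2 * stats::pnorm(-abs(z))),
    estimator = estimator
  )
}

#' One-line model summary
#'
#' @param x a `dlmm_fit`.
#' @param ... unused.
#' @return A one-row tibble: `n_sites`, `n_total`, `p`, `q`, `sigma2`,
#'   `logLik`, `method`, `converged`.
#' @method glance dlmm_fit
#' @export
glance.dlmm_fit <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites,
    n_total = x$n_total,
    p = length(x$beta),
    q = length(x$theta),
    sigma2 = x$sigma2,
    logLik = x$loglik,
    method = x$method,
    converged = x$converged
  )
}

#' Likelihood-ratio test for one variance component
#'
#' Tests whether a candidate design column carries a site-level random
#' effect, on top of a base specification that always retains the random
#' intercept. The statistic is
#' \eqn{LR = -2\{\sup_{H_0} L - \sup_{H_1} L\}}; because the null value
#' \eqn{\sigma_k^2 = 0} sits on the boundary of the parameter space, the
#' null distribution is the 50:50 mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1}, so the p-value is 1 when
#' \eqn{LR = 0} and \eqn{\tfrac12 P(\chi^2_1 \ge LR)} otherwise.
#'
#' Both constrained fits use the full reconstructed likelihood, so the test
#' is identical to its pooled-data counterpart. ML likelihoods are the
#' default; REML-based LR is available but compares restricted likelihoods
#' whose fixed-effect adjustment is shared under the common design, a
#' documented caveat.
#'
#' @inheritParams dlmm
#' @param candidate the design column to test (name or index); must not be
#'   in `base_re`.
#' @param base_re the null specification, containing the random intercept.
#' @return An object of class `dlmm_lrt`: list with `lr`, `p_value`,
#'   `component_tested`, `df_mixture`, `fit0`, `fit1`.
#' @export
lrt_variance_component <- function(ads, candidate,
                                   base_re = "(Intercept)",
                                   method = c("ml", "reml")) {
  method <- match.arg(method)
  ads <- align_ads(ads)
  columns <- ads[[1L]]$columns
  base_idx <- resolve_re(base_re, columns)
  cand_idx <- resolve_re(candidate, columns)
  if (length(cand_idx) != 1L) {
    stop("`candidate` must be a single column", call. = FALSE)
  }
  if (cand_idx %in% base_idx) {
    stop("candidate column is already in the base specification",
         call. = FALSE)
  }
  fit0 <- dlmm(ads, re = base_idx, method = method)
  fit1 <- dlmm(ads, re = c(base_idx, cand_idx), method = method)
  lr <- 2 * (fit1$loglik - fit0$loglik)
  if (lr < 0) {
    if (lr < -1e-6) {
      warning("likelihood ratio was negative (", format(lr),
              "); clamped to 0 — optimizer noise above tolerance",
              call. = FALSE)
    }
    lr <- 0
  }
  p_value <- if (lr < 1e-8) 1 else 0.5 * stats::pchisq(lr, df = 1,
                                                       lower.tail = FALSE)
  structure(
    list(lr = lr, p_value = p_value,
         component_tested = columns[cand_idx],
         df_mixture = "0.5*chisq_0 + 0.5*chisq_1",
         method = method, fit0 = fit0, fit1 = fit1),
    class = "dlmm_lrt"
  )
}

#' @export
print.dlmm_lrt <- function(x, ...) {
  cat("Variance-component likelihood-ratio test (", toupper(x$method),
      ")\n", sep = "")
  cat("  component:", x$component_tested, "\n")
  cat("  LR =", format(x$lr, digits = 6),
      "  null: 50:50 mixture of chi^2_0 and chi^2_1\n")
  cat("  p-value =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' @method tidy dlmm_lrt
#' @export
tidy.dlmm_lrt <- function(x, ...) {
  tibble::tibble(term = x$component_tested, lr = x$lr,
                 p.value = x$p_value, method = x$method)
}

#' Forward selection of random effects by boundary LRT
#'
#' Starting from a random-intercept-only model, repeatedly tests every
#' remaining candidate column with [lrt_variance_component()] against the
#' current specification and admits the one with the smallest mixture
#' p-value while it is below `alpha`. Ties break on larger LR, then lower
#' column index. No multiplicity correction is applied; the trace records
#' every test so users can adjust.
#'
#' @inheritParams lrt_variance_component
#' @param candidate_columns candidate design columns (names or indices);
#'   the intercept is not a valid candidate.
#' @param alpha admission threshold on the mixture p-value (default 0.05).
#' @return An object of class `dlmm_selection`: list with `trace` (tibble
#'   of `step`, `candidate`, `lr`, `p.value`, `accepted`), `final_re`
#'   (selected columns, intercept first), `alpha`, `n_tests`.
#' @export
forward_select <- function(ads, candidate_columns, alpha = 0.05,
                           method = c("ml", "reml")) {
  method <- match.arg(method)
  ads <- align_ads(ads)
  columns <- ads[[1L]]$columns
  cand_idx <- resolve_re(candidate_columns, columns)
  if (1L %in% cand_idx) {
    stop("the intercept is always retained and cannot be a candidate",
         call. = FALSE)
  }
  current <- 1L
  remaining <- cand_idx
  trace <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    tests <- lapply(remaining, function(j) {
      t <- lrt_variance_component(ads, candidate = j, base_re = current,
                                  method = method)
      tibble::tibble(step = step, candidate = columns[j], column = j,
                     lr = t$lr, p.value = t$p_value, accepted = FALSE)
    })
    tests <- dplyr::bind_rows(tests)
    ord <- order(tests$p.value, -tests$lr, tests$column)
    best <- ord[1L]
    if (tests$p.value[best] < alpha) {
      tests$accepted[best] <- TRUE
      current <- c(current, tests$column[best])
      remaining <- setdiff(remaining, tests$column[best])
      trace[[step]] <- tests
    } else {
      trace[[step]] <- tests
      break
    }
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else {
    tibble::tibble(step = integer(), candidate = character(),
                   column = integer(), lr = numeric(), p.value = numeric(),
                   accepted = logical())
  }
  structure(
    list(trace = dplyr::select(trace, -"column"),
         final_re = columns[current], alpha = alpha, method = method,
         n_tests = nrow(trace)),
    class = "dlmm_selection"
  )
}

#' @export
print.dlmm_selection <- function(x, ...) {
  cat("Forward selection of random effects (alpha = ", x$alpha, ", ",
      toupper(x$method), " likelihood, ", x$n_tests, " tests)\n", sep = "")
  cat("  selected:", paste(x$final_re, collapse = ", "), "\n")
  if (nrow(x$trace)) print(x$trace)
  invisible(x)
}

#' @method tidy dlmm_selection
#' @export
tidy.dlmm_selection <- function(x, ...) x$trace
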