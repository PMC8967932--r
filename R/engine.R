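#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Internal engine: reconstruct every Gamma_i^{-1} quantity the mixed-model
# likelihood needs from the aggregated cross-products alone.
#
# With Gamma_i = Z_i Theta Z_i' + I and Z the re-columns of X, the Woodbury
# identity gives, for any A, B among {X, Z, y},
#     A' Gamma^{-1} B = A'B - (A'Z) M (Z'B),
#     M = Theta (I_q + Z'Z Theta)^{-1},
# and the determinant lemma gives |Gamma_i| = |I_q + Z'Z Theta|.
# A'B, A'Z, Z'B, Z'Z are all sub-blocks of SX / SXy / sy, so the pooled
# objective is an exact function of the shared aggregates. M is evaluated in
# the symmetric push-through form
#     M = Theta^{1/2} (I + Theta^{1/2} Z'Z Theta^{1/2})^{-1} Theta^{1/2},
# which is defined (and exact) at theta_k = 0, unlike the textbook
# Theta^{-1} form.
# ---------------------------------------------------------------------------

# Align a list of ADs to the first site's column order; error on mismatch.
align_ads <- function(ads) {
  if (!length(ads)) stop("no aggregated data supplied", call. = FALSE)
  if (inherits(ads, "dlmm_ad")) ads <- list(ads)
  lapply(ads, function(ad) stopifnot(inherits(ad, "dlmm_ad")))
  ref <- ads[[1L]]$columns
  lapply(ads, function(ad) {
    if (!setequal(ad$columns, ref) || length(ad$columns) != length(ref)) {
      stop("site \"", ad$site_id, "\" has design columns {",
           paste(ad$columns, collapse = ", "), "} but site \"",
           ads[[1L]]$site_id, "\" has {", paste(ref, collapse = ", "),
           "}; aggregated data must share one column set", call. = FALSE)
    }
    if (!identical(ad$columns, ref)) {
      o <- match(ref, ad$columns)
      ad$sx <- ad$sx[o, o, drop = FALSE]
      ad$sxy <- ad$sxy[o]
      ad$columns <- ref
    }
    ad
  })
}

# Resolve a random-effect specification (names or indices) against columns.
resolve_re <- function(re, columns) {
  if (is.character(re)) {
    idx <- match(re, columns)
    if (anyNA(idx)) {
      stop("unknown random-effect columns: ",
           paste(re[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(re)
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(columns))) {
      stop("random-effect column indices out of range", call. = FALSE)
    }
  }
  if (anyDuplicated(idx)) {
    stop("duplicated random-effect columns", call. = FALSE)
  }
  idx
}

# Precompute the per-site blocks the objective reuses at every theta.
engine_prepare <- function(ads, re_idx) {
  ads <- align_ads(ads)
  p <- length(ads[[1L]]$columns)
  q <- length(re_idx)
  K <- length(ads)
  n <- vapply(ads, `[[`, numeric(1), "n")
  sy <- vapply(ads, `[[`, numeric(1), "sy")
  sum_sx <- Reduce(`+`, lapply(ads, `[[`, "sx"))
  sum_sxy <- Reduce(`+`, lapply(ads, `[[`, "sxy"))
  prep <- list(
    ads = ads, p = p, q = q, K = K, n = n, N = sum(n), sy = sy,
    sum_sx = unname(sum_sx), sum_sxy = unname(sum_sxy),
    sum_sy = sum(sy), re_idx = re_idx,
    columns = ads[[1L]]$columns
  )
  if (q == 0L) return(prep)
  prep$ZZ <- lapply(ads, function(ad) {
    unname(ad$sx[re_idx, re_idx, drop = FALSE])
  })
  prep$XZ <- lapply(ads, function(ad) {
    unname(ad$sx[, re_idx, drop = FALSE])
  })
  prep$ZY <- lapply(ads, function(ad) unname(ad$sxy[re_idx]))
  if (q == 1L) {
    prep$zz1 <- vapply(prep$ZZ, function(m) m[1L, 1L], numeric(1))
    prep$xz1 <- do.call(rbind, lapply(prep$XZ, function(m) m[, 1L]))
    prep$zy1 <- vapply(prep$ZY, `[[`, numeric(1), 1L)
  } else if (q == 2L) {
    prep$zz11 <- vapply(prep$ZZ, function(m) m[1L, 1L], numeric(1))
    prep$zz12 <- vapply(prep$ZZ, function(m) m[1L, 2L], numeric(1))
    prep$zz22 <- vapply(prep$ZZ, function(m) m[2L, 2L], numeric(1))
    prep$XZ1 <- do.call(rbind, lapply(prep$XZ, function(m) m[, 1L]))
    prep$XZ2 <- do.call(rbind, lapply(prep$XZ, function(m) m[, 2L]))
    prep$zy_1 <- vapply(prep$ZY, `[[`, numeric(1), 1L)
    prep$zy_2 <- vapply(prep$ZY, `[[`, numeric(1), 2L)
  }
  prep
}

# Summed Gamma^{-1} products at a given theta: sum_xgx (p x p), sum_xgy (p),
# sum_ygy, sum_logdet. Vectorised closed forms for q in {1, 2}; generic
# per-site loop otherwise. The two paths agree to machine precision (tested).
engine_sums <- function(prep, theta) {
  p <- prep$p
  q <- prep$q
  if (q == 0L || all(theta == 0)) {
    return(list(sum_xgx = prep$sum_sx, sum_xgy = prep$sum_sxy,
                sum_ygy = prep$sum_sy, sum_logdet = 0))
  }
  if (q == 1L) {
    th <- theta[1L]
    m <- th / (1 + th * prep$zz1)
    sum_xgx <- prep$sum_sx - crossprod(prep$xz1, prep$xz1 * m)
    sum_xgy <- prep$sum_sxy - colSums(prep$xz1 * (m * prep$zy1))
    sum_ygy <- prep$sum_sy - sum(m * prep$zy1^2)
    return(list(sum_xgx = sum_xgx, sum_xgy = sum_xgy, sum_ygy = sum_ygy,
                sum_logdet = sum(log1p(th * prep$zz1))))
  }
  if (q == 2L) {
    t1 <- theta[1L]; t2 <- theta[2L]
    d <- (1 + t1 * prep$zz11) * (1 + t2 * prep$zz22) -
      t1 * t2 * prep$zz12^2
    m11 <- t1 * (1 + t2 * prep$zz22) / d
    m12 <- -t1 * t2 * prep$zz12 / d
    m22 <- t2 * (1 + t1 * prep$zz11) / d
    XZ1 <- prep$XZ1; XZ2 <- prep$XZ2
    sum_xgx <- prep$sum_sx -
      crossprod(XZ1, XZ1 * m11) -
      crossprod(XZ1, XZ2 * m12) - crossprod(XZ2, XZ1 * m12) -
      crossprod(XZ2, XZ2 * m22)
    w1 <- m11 * prep$zy_1 + m12 * prep$zy_2
    w2 <- m12 * prep$zy_1 + m22 * prep$zy_2
    sum_xgy <- prep$sum_sxy - colSums(XZ1 * w1) - colSums(XZ2 * w2)
    sum_ygy <- prep$sum_sy -
      sum(m11 * prep$zy_1^2 + 2 * m12 * prep$zy_1 * prep$zy_2 +
            m22 * prep$zy_2^2)
    return(list(sum_xgx = sum_xgx, sum_xgy = sum_xgy, sum_ygy = sum_ygy,
                sum_logdet = sum(log(d))))
  }
  sum_xgx <- matrix(0, p, p)
  sum_xgy <- numeric(p)
  sum_ygy <- 0
  sum_logdet <- 0
  for (i in seq_len(prep$K)) {
    gp <- gamma_core(prep$ZZ[[i]], prep$XZ[[i]], prep$ZY[[i]],
                     unname(prep$ads[[i]]$sx), unname(prep$ads[[i]]$sxy),
                     prep$sy[i], theta)
    sum_xgx <- sum_xgx + gp$xgx
    sum_xgy <- sum_xgy + gp$xgy
    sum_ygy <- sum_ygy + gp$ygy
    sum_logdet <- sum_logdet + gp$logdet
  }
  list(sum_xgx = sum_xgx, sum_xgy = sum_xgy, sum_ygy = sum_ygy,
       sum_logdet = sum_logdet)
}

# One site's full set of Gamma^{-1} products at theta (generic q).
gamma_core <- function(ZZ, XZ, ZY, sx, sxy, sy, theta) {
  q <- length(theta)
  if (q == 0L) {
    return(list(xgx = sx, xgy = sxy, ygy = sy,
                zgx = matrix(0, 0, nrow(sx)), zgy = numeric(),
                zgz = matrix(0, 0, 0), logdet = 0))
  }
  d <- sqrt(theta)
  B <- d * ZZ * rep(d, each = q)              # Theta^{1/2} Z'Z Theta^{1/2}
  IB <- diag(q) + B
  C <- tryCatch(chol(IB), error = function(e) {
    stop("I + Z'Z Theta is numerically singular; aggregated data are ",
         "corrupted", call. = FALSE)
  })
  Tm <- chol2inv(C)
  M <- d * Tm * rep(d, each = q)              # Theta (I + Z'Z Theta)^{-1}
  XZM <- XZ %*% M                             # p x q
  list(
    xgx = sx - XZM %*% t(XZ),
    xgy = drop(sxy - XZM %*% ZY),
    ygy = sy - drop(crossprod(ZY, M %*% ZY)),
    zgx = t(XZ) - ZZ %*% M %*% t(XZ),         # q x p: Z'Gamma^{-1}X
    zgy = drop(ZY - ZZ %*% M %*% ZY),
    zgz = ZZ - ZZ %*% M %*% ZZ,
    logdet = 2 * sum(log(diag(C)))
  )
}

#' Per-site Gamma-inverse products from aggregated data
#'
#' Evaluates, for one site and a given variance-ratio vector
#' \eqn{\theta = \mathrm{diag}(V)/\sigma^2}, every quadratic form in
#' \eqn{\Gamma^{-1} = (Z\Theta Z' + I)^{-1}} that the mixed-model
#' likelihood, covariance and BLUP formulas need — using only the shared
#' aggregates, never the row-level data. `theta = 0` reduces exactly to the
#' raw cross-products with `logdet = 0`.
#'
#' @param ad a `dlmm_ad` object.
#' @param re random-effect design columns (names or indices).
#' @param theta non-negative numeric vector, one entry per `re` column.
#' @return A list with `xgx` (\eqn{X'\Gamma^{-1}X}), `xgy`
#'   (\eqn{X'\Gamma^{-1}y}), `ygy` (\eqn{y'\Gamma^{-1}y}), `zgx`, `zgy`,
#'   `zgz` (the same with \eqn{Z} on the left/both sides) and `logdet`
#'   (\eqn{\log|\Gamma|}).
#' @examples
#' d <- tibble::tibble(x1 = rnorm(8), y = rnorm(8))
#' ad <- aggregate_site(d)
#' gamma_products(ad, re = "(Intercept)", theta = 0.5)$logdet
#' @export
gamma_products <- function(ad, re, theta) {
  stopifnot(inherits(ad, "dlmm_ad"))
  idx <- resolve_re(re, ad$columns)
  theta <- as.numeric(theta)
  if (length(theta) != length(idx) || any(!is.finite(theta)) ||
      any(theta < 0)) {
    stop("`theta` must be non-negative, one entry per random-effect column",
         call. = FALSE)
  }
  gamma_core(unname(ad$sx[idx, idx, drop = FALSE]),
             unname(ad$sx[, idx, drop = FALSE]),
             unname(ad$sxy[idx]),
             unname(ad$sx), unname(ad$sxy), ad$sy, theta)
}

# Solve sum_xgx %*% beta = sum_xgy by Cholesky; name collinear columns on
# rank deficiency (smallest-eigenvalue heuristic); pseudo-inverse fallback
# only for near-singular-but-consistent systems is NOT attempted here.
solve_beta <- function(sum_xgx, sum_xgy, columns) {
  C <- tryCatch(chol(sum_xgx), error = function(e) NULL)
  if (is.null(C)) {
    e <- eigen((sum_xgx + t(sum_xgx)) / 2, symmetric = TRUE)
    v <- abs(e$vectors[, length(e$values)])
    bad <- columns[v > 0.5 * max(v)]
    stop("design is rank deficient across sites; near-collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  drop(backsolve(C, backsolve(C, sum_xgy, transpose = TRUE)))
}

#' Profiled fixed effects at a given variance ratio
#'
#' Solves \eqn{\tilde\beta(\Theta) =
#' (\sum_i X_i'\Gamma_i^{-1}X_i)^{-1} \sum_i X_i'\Gamma_i^{-1} y_i}
#' from aggregated data. At `theta = 0` this is the pooled ordinary
#' least-squares estimate — the lossless distributed linear regression
#' special case.
#'
#' @param ads a `dlmm_ad` or list of them (one per site).
#' @inheritParams gamma_products
#' @return Named numeric vector of length p.
#' @export
profile_beta <- function(ads, re = integer(), theta = numeric()) {
  ads <- align_ads(ads)
  idx <- resolve_re(re, ads[[1L]]$columns)
  prep <- engine_prepare(ads, idx)
  s <- engine_sums(prep, as.numeric(theta))
  stats::setNames(solve_beta(s$sum_xgx, s$sum_xgy, prep$columns),
                  prep$columns)
}

#' Profiled residual variance at a given variance ratio
#'
#' Evaluates \eqn{\tilde\sigma^2(\Theta) = \mathrm{RSS}(\Theta)/N} (ML) or
#' \eqn{\mathrm{RSS}(\Theta)/(N-p)} (REML), where
#' \eqn{\mathrm{RSS}(\Theta) = \sum_i (y_i - X_i\tilde\beta)'
#' \Gamma_i^{-1} (y_i - X_i\tilde\beta)} is expanded through the
#' aggregates as \eqn{y'\Gamma^{-1}y - 2\tilde\beta'X'\Gamma^{-1}y +
#' \tilde\beta'X'\Gamma^{-1}X\tilde\beta}.
#'
#' @inheritParams profile_beta
#' @param beta_tilde profiled fixed effects at the same `theta`
#'   (default: recomputed).
#' @param method `"ml"` (divisor N) or `"reml"` (divisor N - p).
#' @return Positive scalar; errors on degenerate (exact-fit) data.
#' @export
profile_sigma2 <- function(ads, re = integer(), theta = numeric(),
                           beta_tilde = NULL, method = c("ml", "reml")) {
  method <- match.arg(method)
  ads <- align_ads(ads)
  idx <- resolve_re(re, ads[[1L]]$columns)
  prep <- engine_prepare(ads, idx)
  s <- engine_sums(prep, as.numeric(theta))
  if (is.null(beta_tilde)) {
    beta_tilde <- solve_beta(s$sum_xgx, s$sum_xgy, prep$columns)
  }
  rss <- rss_from_sums(s, unname(beta_tilde))
  denom <- if (method == "reml") prep$N - prep$p else prep$N
  if (denom <= 0) stop("fewer observations than fixed effects",
                       call. = FALSE)
  sigma2 <- rss / denom
  if (sigma2 <= 1e-12 * max(s$sum_ygy / prep$N, 1)) {
    stop("degenerate data: profiled residual variance is zero ",
         "(outcome fits exactly)", call. = FALSE)
  }
  sigma2
}

rss_from_sums <- function(s, beta) {
  drop(s$sum_ygy - 2 * sum(beta * s$sum_xgy) +
         crossprod(beta, s$sum_xgx %*% beta))
}

# Core objective evaluator shared by the AD engine and (via a different
# `sums` callback) the dense pooled reference. Returns the log-likelihood.
objective_from_sums <- function(s, N, p, n_i, method, reml_variant,
                                persite_xgx_logdets = NULL) {
  beta <- solve_beta(s$sum_xgx, s$sum_xgy, paste0("col", seq_len(p)))
  rss <- rss_from_sums(s, beta)
  if (rss <= 0) {
    stop("degenerate data: non-positive residual quadratic form",
         call. = FALSE)
  }
  if (method == "ml") {
    sigma2 <- rss / N
    ll <- -0.5 * (N * log(2 * pi) + N * log(sigma2) + s$sum_logdet + N)
  } else if (reml_variant == "joint") {
    sigma2 <- rss / (N - p)
    ldx <- 2 * sum(log(diag(chol(s$sum_xgx))))
    ll <- -0.5 * ((N - p) * log(2 * pi) + (N - p) * log(sigma2) +
                    s$sum_logdet + ldx + (N - p))
  } else {
    # literal per-site restricted form: subtract per-site log|X'G^{-1}X|
    # and add back n_i log sigma2 (which cancels the profile term)
    sigma2 <- rss / N
    lp <- -0.5 * (N * log(2 * pi) + N * log(sigma2) + s$sum_logdet + N)
    ll <- lp - 0.5 * (sum(persite_xgx_logdets) - N * log(sigma2))
  }
  list(ll = ll, beta = beta, sigma2 = sigma2, rss = rss)
}

# Analytic gradient of the profile objective with respect to theta.
# By the envelope theorem (beta-tilde is the interior optimum), with
# s_ik = (Z_i'Gamma_i^{-1} r_i)_k and r_i = y_i - X_i beta-tilde:
#   d RSS / d theta_k      = - sum_i s_ik^2
#   d log|Gamma_i| / d k   =   (Z_i'Gamma_i^{-1}Z_i)_kk
#   d log|sum xgx| / d k   = - sum_i g_ik' (sum xgx)^{-1} g_ik,
#                            g_ik = k-th row of Z_i'Gamma_i^{-1}X_i,
# and the objective is -[c log RSS + sum log|Gamma_i| (+ log|sum xgx|)]/2
# up to theta-free terms, c = N (ML) or N - p (REML).
grad_from_products <- function(prods, beta, rss, cc, bread) {
  q <- length(prods[[1L]]$zgy)
  sum_s2 <- numeric(q)
  sum_zgz <- numeric(q)
  sum_ld <- numeric(q)
  for (gp in prods) {
    si <- gp$zgy - drop(gp$zgx %*% beta)
    sum_s2 <- sum_s2 + si^2
    sum_zgz <- sum_zgz + diag(gp$zgz)
    if (!is.null(bread)) {
      sum_ld <- sum_ld + rowSums((gp$zgx %*% bread) * gp$zgx)
    }
  }
  # gradient of the LOG-LIKELIHOOD (not the negative)
  -0.5 * (-cc * sum_s2 / rss + sum_zgz - sum_ld)
}

engine_gradient <- function(prep, theta, method) {
  s <- engine_sums(prep, theta)
  beta <- solve_beta(s$sum_xgx, s$sum_xgy, prep$columns)
  rss <- rss_from_sums(s, beta)
  reml <- method == "reml"
  prods <- lapply(seq_len(prep$K), function(i) {
    gamma_core(prep$ZZ[[i]], prep$XZ[[i]], prep$ZY[[i]],
               unname(prep$ads[[i]]$sx), unname(prep$ads[[i]]$sxy),
               prep$sy[i], theta)
  })
  grad_from_products(prods, beta, rss,
                     if (reml) prep$N - prep$p else prep$N,
                     if (reml) chol2inv(chol(s$sum_xgx)) else NULL)
}

engine_objective <- function(prep, theta, method, reml_variant) {
  s <- engine_sums(prep, theta)
  persite <- NULL
  if (method == "reml" && reml_variant == "per_site") {
    persite <- vapply(seq_len(prep$K), function(i) {
      gp <- gamma_core(prep$ZZ[[i]], prep$XZ[[i]], prep$ZY[[i]],
                       unname(prep$ads[[i]]$sx),
                       unname(prep$ads[[i]]$sxy), prep$sy[i], theta)
      2 * sum(log(diag(chol(gp$xgx))))
    }, numeric(1))
    if (prep$q == 0L) persite <- vapply(prep$ads, function(ad) {
      2 * sum(log(diag(chol(ad$sx))))
    }, numeric(1))
  }
  objective_from_sums(s, prep$N, prep$p, prep$n, method, reml_variant,
                      persite)
}

#' Profile log-likelihood from aggregated data
#'
#' Evaluates the pooled profile log-likelihood \eqn{L_p(\Theta)} (ML) or
#' the restricted profile log-likelihood (REML) at a given variance-ratio
#' vector, reconstructed exactly from the aggregates. The ML objective is
#' \deqn{L_p(\Theta) = -\tfrac12 \{ N\log 2\pi + N \log\tilde\sigma^2
#'   + \textstyle\sum_i \log|\Gamma_i| + N \},}
#' using the identity that the profiled residual quadratic form equals
#' \eqn{N\tilde\sigma^2}. The default REML objective adds the joint
#' determinant \eqn{-\tfrac12\log|\sum_i X_i'\Gamma_i^{-1}X_i|} and uses
#' divisor \eqn{N - p}; `reml_variant = "per_site"` instead evaluates the
#' literal per-site restricted form (see the methods vignette).
#'
#' @inheritParams profile_sigma2
#' @param reml_variant `"joint"` (default) or `"per_site"`.
#' @return Scalar log-likelihood (includes the \eqn{2\pi} constants).
#' @export
profile_loglik <- function(ads, re = integer(), theta = numeric(),
                           method = c("reml", "ml"),
                           reml_variant = c("joint", "per_site")) {
  method <- match.arg(method)
  reml_variant <- match.arg(reml_variant)
  ads <- align_ads(ads)
  idx <- resolve_re(re, ads[[1L]]$columns)
  prep <- engine_prepare(ads, idx)
  engine_objective(prep, as.numeric(theta), method, reml_variant)$ll
}

# ---------------------------------------------------------------------------
# Optimizer over theta >= 0: L-BFGS-B on eta = log(theta + 1e-10) with the
# analytic profile gradient where available, default start 0.1, restarts
# from {0.01, 1, 10} when a start fails to converge, then clamping of
# components below 1e-8 to exact zero and a Brent re-polish of the
# survivors. `negobj` maps theta -> negative log-likelihood; `neggrad`
# (optional) maps theta -> its gradient.
# ---------------------------------------------------------------------------
optimize_theta <- function(negobj, q, neggrad = NULL,
                           starts = c(0.1, 0.01, 1, 10), maxit = 500L) {
  eps <- 1e-10
  lower <- log(eps)
  upper <- log(1e6)
  to_theta <- function(eta) pmax(exp(eta) - eps, 0)
  gr <- if (!is.null(neggrad)) {
    function(eta) neggrad(to_theta(eta)) * exp(eta)   # chain rule
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(rep(log(s + eps), q),
                   function(eta) negobj(to_theta(eta)), gr = gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = maxit, factr = 1e3,
                                  pgtol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) {
    stop("variance-component optimization failed from every start",
         call. = FALSE)
  }
  theta <- to_theta(best$par)
  converged <- best$convergence == 0
  value <- best$value

  # boundary polishing: clamp negligible components to exact zero and
  # refine the survivors by cyclic one-dimensional Brent searches,
  # alternating with a quasi-Newton restart from the polished point
  # (coordinate sweeps alone can stall off the joint optimum for q > 2)
  for (round in 1:2) {
    theta[theta < 1e-8] <- 0
    # boundary adjudication for components at or near zero: the first-order
    # condition at theta_k = 0 decides between the boundary (objective
    # increasing into the interior) and a small interior optimum, which a
    # bounded Brent search then locates. Quasi-Newton iterates routinely
    # stall in this region because d(theta)/d(eta) vanishes there.
    for (k in which(theta < 1e-4)) {
      th0 <- theta
      th0[k] <- 0
      v0 <- negobj(th0)
      interior <- if (!is.null(neggrad)) {
        neggrad(th0)[k] < 0
      } else {
        v0 > value
      }
      if (!interior) {
        if (v0 <= value + 1e-12 * abs(value)) {
          theta <- th0
          value <- min(v0, value)
        }
      } else {
        o <- stats::optimize(function(t) {
          th <- theta
          th[k] <- t
          negobj(th)
        }, interval = c(0, max(3 * theta[k], 1e-3)), tol = 1e-14)
        if (o$objective < min(value, v0)) {
          theta[k] <- o$minimum
          value <- o$objective
        }
      }
    }
    theta[theta < 1e-8] <- 0
    free <- which(theta > 0)
    if (!length(free)) break
    for (sweep in 1:3) {
      improved <- FALSE
      for (k in free) {
        cur <- theta[k]
        o <- stats::optimize(function(t) {
          th <- theta
          th[k] <- t
          negobj(th)
        }, interval = c(max(cur / 3, 0), cur * 3 + 1e-8),
        tol = 1e-12 * (1 + cur))
        if (o$objective < value - 1e-13 * abs(value)) {
          theta[k] <- o$minimum
          value <- o$objective
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    if (length(free) < 2L) break
    refit <- tryCatch(
      stats::optim(log(theta + eps), function(eta) negobj(to_theta(eta)),
                   gr = gr, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = maxit, factr = 1e3,
                                  pgtol = 1e-9)),
      error = function(e) NULL
    )
    if (is.null(refit) || refit$value >= value - 1e-13 * abs(value)) break
    theta <- to_theta(refit$par)
    value <- refit$value
  }
  theta[theta < 1e-8] <- 0

  # final Newton refinement on the analytic gradient: objective-difference
  # searches bottom out at x-error ~ sqrt(noise/curvature), which is poor
  # when the likelihood is flat (few sites); root-finding the gradient is
  # conditioned as noise/curvature instead
  free <- which(theta > 0)
  if (length(free) && !is.null(neggrad)) {
    for (it in 1:20) {
      g <- neggrad(theta)[free]
      J <- matrix(0, length(free), length(free))
      for (j in seq_along(free)) {
        h <- 1e-5 * (1 + theta[free[j]])
        tp <- theta; tp[free[j]] <- tp[free[j]] + h
        tm <- theta; tm[free[j]] <- max(tm[free[j]] - h, 0)
        J[, j] <- (neggrad(tp)[free] - neggrad(tm)[free]) /
          (tp[free[j]] - tm[free[j]])
      }
      delta <- tryCatch(solve(J, -g), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) break
      # damp: never move a component by more than half its magnitude
      delta <- pmin(pmax(delta, -0.5 * theta[free]), 0.5 * theta[free] + 1)
      cand <- theta
      cand[free] <- pmax(theta[free] + delta, 0)
      if (max(abs(neggrad(cand)[free])) <= max(abs(g))) {
        theta <- cand
      } else {
        break
      }
      if (max(abs(delta) / (1 + theta[free])) < 1e-12) break
    }
    theta[theta < 1e-8] <- 0
  }
  value <- min(value, negobj(theta))
  if (!converged && !is.null(neggrad)) {
    # certify the polished iterate by the first-order conditions: free
    # components have (scaled) zero gradient, boundary components have the
    # objective increasing into the interior
    g <- neggrad(theta)
    if (all(abs(g[theta > 0]) * pmax(theta[theta > 0], 1) < 1e-5) &&
        all(g[theta == 0] > -1e-5)) {
      converged <- TRUE
    }
  }
  list(theta = theta, value = value, converged = converged,
       counts = best$counts)
}

#' Fit a distributed linear mixed model from aggregated data
#'
#' Maximizes the reconstructed ML or REML profile likelihood over the
#' non-negative variance ratios \eqn{\Theta = V/\sigma^2}, then recovers
#' \eqn{\hat\beta = \tilde\beta(\hat\Theta)},
#' \eqn{\hat\sigma^2 = \tilde\sigma^2(\hat\Theta)} and
#' \eqn{\hat V = \hat\sigma^2 \hat\Theta}. Because the objective is an
#' exact reconstruction of the pooled-data objective, the result is
#' numerically identical to fitting the model on the stacked individual
#' records (see [fit_pooled()] and the methods vignette).
#'
#' Sites' aggregates must share one design-column set; they are aligned by
#' name to the first site's order. Variance ratios estimated below 1e-8 are
#' reported as exactly zero.
#'
#' @inheritParams profile_loglik
#' @param re random-effect design columns (names such as
#'   `c("(Intercept)", "x1")`, or indices). May be empty for a fixed-effects
#'   (pooled least squares) fit.
#' @return An object of class `dlmm_fit` with elements `beta`, `sigma2`,
#'   `theta`, `vc` (the random-effect variances \eqn{\hat\sigma^2\hat\Theta}),
#'   `loglik`, `method`, `reml_variant`, `converged`, `n_total`, `n_sites`,
#'   `re`, `columns`, and the optimizer record `optim`. Methods:
#'   [tidy.dlmm_fit()], [glance.dlmm_fit()], [autoplot.dlmm_fit()].
#' @examples
#' sim <- simulate_sites(n_sites = 10, n_per_site = 40,
#'                       beta = c(1, 0.5), re_columns = 1,
#'                       re_variances = 0.3, sigma2 = 1, seed = 7)
#' ads <- aggregate_sites(sim$data)
#' fit <- dlmm(ads, re = "(Intercept)")
#' glance(fit)
#' @export
dlmm <- function(ads, re = "(Intercept)", method = c("reml", "ml"),
                 reml_variant = c("joint", "per_site")) {
  method <- match.arg(method)
  reml_variant <- match.arg(reml_variant)
  ads <- align_ads(ads)
  columns <- ads[[1L]]$columns
  idx <- resolve_re(re, columns)
  prep <- engine_prepare(ads, idx)
  if (prep$N <= prep$p) {
    stop("need more observations than fixed effects", call. = FALSE)
  }
  q <- length(idx)

  if (q == 0L) {
    res <- engine_objective(prep, numeric(), method, reml_variant)
    opt <- list(theta = numeric(), value = -res$ll, converged = TRUE,
                counts = c(`function` = 1L, gradient = 0L))
  } else {
    negobj <- function(theta) {
      -engine_objective(prep, theta, method, reml_variant)$ll
    }
    # analytic gradient for ML and joint-determinant REML; the literal
    # per-site restricted variant falls back to finite differences
    neggrad <- if (method == "ml" || reml_variant == "joint") {
      function(theta) -engine_gradient(prep, theta, method)
    }
    opt <- optimize_theta(negobj, q, neggrad)
    res <- engine_objective(prep, opt$theta, method, reml_variant)
    if (!opt$converged) {
      warning("variance-component optimizer did not report convergence; ",
              "returning the best iterate", call. = FALSE)
    }
  }

  # per-site Gamma^{-1} products at the optimum: everything the covariance,
  # sandwich and BLUP formulas need, still AD-only
  products <- lapply(seq_len(prep$K), function(i) {
    gp <- gamma_core(if (q) prep$ZZ[[i]] else matrix(0, 0, 0),
                     if (q) prep$XZ[[i]] else matrix(0, prep$p, 0),
                     if (q) prep$ZY[[i]] else numeric(),
                     unname(prep$ads[[i]]$sx), unname(prep$ads[[i]]$sxy),
                     prep$sy[i], opt$theta)
    gp$site_id <- prep$ads[[i]]$site_id
    gp$n <- prep$n[i]
    gp
  })
  sum_xgx <- Reduce(`+`, lapply(products, `[[`, "xgx"))

  re_names <- columns[idx]
  structure(
    list(
      products = products,
      sum_xgx = sum_xgx,
      beta = stats::setNames(res$beta, columns),
      sigma2 = res$sigma2,
      theta = stats::setNames(opt$theta, re_names),
      vc = stats::setNames(res$sigma2 * opt$theta, re_names),
      loglik = res$ll,
      method = method,
      reml_variant = reml_variant,
      converged = opt$converged,
      n_total = prep$N,
      n_sites = prep$K,
      re = re_names,
      re_idx = idx,
      columns = columns,
      optim = opt[c("value", "counts", "converged")]
    ),
    class = "dlmm_fit"
  )
}

#' @export
print.dlmm_fit <- function(x, ...) {
  cat("Distributed linear mixed model fit (",
      toupper(x$method),
      if (x$method == "reml") paste0(", ", x$reml_variant, " variant"),
      ")\n", sep = "")
  cat("  sites:", x$n_sites, " observations:", x$n_total, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n\n")
  cat("Fixed effects:\n")
  print(signif(x$beta, 5))
  if (length(x$vc)) {
    cat("\nRandom-effect variances (diagonal V):\n")
    print(signif(x$vc, 5))
  }
  cat("\nResidual variance:", signif(x$sigma2, 5), "\n")
  invisible(x)
}
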