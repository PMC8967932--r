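#' Simulate multi-site data from a linear mixed model
#'
#' Draws data from the generative model
#' \deqn{y_{ij} = x_{ij}' \beta + z_{ij}' u_i + \epsilon_{ij},\qquad
#'       u_i \sim N(0, V),\ \epsilon_{ij} \sim N(0, \sigma^2),}
#' where site-level random effects are mutually independent
#' (\eqn{V = \mathrm{diag}(\sigma_1^2, \dots, \sigma_q^2)}) and the
#' random-effect covariates \eqn{z_{ij}} are a subset of the fixed-effect
#' covariates \eqn{x_{ij}} (possibly just the constant 1, a random
#' intercept).
#'
#' The design matrix always carries an intercept as its first column, named
#' `"(Intercept)"`. Non-intercept covariates are generated independently:
#' continuous columns as standard normal, binary columns as
#' Bernoulli(`binary_prob`). A single global `seed` streams one sub-seed per
#' site, so enlarging `n_sites` leaves the draws of earlier sites untouched.
#'
#' @param n_sites number of sites \eqn{K}.
#' @param n_per_site per-site sample sizes \eqn{n_i}; a single integer is
#'   recycled to all sites.
#' @param beta numeric vector of fixed effects; the first entry is the
#'   intercept. Its length fixes the number of design columns \eqn{p}.
#' @param re_columns integer indices (1-based) of the design columns that
#'   carry random effects; `1` is the random intercept. May be empty.
#' @param re_variances non-negative variances \eqn{\sigma_k^2}, aligned to
#'   `re_columns`.
#' @param sigma2 residual variance \eqn{\sigma^2 \ge 0}. Zero is permitted
#'   here (a noiseless draw, useful for degenerate-case checks) even though
#'   the fitting functions require positive residual variance.
#' @param covariate_kinds character vector of length `length(beta) - 1`
#'   with entries `"continuous"` or `"binary"`, one per non-intercept
#'   column. Defaults to all continuous.
#' @param binary_prob success probability for binary covariates (recycled).
#' @param seed integer seed; required for reproducibility.
#' @param outcome_name name of the outcome column in the returned data.
#'
#' @return An object of class `dlmm_sim`: a list with
#'   \describe{
#'     \item{data}{a tibble with columns `site`, the covariates
#'       (`x1`, `x2`, ...) and the outcome; one row per subject.}
#'     \item{truth}{a tibble of the realised random effects, one row per
#'       site and random-effect column.}
#'     \item{config}{the echoed simulation settings.}
#'   }
#' @examples
#' sim <- simulate_sites(n_sites = 3, n_per_site = 20,
#'                       beta = c(1, 0.5), re_columns = 1,
#'                       re_variances = 0.4, sigma2 = 1, seed = 42)
#' dplyr::count(sim$data, site)
#' @export
simulate_sites <- function(n_sites,
                           n_per_site,
                           beta,
                           re_columns = integer(),
                           re_variances = numeric(),
                           sigma2 = 1,
                           covariate_kinds = NULL,
                           binary_prob = 0.5,
                           seed,
                           outcome_name = "y") {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) {
    stop("`n_sites` must be a positive integer", call. = FALSE)
  }
  n_per_site <- as.integer(rep_len(n_per_site, n_sites))
  if (anyNA(n_per_site) || any(n_per_site < 1L)) {
    stop("`n_per_site` entries must be positive integers", call. = FALSE)
  }
  beta <- as.numeric(beta)
  p <- length(beta)
  if (p < 1L || anyNA(beta)) {
    stop("`beta` must be a non-empty numeric vector", call. = FALSE)
  }
  re_columns <- as.integer(re_columns)
  q <- length(re_columns)
  if (anyDuplicated(re_columns) ||
      (q > 0L && (min(re_columns) < 1L || max(re_columns) > p))) {
    stop("`re_columns` must be distinct indices in 1..length(beta)",
         call. = FALSE)
  }
  re_variances <- as.numeric(re_variances)
  if (length(re_variances) != q || anyNA(re_variances) ||
      any(re_variances < 0)) {
    stop("`re_variances` must be non-negative and aligned to `re_columns`",
         call. = FALSE)
  }
  if (length(sigma2) != 1L || is.na(sigma2) || sigma2 < 0) {
    stop("`sigma2` must be a single non-negative number", call. = FALSE)
  }
  if (is.null(covariate_kinds)) {
    covariate_kinds <- rep("continuous", max(p - 1L, 0L))
  }
  if (length(covariate_kinds) != p - 1L ||
      !all(covariate_kinds %in% c("continuous", "binary"))) {
    stop("`covariate_kinds` must tag each non-intercept column as ",
         "\"continuous\" or \"binary\"", call. = FALSE)
  }
  binary_prob <- rep_len(binary_prob, max(p - 1L, 0L))

  column_names <- c("(Intercept)", if (p > 1L) paste0("x", seq_len(p - 1L)))
  if (outcome_name %in% column_names) {
    stop("`outcome_name` collides with a covariate column name",
         call. = FALSE)
  }

  # one sub-seed per site, drawn sequentially so earlier sites are stable
  # when n_sites grows
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, n_sites)

  site_ids <- sprintf("site%0*d", nchar(n_sites), seq_len(n_sites))
  u <- matrix(0, n_sites, q)

  site_tbls <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    set.seed(sub_seeds[i])
    n_i <- n_per_site[i]
    if (q > 0L) u[i, ] <- stats::rnorm(q, 0, sqrt(re_variances))
    X <- matrix(1, n_i, p)
    for (j in seq_len(p - 1L)) {
      X[, j + 1L] <- if (covariate_kinds[j] == "continuous") {
        stats::rnorm(n_i)
      } else {
        stats::rbinom(n_i, 1L, binary_prob[j])
      }
    }
    eps <- if (sigma2 > 0) stats::rnorm(n_i, 0, sqrt(sigma2)) else 0
    y <- drop(X %*% beta) + eps
    if (q > 0L) y <- y + drop(X[, re_columns, drop = FALSE] %*% u[i, ])
    tbl <- tibble::as_tibble(as.data.frame(X[, -1L, drop = FALSE]))
    names(tbl) <- column_names[-1L]
    tbl[[outcome_name]] <- y
    site_tbls[[i]] <- dplyr::bind_cols(tibble::tibble(site = site_ids[i]),
                                       tbl)
  }

  truth <- if (q > 0L) {
    tibble::tibble(
      site = rep(site_ids, each = q),
      term = rep(column_names[re_columns], n_sites),
      u = as.vector(t(u))
    )
  } else {
    tibble::tibble(site = character(), term = character(), u = numeric())
  }

  structure(
    list(
      data = dplyr::bind_rows(site_tbls),
      truth = truth,
      config = list(
        n_sites = n_sites, n_per_site = n_per_site, beta = beta,
        re_columns = re_columns, re_variances = re_variances,
        sigma2 = sigma2, covariate_kinds = covariate_kinds,
        binary_prob = binary_prob, seed = as.integer(seed),
        column_names = column_names, outcome_name = outcome_name
      )
    ),
    class = "dlmm_sim"
  )
}

#' @export
print.dlmm_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated multi-site LMM data\n")
  cat("  sites:", cfg$n_sites, " total n:", sum(cfg$n_per_site), "\n")
  cat("  fixed effects:", paste(signif(cfg$beta, 4), collapse = ", "), "\n")
  if (length(cfg$re_columns)) {
    cat("  random effects on:",
        paste(cfg$column_names[cfg$re_columns], collapse = ", "),
        " variances:", paste(signif(cfg$re_variances, 4), collapse = ", "),
        "\n")
  }
  cat("  residual variance:", signif(cfg$sigma2, 4), "\n")
  invisible(x)
}

#' Write per-site CSV files / read one back
#'
#' `write_sites()` writes one CSV per site (header row: covariates then the
#' outcome column). `read_site()` reads a single site file back into a
#' validated tibble; every cell must be numeric and non-missing.
#'
#' @param sim a `dlmm_sim` object, or a data frame with a `site` column.
#' @param dir directory to write into (created if needed).
#' @param outcome name of the outcome column.
#' @return `write_sites()` returns the written file paths (invisibly, named
#'   by site); `read_site()` returns a tibble.
#' @export
write_sites <- function(sim, dir, outcome = "y") {
  data <- if (inherits(sim, "dlmm_sim")) sim$data else tibble::as_tibble(sim)
  if (inherits(sim, "dlmm_sim")) outcome <- sim$config$outcome_name
  if (!"site" %in% names(data)) {
    stop("`sim` must contain a `site` column", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(split(data, data$site), function(d) {
    path <- file.path(dir, paste0(d$site[1L], ".csv"))
    readr::write_csv(dplyr::select(d, -"site"), path)
    path
  }, character(1))
  invisible(paths)
}

#' @param path CSV file path.
#' @param columns optional character vector mapping/reordering: the
#'   covariate columns to keep, in the desired order. Defaults to every
#'   non-outcome column in file order.
#' @rdname write_sites
#' @export
read_site <- function(path, outcome = "y", columns = NULL) {
  if (!file.exists(path)) {
    stop("site file not found: ", path, call. = FALSE)
  }
  d <- readr::read_csv(path, col_types = readr::cols(.default = "d"),
                       progress = FALSE)
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    stop("non-numeric cell in ", path, " at row ", probs$row[1L],
         call. = FALSE)
  }
  if (!outcome %in% names(d)) {
    stop("outcome column \"", outcome, "\" missing in ", path,
         call. = FALSE)
  }
  if (is.null(columns)) columns <- setdiff(names(d), outcome)
  missing_cols <- setdiff(columns, names(d))
  if (length(missing_cols)) {
    stop("columns missing in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d <- d[, c(columns, outcome)]
  bad <- which(!stats::complete.cases(d))
  if (length(bad)) {
    stop("missing value in ", path, " at row ", bad[1L], call. = FALSE)
  }
  tibble::as_tibble(d)
}
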