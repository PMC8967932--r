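#' Reduce one site's records to shareable aggregated data
#'
#' Computes the four aggregated objects a site contributes to a distributed
#' linear mixed model fit: the cross-products
#' \eqn{S^X = X'X} (p x p), \eqn{S^{Xy} = X'y} (length p),
#' \eqn{s^y = y'y} (scalar) and the sample size \eqn{n}. These are
#' sufficient to reconstruct the pooled ML/REML objective exactly, and are
#' the only quantities that ever leave a site.
#'
#' The design matrix is the intercept column followed by every covariate
#' column of `data` (or the subset named in `covariates`), in order.
#'
#' @param data one site's records: a data frame with numeric covariate
#'   columns and the outcome column. A `site` column, if present, is used
#'   as the site id and dropped from the design.
#' @param outcome name of the outcome column (default `"y"`).
#' @param covariates optional character vector selecting/ordering the
#'   covariate columns; defaults to all non-outcome columns.
#' @param site_id identifier recorded in the aggregate; defaults to the
#'   `site` column value or `"site1"`.
#' @param intercept prepend an intercept column of ones (default `TRUE`).
#' @return An object of class `dlmm_ad` with elements `site_id`, `n`, `sx`,
#'   `sxy`, `sy`, `columns`, `outcome`, `schema_version`.
#' @examples
#' d <- tibble::tibble(x1 = c(0, 1, 2), y = c(1, 2, 3))
#' ad <- aggregate_site(d)
#' ad$sx   # [[3,3],[3,5]]
#' @export
aggregate_site <- function(data, outcome = "y", covariates = NULL,
                           site_id = NULL, intercept = TRUE) {
  data <- tibble::as_tibble(data)
  if ("site" %in% names(data)) {
    if (is.null(site_id)) site_id <- as.character(data$site[1L])
    data$site <- NULL
  }
  if (is.null(site_id)) site_id <- "site1"
  if (!outcome %in% names(data)) {
    stop("outcome column \"", outcome, "\" not found", call. = FALSE)
  }
  if (is.null(covariates)) covariates <- setdiff(names(data), outcome)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    stop("covariate columns not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  y <- as.numeric(data[[outcome]])
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (intercept) {
    X <- cbind(`(Intercept)` = 1, X)
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in design or outcome", call. = FALSE)
  }
  n <- nrow(X)
  if (n < 1L) stop("site has no rows", call. = FALSE)

  ad <- structure(
    list(
      site_id = site_id,
      n = n,
      sx = crossprod(X),
      sxy = drop(crossprod(X, y)),
      sy = sum(y^2),
      columns = colnames(X),
      outcome = outcome,
      schema_version = "1.0"
    ),
    class = "dlmm_ad"
  )
  validate_ad(ad)
  ad
}

#' Aggregate every site of a multi-site table
#'
#' Splits `data` by its `site` column and applies [aggregate_site()] to
#' each part.
#'
#' @inheritParams aggregate_site
#' @param site name of the grouping column (default `"site"`).
#' @return A named list of `dlmm_ad` objects, one per site.
#' @export
aggregate_sites <- function(data, outcome = "y", covariates = NULL,
                            site = "site", intercept = TRUE) {
  data <- tibble::as_tibble(data)
  if (!site %in% names(data)) {
    stop("grouping column \"", site, "\" not found", call. = FALSE)
  }
  parts <- split(dplyr::select(data, -dplyr::all_of(site)), data[[site]])
  purrr::imap(parts, function(d, id) {
    aggregate_site(d, outcome = outcome, covariates = covariates,
                   site_id = id, intercept = intercept)
  })
}

validate_ad <- function(ad) {
  sx <- ad$sx
  p <- length(ad$columns)
  if (!is.matrix(sx) || nrow(sx) != p || ncol(sx) != p) {
    stop("aggregated data: `sx` must be a ", p, " x ", p, " matrix",
         call. = FALSE)
  }
  scale <- max(abs(sx), 1)
  if (max(abs(sx - t(sx))) > 1e-10 * scale) {
    stop("aggregated data: `sx` is not symmetric", call. = FALSE)
  }
  ev <- eigen((sx + t(sx)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * scale) {
    stop("aggregated data: `sx` is not positive semi-definite",
         call. = FALSE)
  }
  if (length(ad$sxy) != p) {
    stop("aggregated data: `sxy` length does not match columns",
         call. = FALSE)
  }
  # residual sum of squares implied by the aggregates must be non-negative
  rss <- ad$sy - sum(ad$sxy * drop(pseudo_inverse(sx) %*% ad$sxy))
  if (rss < -1e-8 * max(ad$sy, 1)) {
    stop("aggregated data: implied residual sum of squares is negative",
         call. = FALSE)
  }
  if (ad$n < 1) stop("aggregated data: n must be >= 1", call. = FALSE)
  invisible(ad)
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix (small p)
pseudo_inverse <- function(a, tol = 1e-12) {
  e <- eigen((a + t(a)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 1)
  if (!any(keep)) return(matrix(0, nrow(a), ncol(a)))
  v <- e$vectors[, keep, drop = FALSE]
  v %*% (t(v) / e$values[keep])
}

#' @export
print.dlmm_ad <- function(x, ...) {
  cat("Aggregated site data (schema ", x$schema_version, ")\n", sep = "")
  cat("  site:", x$site_id, " n:", x$n, "\n")
  cat("  design columns:", paste(x$columns, collapse = ", "), "\n")
  cat("  outcome:", x$outcome, "\n")
  invisible(x)
}

#' Write / read aggregated data as JSON
#'
#' The interchange format is a flat JSON object
#' `{"schema_version","site_id","n","columns","outcome","sx","sxy","sy"}`
#' with `sx` a row-major nested list. Numbers are serialized at full
#' round-trip precision, so `read_ad(write_ad(ad))` reproduces every value
#' exactly. `read_ad()` re-validates symmetry, positive semi-definiteness
#' and the non-negativity of the implied residual sum of squares.
#'
#' @param ad a `dlmm_ad` object.
#' @param path file path.
#' @return `write_ad()` returns `path` invisibly; `read_ad()` returns a
#'   `dlmm_ad`.
#' @export
write_ad <- function(ad, path) {
  stopifnot(inherits(ad, "dlmm_ad"))
  payload <- list(
    schema_version = ad$schema_version,
    site_id = ad$site_id,
    n = ad$n,
    columns = as.list(ad$columns),
    outcome = ad$outcome,
    sx = apply(ad$sx, 1L, as.list, simplify = FALSE),
    sxy = as.list(unname(ad$sxy)),
    sy = ad$sy
  )
  # digits = I(17): 17 significant digits round-trip an IEEE double exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ad
#' @export
read_ad <- function(path) {
  if (!file.exists(path)) {
    stop("aggregated-data file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("schema_version", "site_id", "n", "columns", "outcome",
                "sx", "sxy", "sy")
  absent <- setdiff(required, names(obj))
  if (length(absent)) {
    stop("aggregated-data JSON ", path, " is missing keys: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (!identical(substr(obj$schema_version, 1, 2), "1.")) {
    stop("unsupported schema_version \"", obj$schema_version, "\" in ",
         path, call. = FALSE)
  }
  p <- length(obj$columns)
  sx <- if (is.matrix(obj$sx)) {
    matrix(as.numeric(obj$sx), p, p)
  } else {
    # row-major nested lists
    do.call(rbind, lapply(obj$sx, as.numeric))
  }
  dimnames(sx) <- list(obj$columns, obj$columns)
  ad <- structure(
    list(
      site_id = as.character(obj$site_id),
      n = as.integer(obj$n),
      sx = sx,
      sxy = stats::setNames(as.numeric(obj$sxy), obj$columns),
      sy = as.numeric(obj$sy),
      columns = as.character(obj$columns),
      outcome = as.character(obj$outcome),
      schema_version = as.character(obj$schema_version)
    ),
    class = "dlmm_ad"
  )
  validate_ad(ad)
  ad
}

#' Sparse-cell privacy audit of aggregated data
#'
#' For 0/1 covariate columns, marginal counts and pairwise joint counts
#' are exactly inferable from the shared cross-product matrix:
#' `sx[j, j]` is the number of subjects with column j equal to 1,
#' `n - sx[j, j]` its complement, and `sx[j, k]` the joint count of a pair.
#' Any such inferable count below `threshold` is flagged as a sparse cell
#' that could aid re-identification. The audit is advisory — it reports and
#' never blocks — but the command-line interface offers a strict mode that
#' refuses to write a failing aggregate.
#'
#' Higher-order cell counts (three or more characteristics jointly) are not
#' inferable from `sx` alone and are outside the audit's reach.
#'
#' @param ad a `dlmm_ad` object.
#' @param binary_columns names of columns whose site values are 0/1.
#' @param threshold minimum acceptable cell count (default 5).
#' @return An object of class `dlmm_privacy`: list with `flags` (tibble of
#'   `description`, `count`), `threshold` and `passed`
#'   (`TRUE` iff no flags).
#' @export
privacy_audit <- function(ad, binary_columns = character(), threshold = 5) {
  stopifnot(inherits(ad, "dlmm_ad"))
  binary_columns <- as.character(binary_columns)
  absent <- setdiff(binary_columns, ad$columns)
  if (length(absent)) {
    stop("unknown columns: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(binary_columns, ad$columns)
  ints <- ad$sx[idx, idx, drop = FALSE]
  if (length(ints) && max(abs(ints - round(ints))) > 1e-8) {
    stop("columns ", paste(binary_columns, collapse = ", "),
         " have non-integral cross-products; not 0/1 columns",
         call. = FALSE)
  }

  desc <- character()
  count <- numeric()
  for (a in seq_along(idx)) {
    j <- idx[a]
    cj <- round(ad$sx[j, j])
    if (cj < threshold) {
      desc <- c(desc, paste0("count of ", binary_columns[a], " = 1"))
      count <- c(count, cj)
    }
    if (ad$n - cj < threshold) {
      desc <- c(desc, paste0("count of ", binary_columns[a], " = 0"))
      count <- c(count, ad$n - cj)
    }
    for (b in seq_along(idx)) {
      if (b <= a) next
      k <- idx[b]
      cjk <- round(ad$sx[j, k])
      if (cjk < threshold) {
        desc <- c(desc, paste0("joint count of ", binary_columns[a],
                               " = 1 and ", binary_columns[b], " = 1"))
        count <- c(count, cjk)
      }
    }
  }
  flags <- tibble::tibble(description = desc, count = count)
  structure(
    list(flags = flags, threshold = threshold, passed = nrow(flags) == 0L),
    class = "dlmm_privacy"
  )
}

#' @export
print.dlmm_privacy <- function(x, ...) {
  cat("Sparse-cell privacy audit (threshold ", x$threshold, "): ",
      if (x$passed) "passed" else "FLAGGED", "\n", sep = "")
  if (!x$passed) print(x$flags)
  invisible(x)
}

#' @method tidy dlmm_privacy
#' @export
tidy.dlmm_privacy <- function(x, ...) x$flags
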