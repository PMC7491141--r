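# Internal linear-model and design-matrix machinery shared by the EWA,
# mediation and MR modules. Everything here is plain base-R least squares;
# callers are responsible for passing complete (no-NA) data.

#' Default covariate sets
#'
#' Column-name vectors for the standard adjustment sets used throughout the
#' pipeline. `ewa_covariates()` is the epigenome-wide scan adjustment set
#' (sex, age, race, smoking, adherence, white blood cell count, five
#' cell-type proportions with CD4 left out as the complement, and
#' `n_ncpc` negative-control principal components). `mediation_covariates()`
#' is the same set without the technical PCs. `mr_covariates()` is the
#' genetic-association set (age, sex, race, five ancestry PCs);
#' `mr_outcome_covariates()` is the step-2 outcome set, which omits race.
#'
#' @param n_ncpc number of negative-control PCs available in the sample table.
#' @param race include race indicator (step-2 MR outcome models omit it by
#'   default).
#' @return character vector of column names.
#' @export
ewa_covariates <- function(n_ncpc = 5) {
  c(mediation_covariates(), if (n_ncpc > 0) paste0("ncpc", seq_len(n_ncpc)))
}

#' @rdname ewa_covariates
#' @export
mediation_covariates <- function() {
  c("sex", "age", "race", "smoking", "adherence", "wbc",
    "cd8t", "gran", "nk", "bcell", "mono")
}

#' @rdname ewa_covariates
#' @export
mr_covariates <- function() {
  c("age", "sex", "race", paste0("apc", 1:5))
}

#' @rdname ewa_covariates
#' @export
mr_outcome_covariates <- function(race = FALSE) {
  c("age", "sex", if (race) "race", paste0("apc", 1:5))
}

# Build a design matrix (with intercept) from covariate column names.
# Factors expand to treatment-coded dummies via model.matrix.
mm_design <- function(samples, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)")))
  }
  missing_cols <- setdiff(covariates, names(samples))
  if (length(missing_cols) > 0L) {
    stop("covariate column(s) not found in sample table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- stats::model.matrix(stats::reformulate(covariates), data = samples)
  # factor levels are fixed cohort-wide; a level absent from an analysis
  # subset yields an all-zero dummy, which is dropped rather than treated
  # as a rank deficiency
  if (ncol(X) > 1L) {
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(col) stats::var(col) > 0))
    X <- X[, keep, drop = FALSE]
  }
  X
}

# Single-response OLS with full inferential output. Errors on rank
# deficiency, naming the aliased columns.
ols_stats <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, y)
  resid <- y - drop(X %*% coefs)
  df <- length(y) - qx$rank
  if (df <= 0L) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- sum(resid^2) / df
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- stats::setNames(sqrt(diag(xtx_inv) * sigma2), colnames(X))
  tval <- coefs / se
  list(coef = coefs, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       residuals = resid, df = df, sigma = sqrt(sigma2))
}

# Multi-response OLS: one design X (n x k), response matrix Y (n x p).
# Returns per-response coefficient, SE, t, p for a single focal column.
# Degenerate responses (zero residual + zero effect, i.e. constant columns)
# are handled by the caller.
ols_multi_focal <- function(X, Y, focal) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qx, Y)                       # k x p
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  df <- nrow(X) - qx$rank
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)[order(qx$pivot), order(qx$pivot), drop = FALSE]
  j <- match(focal, colnames(X))
  if (is.na(j)) stop("focal column '", focal, "' not in design", call. = FALSE)
  se <- sqrt(xtx_inv[j, j] * rss / df)
  est <- coefs[j, ]
  tval <- est / se
  list(effect = est, se = se, t = tval,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), df = df)
}

# Fast coefficient-only OLS used inside bootstrap loops. Coefficients are
# returned in original column order (dqrls pivots internally).
ols_coef <- function(X, y) {
  f <- .lm.fit(X, y)
  out <- f$coefficients
  out[f$pivot] <- f$coefficients
  out
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
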