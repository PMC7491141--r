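# Exposure-outcome models upstream of mediation: the linear severity
# association, the Cox proportional hazards model, and the log-rank test
# for trend across ordered exposure-frequency groups.

new_association_fit <- function(df, model, n, extra = list()) {
  structure(c(list(terms = df, model = model, n = n), extra),
            class = "association_fit")
}

#' @export
print.association_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s association fit (n = %d)\n", x$model, x$n))
  print(format(x$terms, digits = digits), ...)
  invisible(x)
}

#' @export
coef.association_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

#' @export
summary.association_fit <- function(object, ...) object

#' Linear exposure-outcome association
#'
#' Ordinary least squares of a continuous outcome (e.g. the severity index)
#' on an exposure and confounders, with intercept and two-sided t p-values.
#' By default the full cohort (all exposure groups) is used; set
#' `two_group = TRUE` to restrict to the persistent/none contrast.
#'
#' @param samples a `sample_table`.
#' @param outcome outcome column name (e.g. `"vacs_at_draw"`).
#' @param terms covariate column names; the first is the exposure of
#'   interest (term order is preserved in the output).
#' @param two_group restrict to persistent/none samples.
#' @return an `association_fit`, with one row per design column (intercept
#'   excluded) carrying estimate, SE, t and p.
#' @export
fit_linear_association <- function(samples, outcome, terms,
                                   two_group = FALSE) {
  if (two_group) {
    samples <- samples[samples$exposure_group %in% c("none", "persistent"), ]
    # keep cohort-wide factor levels; mm_design drops empty dummies
  }
  y <- samples[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome, call. = FALSE)
  keep <- stats::complete.cases(y, samples[, intersect(terms, names(samples))])
  samples <- samples[keep, ]
  y <- y[keep]
  if (stats::var(y) == 0) stop("outcome is constant", call. = FALSE)
  X <- mm_design(samples, terms)
  if (nrow(X) <= ncol(X) + 2L) {
    stop("too few samples for the requested terms", call. = FALSE)
  }
  fit <- ols_stats(X, y)
  idx <- -1L   # drop intercept from the report
  df <- data.frame(term = colnames(X)[idx],
                   estimate = unname(fit$coef[idx]),
                   se = unname(fit$se[idx]),
                   statistic = unname(fit$t[idx]),
                   p = unname(fit$p[idx]),
                   stringsAsFactors = FALSE)
  new_association_fit(df, "linear", nrow(X),
                      extra = list(outcome = outcome, sigma = fit$sigma,
                                   residuals = fit$residuals, design = X))
}

#' Cox proportional hazards exposure-survival model
#'
#' Maximum partial likelihood with Efron tie handling (via
#' \code{survival::coxph}); reports per-term hazard ratios with Wald 95\%
#' CIs and p-values, plus a Schoenfeld-residual proportional-hazards
#' diagnostic (correlation of scaled residuals with time, not acted on).
#'
#' @inheritParams fit_linear_association
#' @param terms covariate column names; first is the exposure of interest.
#' @return an `association_fit` with columns estimate (log HR), SE, z, p,
#'   hr, ci_lo, ci_hi.
#' @export
fit_cox <- function(samples, terms, two_group = FALSE) {
  if (two_group) {
    samples <- samples[samples$exposure_group %in% c("none", "persistent"), ]
    # keep cohort-wide factor levels; mm_design drops empty dummies
  }
  if (!all(c("surv_years", "event") %in% names(samples))) {
    stop("samples must carry surv_years and event", call. = FALSE)
  }
  keep <- stats::complete.cases(samples[, c("surv_years", "event",
                                            intersect(terms, names(samples)))])
  samples <- samples[keep, ]
  if (sum(samples$event) == 0L) {
    stop("no events observed; cannot fit Cox model", call. = FALSE)
  }
  if (any(samples$surv_years <= 0)) {
    stop("survival times must be positive", call. = FALSE)
  }
  fml <- stats::reformulate(terms,
                            response = "survival::Surv(surv_years, event)")
  fit <- withCallingHandlers(
    survival::coxph(fml, data = samples, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w))) {
        stop("Cox model failed to converge: ", conditionMessage(w),
             call. = FALSE)
      }
    })
  s <- summary(fit)
  est <- s$coefficients[, "coef"]
  se <- s$coefficients[, "se(coef)"]
  df <- data.frame(term = rownames(s$coefficients),
                   estimate = unname(est), se = unname(se),
                   statistic = unname(s$coefficients[, "z"]),
                   p = unname(s$coefficients[, "Pr(>|z|)"]),
                   hr = unname(exp(est)),
                   ci_lo = unname(exp(est - 1.96 * se)),
                   ci_hi = unname(exp(est + 1.96 * se)),
                   stringsAsFactors = FALSE)
  ph_cor <- tryCatch({
    zph <- survival::cox.zph(fit)
    unname(zph$table[seq_len(nrow(zph$table) - 1L), "chisq"])
  }, error = function(e) NULL)
  new_association_fit(df, "cox", fit$n,
                      extra = list(n_events = fit$nevent,
                                   ph_diagnostic = ph_cor, coxph = fit))
}

#' Log-rank test for trend over ordered groups
#'
#' Tests for ordered differences among Kaplan-Meier curves using the
#' log-rank trend statistic: with per-group observed-minus-expected event
#' counts O - E and their covariance matrix V (from the standard log-rank
#' machinery) and equally spaced group scores s, the statistic is
#' (s'(O-E))^2 / (s'Vs), chi-squared on 1 df.
#'
#' @param samples a `sample_table` with `surv_years` and `event`.
#' @param group ordinal grouping column (default `"exposure_freq"`); its
#'   sorted unique values are used as the trend scores.
#' @return list with `statistic`, `p`, `df = 1`, and per-group observed and
#'   expected counts.
#' @export
km_trend_test <- function(samples, group = "exposure_freq") {
  g <- samples[[group]]
  if (is.null(g)) stop("group column not found: ", group, call. = FALSE)
  keep <- stats::complete.cases(samples$surv_years, samples$event, g)
  samples <- samples[keep, ]
  g <- g[keep]
  levels_used <- sort(unique(g))
  if (length(levels_used) < 2L) {
    stop("need at least two ordered groups for a trend test", call. = FALSE)
  }
  gf <- factor(g, levels = levels_used)
  sd <- survival::survdiff(
    survival::Surv(samples$surv_years, samples$event) ~ gf)
  scores <- as.numeric(levels_used)
  d <- sd$obs - sd$exp
  u <- sum(scores * d)
  v <- drop(t(scores) %*% sd$var %*% scores)
  stat <- if (v > 0) u^2 / v else 0
  list(statistic = stat,
       p = if (v > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1,
       df = 1L, observed = sd$obs, expected = sd$exp, scores = scores)
}

#' Export a Kaplan-Meier step curve as a plain table
#'
#' @param samples a `sample_table`.
#' @param group optional grouping column.
#' @return data frame with columns group (if any), time, surv, n_risk.
#' @export
km_curve <- function(samples, group = NULL) {
  if (is.null(group)) {
    fit <- survival::survfit(
      survival::Surv(samples$surv_years, samples$event) ~ 1)
    data.frame(time = fit$time, surv = fit$surv, n_risk = fit$n.risk)
  } else {
    gf <- factor(samples[[group]])
    fit <- survival::survfit(
      survival::Surv(samples$surv_years, samples$event) ~ gf)
    grp <- rep(sub("^gf=", "", names(fit$strata)), fit$strata)
    data.frame(group = grp, time = fit$time, surv = fit$surv,
               n_risk = fit$n.risk)
  }
}
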