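# Causal mediation between a binary exposure and a continuous outcome in
# the linear structural-equation setting. Point estimates come from the
# product method (two OLS fits); inference is by nonparametric bootstrap of
# whole samples with percentile intervals; robustness to violation of
# sequential ignorability is assessed on the error-correlation parameter
# rho, for which the linear case has a closed form.

# Shared engine for single-site and joint mediation. `cpgs` may be one or
# many; mediator models are fitted per CpG against a common design, the
# outcome model includes all mediators jointly.
mediate_engine <- function(samples, beta, cpgs, covariates, outcome,
                           B, seed, min_group = 10L) {
  samples <- as.data.frame(samples)
  keep <- samples$exposure_group %in% c("none", "persistent")
  samples <- samples[keep, , drop = FALSE]
  x <- as.numeric(samples$exposure_group == "persistent")
  if (min(sum(x == 1), sum(x == 0)) < min_group) {
    stop("need at least ", min_group, " samples in each exposure group",
         call. = FALSE)
  }
  idx <- match(samples$sample_id, colnames(beta))
  if (anyNA(idx)) stop("samples missing from beta matrix", call. = FALSE)
  miss <- setdiff(cpgs, rownames(beta))
  if (length(miss) > 0L) {
    stop("cpg(s) not in beta matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  M <- t(beta[cpgs, idx, drop = FALSE])          # n x J
  y <- samples[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome, call. = FALSE)
  C <- mm_design(samples, covariates)            # includes intercept
  Xm <- cbind(C[, 1, drop = FALSE], exposure = x, C[, -1, drop = FALSE])
  Xy <- cbind(Xm[, 1:2, drop = FALSE], M, Xm[, -(1:2), drop = FALSE])
  colnames(Xy)[2 + seq_along(cpgs)] <- cpgs

  med_fits <- lapply(seq_along(cpgs), function(j) ols_stats(Xm, M[, j]))
  out_fit <- ols_stats(Xy, y)
  beta0 <- vapply(med_fits, function(f) unname(f$coef["exposure"]),
                  numeric(1))
  alpha1 <- unname(out_fit$coef[2 + seq_along(cpgs)])
  alpha0 <- unname(out_fit$coef["exposure"])
  acme_j <- alpha1 * beta0
  acme <- sum(acme_j)
  te <- alpha0 + acme

  ## bootstrap (resampling whole samples)
  set_seed_if(seed)
  n <- length(y)
  draws_acme <- numeric(B)
  draws_te <- numeric(B)
  draws_acme_j <- matrix(NA_real_, B, length(cpgs))
  jx <- 2 + seq_along(cpgs)
  for (b in seq_len(B)) {
    ib <- sample.int(n, n, replace = TRUE)
    cb_out <- ols_coef(Xy[ib, , drop = FALSE], y[ib])
    b0b <- vapply(seq_along(cpgs), function(j) {
      ols_coef(Xm[ib, , drop = FALSE], M[ib, j])[2]
    }, numeric(1))
    aj <- cb_out[jx] * b0b
    draws_acme_j[b, ] <- aj
    draws_acme[b] <- sum(aj)
    draws_te[b] <- cb_out[2] + sum(aj)
  }
  draws_pm <- draws_acme / draws_te

  list(samples_n = n, cpgs = cpgs, beta0 = beta0, alpha1 = alpha1,
       alpha0 = alpha0, acme_j = acme_j, acme = acme, te = te,
       y = y, M = M, Xm = Xm,
       med_fits = med_fits, out_fit = out_fit,
       draws_acme = draws_acme, draws_te = draws_te, draws_pm = draws_pm,
       draws_acme_j = draws_acme_j, B = B, seed = seed)
}

boot_ci <- function(draws) unname(stats::quantile(draws, c(0.025, 0.975),
                                                  na.rm = TRUE, type = 7))

boot_p <- function(draws) {
  draws <- draws[!is.na(draws)]
  B <- length(draws)
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  max(min(p, 1), 1 / B)
}

#' Single-site causal mediation analysis
#'
#' Estimates the average causal mediation effect (ACME) of one CpG between
#' the binary persistent-vs-none exposure contrast and a continuous outcome.
#' Two OLS fits are used: the mediator model M ~ X + C (exposure coefficient
#' beta0) and the outcome model Y ~ X + M + C (mediator coefficient alpha1,
#' direct effect alpha0). Then ACME = alpha1 * beta0, the average direct
#' effect (ADE) is alpha0, the total effect TE = alpha0 + alpha1 * beta0,
#' and the proportion mediated PM = ACME / TE. Confidence intervals and
#' two-sided p-values come from a nonparametric bootstrap resampling whole
#' samples (percentile intervals; p = 2 * min(fraction of draws <= 0,
#' fraction >= 0), floored at 1/B).
#'
#' @param samples a `sample_table`; inconsistent reporters are excluded.
#' @param beta CpGs x samples matrix.
#' @param cpg mediator CpG id.
#' @param covariates confounder column names (default
#'   [mediation_covariates()]).
#' @param outcome outcome column (default `"vacs_avg_after"`, the average
#'   severity index after methylation profiling, preserving temporality).
#' @param B bootstrap replicates (>= 1000 recommended).
#' @param seed RNG seed for the bootstrap; fixed seed gives bit-identical
#'   results.
#' @return object of class `mediation_fit`.
#' @export
fit_mediation <- function(samples, beta, cpg,
                          covariates = mediation_covariates(),
                          outcome = "vacs_avg_after",
                          B = 10000L, seed = 1L) {
  stopifnot(length(cpg) == 1L, B >= 1)
  eng <- mediate_engine(samples, beta, cpg, covariates, outcome, B, seed)
  pm_defined <- abs(eng$te) > 1e-12
  fit <- structure(list(
    cpg = cpg, n = eng$samples_n, B = B, seed = seed,
    beta0 = eng$beta0, alpha1 = eng$alpha1, alpha0 = eng$alpha0,
    acme = eng$acme, ade = eng$alpha0, te = eng$te,
    pm = if (pm_defined) eng$acme / eng$te else NA_real_,
    pm_defined = pm_defined,
    acme_ci = boot_ci(eng$draws_acme), acme_p = boot_p(eng$draws_acme),
    pm_ci = if (pm_defined) boot_ci(eng$draws_pm) else c(NA_real_, NA_real_),
    pm_p = if (pm_defined) boot_p(eng$draws_pm) else NA_real_,
    te_ci = boot_ci(eng$draws_te), te_p = boot_p(eng$draws_te),
    covariates = covariates, outcome = outcome,
    engine = eng), class = "mediation_fit")
  fit
}

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Causal mediation fit for %s (n = %d, B = %d)\n",
              x$cpg, x$n, x$B))
  cat(sprintf("  ACME %.*f  [%.*f, %.*f]  p = %.3g\n", digits, x$acme,
              digits, x$acme_ci[1], digits, x$acme_ci[2], x$acme_p))
  if (x$pm_defined) {
    cat(sprintf("  PM   %.1f%%  [%.1f%%, %.1f%%]  p = %.3g\n", 100 * x$pm,
                100 * x$pm_ci[1], 100 * x$pm_ci[2], x$pm_p))
  } else {
    cat("  PM   undefined (total effect ~ 0)\n")
  }
  cat(sprintf("  ADE  %.*f   TE %.*f\n", digits, x$ade, digits, x$te))
  invisible(x)
}

#' @export
coef.mediation_fit <- function(object, ...) {
  c(acme = object$acme, ade = object$ade, te = object$te, pm = object$pm,
    alpha1 = object$alpha1, beta0 = object$beta0)
}

#' @export
confint.mediation_fit <- function(object, parm = c("acme", "pm", "te"),
                                  level = 0.95, ...) {
  if (level != 0.95) {
    warning("bootstrap intervals are stored at the 95% level", call. = FALSE)
  }
  parm <- match.arg(parm, several.ok = TRUE)
  out <- rbind(acme = object$acme_ci, pm = object$pm_ci, te = object$te_ci)
  colnames(out) <- c("2.5 %", "97.5 %")
  out[parm, , drop = FALSE]
}

#' @export
summary.mediation_fit <- function(object, ...) object

#' Effect decomposition from ACME and total effect
#'
#' Average direct effect = total - ACME; proportion mediated = ACME / total.
#' A total effect of (numerically) zero leaves the proportion undefined.
#'
#' @param acme average causal mediation effect.
#' @param total total effect.
#' @return list with `ade`, `pm` and logical `pm_defined`.
#' @export
derive_effect_decomposition <- function(acme, total) {
  defined <- abs(total) > 1e-12
  list(ade = total - acme,
       pm = if (defined) acme / total else NA_real_,
       pm_defined = defined)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(m >= 1, alpha > 0, alpha <= 1)
  alpha / m
}

#' Joint mediation analysis over multiple CpGs
#'
#' One outcome model with all mediators (Y ~ X + M1 + ... + Mn + C) and
#' per-mediator mediator models (Mj ~ X + C). The joint ACME is the sum of
#' the per-mediator products alpha_j * beta0_j; TE = alpha0 + joint ACME;
#' joint PM = joint ACME / TE. Bootstrap inference as in
#' [fit_mediation()], conditional on the fixed mediator set. With a single
#' CpG this reduces exactly to the single-site fit.
#'
#' @inheritParams fit_mediation
#' @param cpgs mediator CpG ids.
#' @return object of class `joint_mediation_fit`.
#' @export
fit_joint_mediation <- function(samples, beta, cpgs,
                                covariates = mediation_covariates(),
                                outcome = "vacs_avg_after",
                                B = 10000L, seed = 1L) {
  stopifnot(length(cpgs) >= 1L, B >= 1)
  eng <- mediate_engine(samples, beta, cpgs, covariates, outcome, B, seed)
  pm_defined <- abs(eng$te) > 1e-12
  structure(list(
    cpgs = cpgs, n = eng$samples_n, B = B, seed = seed,
    per_mediator = data.frame(cpg = cpgs, beta0 = eng$beta0,
                              alpha = eng$alpha1, acme = eng$acme_j,
                              stringsAsFactors = FALSE),
    alpha0 = eng$alpha0, acme = eng$acme, ade = eng$alpha0, te = eng$te,
    pm = if (pm_defined) eng$acme / eng$te else NA_real_,
    pm_defined = pm_defined,
    acme_ci = boot_ci(eng$draws_acme), acme_p = boot_p(eng$draws_acme),
    pm_ci = if (pm_defined) boot_ci(eng$draws_pm) else c(NA_real_, NA_real_),
    pm_p = if (pm_defined) boot_p(eng$draws_pm) else NA_real_,
    covariates = covariates, outcome = outcome,
    engine = eng), class = "joint_mediation_fit")
}

#' @export
print.joint_mediation_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Joint mediation fit over %d CpGs (n = %d, B = %d)\n",
              length(x$cpgs), x$n, x$B))
  cat(sprintf("  joint ACME %.*f  [%.*f, %.*f]  p = %.3g\n", digits, x$acme,
              digits, x$acme_ci[1], digits, x$acme_ci[2], x$acme_p))
  if (x$pm_defined) {
    cat(sprintf("  joint PM   %.1f%%  [%.1f%%, %.1f%%]\n", 100 * x$pm,
                100 * x$pm_ci[1], 100 * x$pm_ci[2]))
  }
  cat(sprintf("  ADE %.*f   TE %.*f\n", digits, x$ade, digits, x$te))
  invisible(x)
}

#' @export
coef.joint_mediation_fit <- function(object, ...) {
  c(acme = object$acme, ade = object$ade, te = object$te, pm = object$pm)
}

#' Sensitivity of the ACME to unmeasured mediator-outcome confounding
#'
#' Sequential ignorability implies zero correlation rho between the errors
#' of the mediator and outcome models. In the linear structural-equation
#' case the ACME as a function of an assumed rho has the closed form
#' ACME(rho) = beta0 * (s1 / s2) * (r - rho * sqrt((1 - r^2) / (1 - rho^2))),
#' where s1 and s2 are the residual SDs of the outcome-without-mediator
#' model (Y ~ X + C) and the mediator model (M ~ X + C), and r is the
#' sample correlation of their residuals. ACME(0) equals the point-estimate
#' ACME; the curve is monotone in rho and crosses zero exactly once, at
#' rho_zero = r (reported analytically and rounded to the grid).
#' Pointwise 95\% bootstrap bands are attached when `boot_B > 0`.
#'
#' @param fit a `mediation_fit`.
#' @param rho_grid grid of rho values, each strictly inside (-1, 1).
#' @param boot_B bootstrap replicates for the pointwise bands (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `sensitivity_curve`: data frame `curve` (rho,
#'   acme, lo, hi), `rho_zero` (analytic), `rho_zero_grid`.
#' @export
sensitivity_acme <- function(fit, rho_grid = seq(-0.9, 0.9, by = 0.05),
                             boot_B = 500L, seed = 1L) {
  stopifnot(inherits(fit, "mediation_fit"))
  if (any(abs(rho_grid) >= 1)) {
    stop("rho grid values must satisfy |rho| < 1", call. = FALSE)
  }
  eng <- fit$engine
  comp <- sens_components(eng$Xm, eng$M[, 1], eng$y)
  curve_fun <- function(rho, cp) {
    cp$beta0 * (cp$s1 / cp$s2) *
      (cp$r - rho * sqrt((1 - cp$r^2) / (1 - rho^2)))
  }
  acme_rho <- curve_fun(rho_grid, comp)
  lo <- hi <- rep(NA_real_, length(rho_grid))
  if (boot_B > 0) {
    set_seed_if(seed)
    n <- length(eng$y)
    draws <- matrix(NA_real_, boot_B, length(rho_grid))
    for (b in seq_len(boot_B)) {
      ib <- sample.int(n, n, replace = TRUE)
      cb <- sens_components(eng$Xm[ib, , drop = FALSE], eng$M[ib, 1],
                            eng$y[ib])
      draws[b, ] <- curve_fun(rho_grid, cb)
    }
    qs <- apply(draws, 2, stats::quantile, c(0.025, 0.975), na.rm = TRUE)
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  structure(list(curve = data.frame(rho = rho_grid, acme = acme_rho,
                                    lo = lo, hi = hi),
                 rho_zero = comp$r,
                 rho_zero_grid = round(comp$r / 0.05) * 0.05,
                 acme0 = curve_fun(0, comp), cpg = fit$cpg),
            class = "sensitivity_curve")
}

# Residual components of the rho-sensitivity closed form: residual SDs of
# Y ~ X + C and M ~ X + C (same design, hence same df) and the correlation
# of their residuals.
sens_components <- function(Xm, m, y) {
  fy <- ols_stats(Xm, y)
  fm <- ols_stats(Xm, m)
  list(beta0 = unname(fm$coef["exposure"]),
       s1 = fy$sigma, s2 = fm$sigma,
       r = stats::cor(fy$residuals, fm$residuals))
}

#' @export
print.sensitivity_curve <- function(x, ...) {
  cat(sprintf("rho-sensitivity of ACME for %s\n", x$cpg))
  cat(sprintf("  ACME(0) = %.4g; rho at which ACME = 0: %.3f (grid: %.2f)\n",
              x$acme0, x$rho_zero, x$rho_zero_grid))
  invisible(x)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$rho, cv$acme, type = "l", xlab = expression(rho),
                 ylab = "ACME", ...)
  if (!all(is.na(cv$lo))) {
    graphics::polygon(c(cv$rho, rev(cv$rho)), c(cv$lo, rev(cv$hi)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(cv$rho, cv$acme)
  }
  graphics::abline(h = 0, lty = 2)
  graphics::abline(v = x$rho_zero, lty = 3)
  invisible(x)
}
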