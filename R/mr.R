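# Two-step epigenetic Mendelian randomization. Step 1 asks whether the
# exposure causally shifts candidate CpG methylation, using external
# exposure-GWAS instruments; step 2 asks whether CpG methylation causally
# shifts the outcome, using in-sample cis-meQTL instruments. Both steps use
# fixed-effect inverse-variance-weighted (IVW) estimation with first-order
# weights; instruments are greedily LD-pruned on in-sample dosage
# correlation.

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW combining per-instrument Wald ratios with first-order
#' weights: estimate = sum(bx * by / se_by^2) / sum(bx^2 / se_by^2), SE =
#' sqrt(1 / sum(bx^2 / se_by^2)), Wald 95\% CI and two-sided normal p.
#' Equivalent to the slope of the zero-intercept regression of by on bx
#' weighted by 1/se_by^2; with a single instrument it reduces to the Wald
#' ratio by/bx.
#'
#' @param bx instrument-exposure effects.
#' @param by instrument-outcome effects.
#' @param se_by standard errors of `by` (> 0).
#' @param label optional step label carried in the result.
#' @return object of class `ivw_fit`: estimate, se, ci, p, n_instruments.
#' @export
ivw <- function(bx, by, se_by, label = "") {
  stopifnot(length(bx) == length(by), length(by) == length(se_by),
            length(bx) >= 1L)
  if (any(se_by <= 0)) stop("se_by must be positive", call. = FALSE)
  if (all(bx == 0)) {
    stop("all instrument-exposure effects are zero; no identification",
         call. = FALSE)
  }
  w <- 1 / se_by^2
  est <- sum(bx * by * w) / sum(bx^2 * w)
  se <- sqrt(1 / sum(bx^2 * w))
  structure(list(estimate = est, se = se,
                 ci = c(est - 1.96 * se, est + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(est / se)),
                 n_instruments = length(bx), label = label),
            class = "ivw_fit")
}

#' @export
print.ivw_fit <- function(x, digits = 3, ...) {
  cat(sprintf("IVW MR%s: %d IV(s), estimate %.*f (SE %.*f), CI [%.*f, %.*f], p = %.3g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n_instruments, digits, x$estimate, digits, x$se,
              digits, x$ci[1], digits, x$ci[2], x$p))
  invisible(x)
}

#' @export
coef.ivw_fit <- function(object, ...) c(estimate = object$estimate)

#' Greedy LD pruning
#'
#' SNPs are visited in order of ascending ranking p-value; a SNP is kept iff
#' the squared Pearson correlation of its dosages with every already-kept
#' SNP is below `r2_cut`. The retained set therefore has all pairwise
#' r-squared < `r2_cut`, and every dropped SNP is correlated with a
#' better-ranked kept SNP.
#'
#' @param geno `genotype_matrix` (or dosage matrix SNPs x samples).
#' @param ranking named numeric vector of p-values (names = snp ids) or a
#'   data frame with columns snp/p.
#' @param r2_cut squared-correlation threshold (default 0.1, strict `<`).
#' @return character vector of retained SNP ids, in ranking order.
#' @export
ld_prune <- function(geno, ranking, r2_cut = 0.1) {
  dos <- if (inherits(geno, "genotype_matrix")) geno$dosages else geno
  if (is.data.frame(ranking)) {
    ranking <- stats::setNames(ranking$p, ranking$snp)
  }
  snps <- intersect(names(ranking), rownames(dos))
  if (length(snps) == 0L) stop("no SNPs overlap the ranking", call. = FALSE)
  snps <- snps[order(ranking[snps])]
  kept <- character(0)
  for (s in snps) {
    v <- dos[s, ]
    if (stats::sd(v) == 0) next          # monomorphic: uninformative
    ok <- TRUE
    for (k in kept) {
      if (stats::cor(v, dos[k, ])^2 >= r2_cut) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  kept
}

#' Per-SNP association scan
#'
#' OLS of a trait on each SNP's dosage plus covariates; reports per-SNP
#' effect, SE and two-sided t p-value. Monomorphic SNPs are flagged rather
#' than fatal.
#'
#' @param geno `genotype_matrix`.
#' @param samples a `sample_table` with ids matching the dosage columns.
#' @param trait trait values: a column name in `samples`, or a numeric
#'   vector aligned with the dosage columns (e.g. one CpG's methylation).
#' @param covariates adjustment columns (default [mr_covariates()]).
#' @param snps optional subset of SNP ids.
#' @return data frame: snp, beta, se, p, flag.
#' @export
snp_assoc <- function(geno, samples, trait, covariates = mr_covariates(),
                      snps = NULL) {
  samples <- as.data.frame(samples)
  dos <- geno$dosages[, match(samples$sample_id, colnames(geno$dosages)),
                      drop = FALSE]
  if (anyNA(dos[1, ])) stop("samples missing from genotypes", call. = FALSE)
  if (is.character(trait) && length(trait) == 1L) {
    y <- samples[[trait]]
    if (is.null(y)) stop("trait column not found: ", trait, call. = FALSE)
  } else {
    y <- as.numeric(trait)
    if (length(y) != nrow(samples)) {
      stop("trait vector length must match samples", call. = FALSE)
    }
  }
  if (stats::var(y) == 0) stop("trait is constant", call. = FALSE)
  if (is.null(snps)) snps <- rownames(dos)
  C <- mm_design(samples, covariates)
  out <- do.call(rbind, lapply(snps, function(s) {
    g <- dos[s, ]
    if (stats::sd(g) == 0) {
      return(data.frame(snp = s, beta = NA_real_, se = NA_real_,
                        p = NA_real_, flag = "monomorphic",
                        stringsAsFactors = FALSE))
    }
    X <- cbind(C[, 1, drop = FALSE], dosage = g, C[, -1, drop = FALSE])
    f <- ols_stats(X, y)
    data.frame(snp = s, beta = unname(f$coef["dosage"]),
               se = unname(f$se["dosage"]), p = unname(f$p["dosage"]),
               flag = "", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' cis-meQTL instrument selection for one CpG
#'
#' SNPs on the CpG's chromosome within `window_bp` of its position (closed
#' interval, 1-based coordinates) are tested against the CpG's methylation
#' with [snp_assoc()]; those with p < `p_cut` are LD-pruned at `r2_cut`
#' (greedy, best p first) and returned as the instrument set.
#'
#' @param geno `genotype_matrix`.
#' @param beta CpGs x samples matrix.
#' @param annot CpG annotation (cpg, chr, pos).
#' @param samples a `sample_table`.
#' @param cpg CpG id (must be present in `annot`).
#' @param window_bp cis window half-width (default 1e6).
#' @param p_cut instrument p-value threshold (default 0.01).
#' @param r2_cut LD pruning threshold (default 0.1).
#' @param covariates adjustment set for the SNP-CpG associations.
#' @return object of class `instrument_set`: data frame with snp, beta, se,
#'   p for the retained instruments (zero rows when no SNP qualifies, which
#'   downstream IVW treats as a skip with warning).
#' @export
cis_meqtl_scan <- function(geno, beta, annot, samples, cpg,
                           window_bp = 1e6, p_cut = 0.01, r2_cut = 0.1,
                           covariates = mr_covariates()) {
  ai <- match(cpg, annot$cpg)
  if (is.na(ai)) stop("cpg not found in annotation: ", cpg, call. = FALSE)
  in_cis <- geno$info$chr == annot$chr[ai] &
    abs(geno$info$pos - annot$pos[ai]) <= window_bp
  snps <- geno$info$snp_id[in_cis]
  empty <- data.frame(snp = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(snps) == 0L) {
    return(structure(empty, cpg = cpg, class = c("instrument_set",
                                                 "data.frame")))
  }
  m <- beta[cpg, match(samples$sample_id, colnames(beta))]
  assoc <- snp_assoc(geno, samples, m, covariates, snps = snps)
  assoc <- assoc[assoc$flag == "" & assoc$p < p_cut, , drop = FALSE]
  if (nrow(assoc) == 0L) {
    return(structure(empty, cpg = cpg, class = c("instrument_set",
                                                 "data.frame")))
  }
  kept <- ld_prune(geno, stats::setNames(assoc$p, assoc$snp), r2_cut)
  out <- assoc[match(kept, assoc$snp), c("snp", "beta", "se", "p")]
  rownames(out) <- NULL
  structure(out, cpg = cpg, class = c("instrument_set", "data.frame"))
}

# Align external instrument effects to the cohort's ALT-dosage orientation:
# if the external effect allele is the REF allele, flip the sign.
harmonize_instruments <- function(external_stats, geno) {
  idx <- match(external_stats$snp, geno$info$snp_id)
  present <- !is.na(idx)
  es <- external_stats[present, , drop = FALSE]
  idx <- idx[present]
  flip <- !is.na(geno$info$ref[idx]) &
    es$effect_allele == geno$info$ref[idx]
  es$beta[flip] <- -es$beta[flip]
  es$dropped <- NULL
  attr(es, "n_dropped") <- sum(!present)
  es
}

#' Two-step epigenetic Mendelian randomization
#'
#' Step 1 (exposure -> CpG): external exposure-GWAS instruments with
#' p < `config$instrument_p`, present in the cohort genotypes, LD-pruned at
#' `config$ld_r2`; bx = external instrument-exposure effects (harmonized to
#' the cohort's ALT allele), by = in-sample SNP -> CpG effects (adjusted for
#' age, sex, race, 5 ancestry PCs). Step 2 (CpG -> outcome): cis-meQTL
#' instruments from [cis_meqtl_scan()]; bx = SNP -> CpG effects, by = SNP ->
#' outcome effects (adjusted for age, sex, 5 ancestry PCs; race optional via
#' `race_in_step2`). Both steps are IVW. A CpG is flagged concordant when
#' both steps have p < 0.05.
#'
#' @param cohort a `meth_cohort` (or list with samples, beta, annot, geno).
#' @param candidates `candidate_set` or character vector of CpG ids.
#' @param external_stats external instrument table (snp, effect_allele,
#'   beta, se, p).
#' @param config a [run_config()].
#' @param outcome outcome column for step 2 (default `"vacs_avg_after"`).
#' @param race_in_step2 include race in the step-2 outcome model.
#' @return object of class `two_step_mr`: data frame `table` with one row
#'   per CpG (step1/step2 estimates, SEs, CIs, p, instrument counts,
#'   concordant flag) plus the per-CpG `ivw_fit` objects.
#' @export
run_two_step_mr <- function(cohort, candidates, external_stats = NULL,
                            config = run_config(),
                            outcome = "vacs_avg_after",
                            race_in_step2 = FALSE) {
  external_stats <- external_stats %||% cohort$external_stats
  cpgs <- if (inherits(candidates, "candidate_set")) candidates$cpg
          else as.character(candidates)
  samples <- cohort$samples
  geno <- cohort$geno

  ## step-1 instrument set: external p filter, presence, LD pruning
  es <- external_stats[external_stats$p < config$instrument_p, , drop = FALSE]
  es <- harmonize_instruments(es, geno)
  if (attr(es, "n_dropped") > 0) {
    warning(attr(es, "n_dropped"),
            " instrument SNP(s) missing from genotypes; dropped",
            call. = FALSE)
  }
  kept <- if (nrow(es) > 0) {
    ld_prune(geno, stats::setNames(es$p, es$snp), config$ld_r2)
  } else character(0)
  es <- es[match(kept, es$snp), , drop = FALSE]

  step2_cov <- mr_outcome_covariates(race = race_in_step2)
  out_assoc_cache <- new.env(parent = emptyenv())

  rows <- list()
  fits <- list()
  for (cpg in cpgs) {
    s1 <- s2 <- NULL
    ## step 1: cocaine -> methylation
    if (nrow(es) >= 1L) {
      m <- cohort$beta[cpg, match(samples$sample_id, colnames(cohort$beta))]
      by1 <- snp_assoc(geno, samples, m, mr_covariates(), snps = es$snp)
      ok <- by1$flag == ""
      if (any(ok)) {
        s1 <- ivw(es$beta[ok], by1$beta[ok], by1$se[ok],
                  label = "exposure->cpg")
      }
    }
    if (is.null(s1)) {
      warning("no step-1 instruments for ", cpg, "; skipped", call. = FALSE)
    }
    ## step 2: methylation -> outcome via cis-meQTLs
    iv2 <- cis_meqtl_scan(geno, cohort$beta, cohort$annot, samples, cpg,
                          window_bp = config$cis_window,
                          p_cut = config$meqtl_p, r2_cut = config$ld_r2)
    if (nrow(iv2) >= 1L) {
      by2 <- do.call(rbind, lapply(iv2$snp, function(s) {
        if (!exists(s, envir = out_assoc_cache)) {
          assign(s, snp_assoc(geno, samples, outcome, step2_cov, snps = s),
                 envir = out_assoc_cache)
        }
        get(s, envir = out_assoc_cache)
      }))
      s2 <- ivw(iv2$beta, by2$beta, by2$se, label = "cpg->outcome")
    } else {
      warning("no cis-meQTL instruments for ", cpg, "; step 2 skipped",
              call. = FALSE)
    }
    rows[[cpg]] <- data.frame(
      cpg = cpg,
      step1_n_iv = if (!is.null(s1)) s1$n_instruments else 0L,
      step1_estimate = if (!is.null(s1)) s1$estimate else NA_real_,
      step1_se = if (!is.null(s1)) s1$se else NA_real_,
      step1_ci_lo = if (!is.null(s1)) s1$ci[1] else NA_real_,
      step1_ci_hi = if (!is.null(s1)) s1$ci[2] else NA_real_,
      step1_p = if (!is.null(s1)) s1$p else NA_real_,
      step2_n_iv = if (!is.null(s2)) s2$n_instruments else 0L,
      step2_estimate = if (!is.null(s2)) s2$estimate else NA_real_,
      step2_se = if (!is.null(s2)) s2$se else NA_real_,
      step2_ci_lo = if (!is.null(s2)) s2$ci[1] else NA_real_,
      step2_ci_hi = if (!is.null(s2)) s2$ci[2] else NA_real_,
      step2_p = if (!is.null(s2)) s2$p else NA_real_,
      concordant = !is.null(s1) && !is.null(s2) &&
        s1$p < 0.05 && s2$p < 0.05,
      stringsAsFactors = FALSE)
    fits[[cpg]] <- list(step1 = s1, step2 = s2)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, instruments_step1 = es,
                 config = config), class = "two_step_mr")
}

#' @export
print.two_step_mr <- function(x, ...) {
  cat(sprintf("Two-step epigenetic MR over %d CpGs (%d step-1 IVs)\n",
              nrow(x$table), nrow(x$instruments_step1)))
  cat(sprintf("  concordant (both steps p < 0.05): %d\n",
              sum(x$table$concordant)))
  invisible(x)
}

#' MR of exposure on cell-type proportions
#'
#' Negative-control analysis: step-1-style IVW of the exposure on each of
#' the six cell-type proportions, with the same external instruments as the
#' main step 1. The exposure should not shift cell composition; significant
#' estimates would indicate that apparent methylation mediation reflects
#' cell-mixture change.
#'
#' @inheritParams run_two_step_mr
#' @return data frame with one row per cell type: estimate, se, ci, p,
#'   n_instruments.
#' @export
mr_cell_proportions <- function(cohort, external_stats = NULL,
                                config = run_config()) {
  external_stats <- external_stats %||% cohort$external_stats
  samples <- cohort$samples
  miss <- setdiff(cell_prop_cols(), names(samples))
  if (length(miss) > 0L) {
    stop("cell proportion column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  es <- external_stats[external_stats$p < config$instrument_p, , drop = FALSE]
  es <- harmonize_instruments(es, cohort$geno)
  kept <- if (nrow(es) > 0) {
    ld_prune(cohort$geno, stats::setNames(es$p, es$snp), config$ld_r2)
  } else character(0)
  es <- es[match(kept, es$snp), , drop = FALSE]
  if (nrow(es) == 0L) stop("no usable instruments", call. = FALSE)
  out <- do.call(rbind, lapply(cell_prop_cols(), function(ct) {
    by <- snp_assoc(cohort$geno, samples, ct, mr_covariates(),
                    snps = es$snp)
    ok <- by$flag == ""
    f <- ivw(es$beta[ok], by$beta[ok], by$se[ok], label = ct)
    data.frame(cell_type = ct, n_iv = f$n_instruments,
               estimate = f$estimate, se = f$se, ci_lo = f$ci[1],
               ci_hi = f$ci[2], p = f$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
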