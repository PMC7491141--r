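# Epigenome-wide association scans: per-CpG OLS of methylation on a
# phenotype plus covariates (one shared design, so all CpGs are solved in a
# single QR factorisation), genomic-inflation diagnostics, CD4-relevant PC
# covariates, dual-threshold candidate selection, and the other-substance
# confound check.

#' Epigenome-wide association scan
#'
#' For each CpG, fits methylation ~ phenotype + covariates by OLS (with
#' intercept) and reports the phenotype coefficient in beta-value units per
#' phenotype unit, with SE, t and two-sided p. Constant CpG columns are
#' flagged (`flag = "constant"`) with effect 0 and p 1 rather than failing
#' the scan. The genomic inflation factor of the scan is attached.
#'
#' The binary exposure phenotype `"exposure_persistent"` is available as a
#' pseudo-column: it contrasts the persistent (1) vs none (0) groups and
#' drops inconsistent reporters from the scan.
#'
#' @param beta CpGs x samples matrix.
#' @param samples a `sample_table` whose `sample_id`s match `colnames(beta)`.
#' @param phenotype phenotype column name, or `"exposure_persistent"`.
#' @param covariates covariate column names (see [ewa_covariates()]).
#' @param extra_pcs optional numeric matrix of additional covariate columns
#'   aligned with `samples` rows (e.g. CD4 PCs from [cd4_pc_covariates()]).
#' @return object of class `ewa_result`: data frame `table` with one row per
#'   CpG (cpg, effect, se, t, p, flag) plus metadata (phenotype, covariates,
#'   n, lambda).
#' @export
run_ewa <- function(beta, samples, phenotype,
                    covariates = ewa_covariates(), extra_pcs = NULL) {
  samples <- as.data.frame(samples)
  if (!is.null(extra_pcs)) {
    extra_pcs <- as.matrix(extra_pcs)
    if (nrow(extra_pcs) != nrow(samples)) {
      stop("extra_pcs rows must match samples", call. = FALSE)
    }
    colnames(extra_pcs) <- colnames(extra_pcs) %||%
      paste0("xpc", seq_len(ncol(extra_pcs)))
    samples <- cbind(samples, extra_pcs)
    covariates <- c(covariates, colnames(extra_pcs))
  }
  if (phenotype == "exposure_persistent") {
    keep <- samples$exposure_group %in% c("none", "persistent")
    samples <- samples[keep, , drop = FALSE]
    samples$exposure_persistent <-
      as.numeric(samples$exposure_group == "persistent")
  }
  ph <- samples[[phenotype]]
  if (is.null(ph)) stop("phenotype column not found: ", phenotype,
                        call. = FALSE)
  if (stats::var(as.numeric(ph)) == 0) {
    stop("phenotype is constant", call. = FALSE)
  }
  idx <- match(samples$sample_id, colnames(beta))
  if (anyNA(idx)) stop("samples missing from beta matrix", call. = FALSE)
  Y <- t(beta[, idx, drop = FALSE])          # samples x CpGs
  X <- mm_design(samples, c(phenotype, covariates))
  const <- apply(Y, 2, function(col) stats::var(col) == 0)
  res <- ols_multi_focal(X, Y, focal = phenotype)
  tab <- data.frame(cpg = colnames(Y),
                    effect = unname(res$effect), se = unname(res$se),
                    t = unname(res$t), p = unname(res$p),
                    flag = "", stringsAsFactors = FALSE)
  if (any(const)) {
    tab$effect[const] <- 0
    tab$se[const] <- NA_real_
    tab$t[const] <- 0
    tab$p[const] <- 1
    tab$flag[const] <- "constant"
  }
  structure(list(table = tab, phenotype = phenotype,
                 covariates = covariates, n = nrow(X),
                 lambda = genomic_inflation(pmax(tab$p[!const], 1e-300))),
            class = "ewa_result")
}

#' @export
print.ewa_result <- function(x, ...) {
  cat(sprintf("EWA scan of %s: %d CpGs, n = %d, lambda = %.3f\n",
              x$phenotype, nrow(x$table), x$n, x$lambda))
  top <- x$table[order(x$table$p), ][1:min(5, nrow(x$table)), ]
  print(format(top, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Genomic inflation factor
#'
#' lambda = median of the association chi-square statistics (obtained from
#' the two-sided p-values via the chi-square(1) quantile) divided by the
#' null median qchisq(0.5, 1) = 0.4549364.
#'
#' @param pvals p-values in (0, 1].
#' @return lambda (1 = perfectly calibrated).
#' @export
genomic_inflation <- function(pvals) {
  pvals <- pvals[!is.na(pvals)]
  if (length(pvals) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0,1]",
                                        call. = FALSE)
  chisq <- stats::qchisq(pvals, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' CD4-relevant principal-component covariates
#'
#' Extracts the top `n_top` CpGs of a CD4 T-cell relevance ranking that are
#' present in the beta matrix and returns the leading `n_pc` principal
#' components of that submatrix (samples in rows; centred, not scaled).
#' These PCs absorb CD4-driven methylation variation in the severity scan,
#' whose index includes the CD4 count. A warning is issued when the
#' cumulative variance fraction of the returned PCs is <= 0.80.
#'
#' @param beta CpGs x samples matrix.
#' @param cd4_ranking data frame with columns `cpg` and `score` (higher =
#'   more CD4-relevant).
#' @param n_top number of top-ranked CpGs used (default 1000; fatal if
#'   fewer overlap the matrix).
#' @param n_pc number of PCs returned (default 2).
#' @return samples x n_pc matrix of PC scores (columns `cd4pc1`, ...), with
#'   attributes `var_fraction` (per-PC) and `cum_var_fraction`.
#' @export
cd4_pc_covariates <- function(beta, cd4_ranking, n_top = 1000L, n_pc = 2L) {
  ranked <- cd4_ranking[order(-cd4_ranking$score), "cpg"]
  ranked <- ranked[ranked %in% rownames(beta)]
  if (length(ranked) < n_top) {
    stop("only ", length(ranked), " ranked CpGs overlap the beta matrix; ",
         n_top, " required", call. = FALSE)
  }
  sub <- t(beta[ranked[seq_len(n_top)], , drop = FALSE])
  pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(n_pc, ncol(pc$x))
  scores <- pc$x[, seq_len(n_pc), drop = FALSE]
  colnames(scores) <- paste0("cd4pc", seq_len(n_pc))
  cum_var <- sum(var_frac[seq_len(n_pc)])
  if (cum_var <= 0.80) {
    warning(sprintf("top %d CD4 PCs explain only %.1f%% of variation",
                    n_pc, 100 * cum_var), call. = FALSE)
  }
  attr(scores, "var_fraction") <- var_frac[seq_len(n_pc)]
  attr(scores, "cum_var_fraction") <- cum_var
  scores
}

#' Dual-threshold candidate selection
#'
#' Selects CpGs with p strictly below `p_cut` in both the exposure and the
#' outcome scan (selection basis `both_thresholds`); ids in `forced` are
#' appended with basis `forced_include` regardless of p-values. Symmetric in
#' its two scans and idempotent.
#'
#' @param ewa_exposure,ewa_outcome `ewa_result` objects over the same CpG
#'   universe.
#' @param p_cut selection threshold (default 0.001, strict `<`).
#' @param forced CpG ids to force-include (fatal if absent from the scans).
#' @return object of class `candidate_set`: data frame with cpg, basis,
#'   p_exposure, p_outcome; thresholds recorded as attributes.
#' @export
select_candidates <- function(ewa_exposure, ewa_outcome, p_cut = 0.001,
                              forced = character(0)) {
  t1 <- ewa_exposure$table
  t2 <- ewa_outcome$table
  if (!setequal(t1$cpg, t2$cpg)) {
    stop("the two scans must cover the same CpG universe", call. = FALSE)
  }
  t2 <- t2[match(t1$cpg, t2$cpg), ]
  both <- t1$p < p_cut & t2$p < p_cut
  out <- data.frame(cpg = t1$cpg[both], basis = "both_thresholds",
                    p_exposure = t1$p[both], p_outcome = t2$p[both],
                    stringsAsFactors = FALSE)
  forced <- setdiff(forced, out$cpg)
  if (length(forced) > 0L) {
    miss <- setdiff(forced, t1$cpg)
    if (length(miss) > 0L) {
      stop("forced CpG(s) absent from scans: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    fi <- match(forced, t1$cpg)
    out <- rbind(out, data.frame(cpg = forced, basis = "forced_include",
                                 p_exposure = t1$p[fi],
                                 p_outcome = t2$p[match(forced, t2$cpg)],
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$p_exposure), ]
  rownames(out) <- NULL
  structure(out, p_cut = p_cut, class = c("candidate_set", "data.frame"))
}

#' Other-substance confound check
#'
#' For each candidate CpG and each substance-use field, fits the same
#' covariate-adjusted single-site model as the EWA scan (methylation ~
#' substance + covariates) and reports effect and p, with a flag where
#' p < 0.05.
#'
#' @param beta CpGs x samples matrix.
#' @param samples a `sample_table`.
#' @param candidates `candidate_set` or character vector of CpG ids.
#' @param substances substance columns (default alcohol/cannabis/opioid).
#' @param covariates adjustment set (default [ewa_covariates()]).
#' @return data frame: cpg, substance, effect, se, p, flagged.
#' @export
substance_confound_check <- function(beta, samples, candidates,
                                     substances = c("alcohol_auditc",
                                                    "cannabis_freq",
                                                    "opioid_freq"),
                                     covariates = ewa_covariates()) {
  cpgs <- if (inherits(candidates, "candidate_set")) candidates$cpg
          else as.character(candidates)
  if (length(cpgs) == 0L) {
    return(data.frame(cpg = character(0), substance = character(0),
                      effect = numeric(0), se = numeric(0), p = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  miss <- setdiff(substances, names(samples))
  if (length(miss) > 0L) {
    stop("substance column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(substances, function(sub) {
    scan <- run_ewa(beta[cpgs, , drop = FALSE], samples, sub, covariates)
    data.frame(cpg = scan$table$cpg, substance = sub,
               effect = scan$table$effect, se = scan$table$se,
               p = scan$table$p, flagged = scan$table$p < 0.05,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
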