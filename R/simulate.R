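# Synthetic-cohort generator. Emulates a veteran HIV cohort with a
# substance-use exposure recorded both as a binary persistent/none contrast
# (5-visit consistency) and as an ordinal 0-5 frequency, beta-valued
# methylation with cell-mixture / meQTL / technical structure, a continuous
# severity outcome driven by exposure + mediator CpGs + confounders, and
# exponential survival with an exposure-frequency-dependent hazard. Known
# ground truth (sim_truth) is returned for recovery testing.

#' Simulation parameters
#'
#' Defaults describe the study conditions the pipeline is designed for: a
#' cohort of 875 with roughly 30\% persistent users, 23\% never-users and the
#' rest inconsistent reporters; 12 true mediator CpGs whose exposure effects
#' are injected on the logit scale and which share a latent pathway factor
#' (`pathway_sd`), so that single-site mediation proportions land in the
#' 10-30\% range while the joint mediation effect stays well below their sum;
#' eight weak exposure-instrument SNPs; and planted cis-meQTLs for the first
#' `n_meqtl_cpgs` CpGs.
#'
#' @param n_samples cohort size.
#' @param n_cpgs number of CpGs on the synthetic array.
#' @param n_true_mediators number of CpGs with a causal exposure -> CpG ->
#'   outcome path (CpGs 1..n_true_mediators).
#' @param alpha0 direct exposure -> outcome effect (outcome units, persistent
#'   vs none contrast).
#' @param alpha1 vector (recycled to `n_true_mediators`) of mediator ->
#'   outcome effects, outcome units per beta-value unit.
#' @param beta0 vector (recycled) of exposure -> mediator effects on the
#'   logit scale.
#' @param confounder_effects named list with `age`, `sex`, `smoking` effects
#'   on the outcome, and `age_m`, `sex_m`, `smoking_m` logit-scale effects on
#'   every mediator CpG.
#' @param sigma_m per-CpG logit-scale noise SD.
#' @param sigma_y outcome-model noise SD.
#' @param pathway_sd SD of the shared latent pathway factor loading on the
#'   mediator CpGs (0 = independent mediators).
#' @param dirichlet_conc total concentration of the Dirichlet cell-mixture
#'   draw (larger = less between-sample variation).
#' @param n_snps total SNPs; `n_instrument_snps` of them act on the exposure
#'   liability with per-allele effect `instrument_effect`.
#' @param n_instrument_snps number of exposure-instrument SNPs.
#' @param instrument_effect per-allele effect on the exposure liability.
#' @param n_meqtl_cpgs number of leading CpGs given planted cis-meQTLs.
#' @param n_cis_snps planted cis-meQTL SNPs per such CpG.
#' @param meqtl_effect planted meQTL effect in beta units per allele.
#' @param maf_range minor-allele-frequency range for simulated SNPs.
#' @param hazard_coef log hazard ratio per exposure-frequency unit.
#' @param base_hazard baseline yearly hazard.
#' @param censor_rate yearly rate of independent exponential censoring
#'   (administrative censoring at 10 years applies regardless).
#' @param cellprop_exposure_effect exposure -> granulocyte-fraction shift
#'   (0 by default; used as an MR positive control).
#' @param n_ncpc number of negative-control (technical) PCs.
#' @param seed RNG seed; same seed, same cohort, bit for bit.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 875L, n_cpgs = 2000L,
                       n_true_mediators = min(12L, n_cpgs),
                       alpha0 = 0.174,
                       alpha1 = -0.26,
                       beta0 = -0.25,
                       confounder_effects = list(age = 0.01, sex = 0.2,
                                                 smoking = 0.15,
                                                 age_m = 0.004, sex_m = 0.05,
                                                 smoking_m = 0.08),
                       sigma_m = 0.35, sigma_y = 0.5,
                       pathway_sd = 0.3,
                       dirichlet_conc = 60,
                       n_snps = 120L, n_instrument_snps = 8L,
                       instrument_effect = 0.15,
                       n_meqtl_cpgs = 20L, n_cis_snps = 3L,
                       meqtl_effect = 0.05,
                       maf_range = c(0.1, 0.5),
                       hazard_coef = log(1.10), base_hazard = 0.03,
                       censor_rate = 0.04,
                       cellprop_exposure_effect = 0,
                       n_ncpc = 5L, seed = 1L) {
  p <- list(n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
            n_true_mediators = as.integer(n_true_mediators),
            alpha0 = alpha0,
            alpha1 = rep_len(alpha1, n_true_mediators),
            beta0 = rep_len(beta0, n_true_mediators),
            confounder_effects = confounder_effects,
            sigma_m = sigma_m, sigma_y = sigma_y, pathway_sd = pathway_sd,
            dirichlet_conc = dirichlet_conc,
            n_snps = as.integer(n_snps),
            n_instrument_snps = as.integer(n_instrument_snps),
            instrument_effect = instrument_effect,
            n_meqtl_cpgs = as.integer(max(n_meqtl_cpgs, n_true_mediators)),
            n_cis_snps = as.integer(n_cis_snps),
            meqtl_effect = meqtl_effect, maf_range = maf_range,
            hazard_coef = hazard_coef, base_hazard = base_hazard,
            censor_rate = censor_rate,
            cellprop_exposure_effect = cellprop_exposure_effect,
            n_ncpc = as.integer(n_ncpc), seed = as.integer(seed))
  stopifnot(p$n_true_mediators <= p$n_cpgs,
            p$sigma_m > 0, p$sigma_y > 0, p$dirichlet_conc > 0,
            p$maf_range[1] > 0.01, p$maf_range[2] <= 0.5,
            p$n_instrument_snps <= p$n_snps, p$base_hazard > 0)
  structure(p, class = "sim_params")
}

# Gauss-Hermite nodes/weights by Golub-Welsch; used to integrate the
# logistic link over Gaussian noise when converting logit-scale effects to
# induced beta-scale shifts.
gauss_hermite <- function(k = 32L) {
  i <- seq_len(k - 1L)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1, ]^2)
}

# E[plogis(mu + s*Z)], Z ~ N(0,1), elementwise over mu.
logit_normal_mean <- function(mu, s, gh = gauss_hermite()) {
  z <- sqrt(2) * gh$nodes
  out <- numeric(length(mu))
  for (q in seq_along(z)) out <- out + gh$weights[q] * stats::plogis(mu + s * z[q])
  out
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates from plausible marginals (age ~ N(50, 8), mostly male,
#' majority African-American), SNP dosages ~ Binomial(2, MAF), an exposure
#' liability as the sum of weak instrument-SNP effects plus standard normal
#' noise (thresholded by liability rank into the ordinal 0-5 frequency and
#' the persistent/none/inconsistent groups, so both exposure codings share
#' one construct), beta-valued methylation on the logit scale (baseline +
#' exposure effect for mediator CpGs + cell-mixture loading + planted meQTL
#' dosage effect + shared pathway factor + noise), a continuous severity
#' outcome `vacs_avg_after` = direct exposure effect + mediator effects +
#' confounders + noise (and an analogous `vacs_at_draw` with independent
#' noise for candidate-selection scans), and exponential survival with
#' hazard increasing in exposure frequency.
#'
#' The returned `truth` reports exposure -> mediator effects on the analysis
#' (beta-value) scale as the numerically integrated expectation difference
#' between exposed and unexposed, so generating truth is directly comparable
#' to regression estimates.
#'
#' @param params a [sim_params()] object.
#' @return list of class `meth_cohort`: `samples` (sample_table), `beta`
#'   (CpGs x samples), `annot`, `geno` (genotype_matrix), `external_stats`
#'   (emulated exposure-GWAS instrument table), `cd4_ranking`, `truth`
#'   (sim_truth).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_samples
  n_cpg <- params$n_cpgs
  n_med <- params$n_true_mediators
  ce <- params$confounder_effects

  ## ---- covariates -------------------------------------------------------
  age <- round(stats::rnorm(n, 50, 8), 1)
  sex <- factor(ifelse(stats::runif(n) < 0.975, "male", "female"),
                levels = c("male", "female"))
  race <- factor(sample(c("caucasian", "african_american", "other"), n,
                        replace = TRUE, prob = c(0.20, 0.67, 0.13)),
                 levels = c("caucasian", "african_american", "other"))
  smoking <- stats::rbinom(n, 1, 0.53)
  adherence <- stats::rbinom(n, 1, 0.78)
  alcohol_auditc <- sample(0:12, n, replace = TRUE,
                           prob = stats::dgeom(0:12, 0.25))
  cannabis_freq <- sample(0:5, n, replace = TRUE,
                          prob = c(0.45, 0.30, 0.10, 0.08, 0.04, 0.03))
  opioid_freq <- sample(0:5, n, replace = TRUE,
                        prob = c(0.60, 0.25, 0.06, 0.05, 0.02, 0.02))
  wbc <- round(pmax(stats::rnorm(n, 6.5, 1.8), 2), 2)
  ancestry <- matrix(stats::rnorm(n * 5), n, 5,
                     dimnames = list(NULL, paste0("apc", 1:5)))
  ncpc <- matrix(stats::rnorm(n * params$n_ncpc), n, params$n_ncpc,
                 dimnames = list(NULL, paste0("ncpc", seq_len(params$n_ncpc))))

  ## ---- genotypes --------------------------------------------------------
  n_meqtl_cpg <- min(params$n_meqtl_cpgs, n_cpg)
  n_cis_total <- n_meqtl_cpg * params$n_cis_snps
  n_snps <- max(params$n_snps, params$n_instrument_snps + n_cis_total)
  maf <- stats::runif(n_snps, params$maf_range[1], params$maf_range[2])
  dosages <- matrix(stats::rbinom(n_snps * n, 2, rep(maf, n)),
                    nrow = n_snps, ncol = n)
  if (all(maf == 0)) stop("degenerate params: all-zero MAF", call. = FALSE)
  snp_id <- sprintf("rs%06d", seq_len(n_snps))
  sample_id <- sprintf("S%04d", seq_len(n))
  colnames(dosages) <- sample_id

  ## CpG layout: chromosomes 2-22, 3 Mb apart within chromosome, so cis
  ## windows (1 Mb) never overlap across CpGs. Instruments live on chr 1.
  cpg_id <- sprintf("cg%07d", seq_len(n_cpg))
  cpg_chr <- as.character(2L + (seq_len(n_cpg) - 1L) %% 21L)
  cpg_pos <- 10e6 + ((seq_len(n_cpg) - 1L) %/% 21L) * 3e6
  annot <- data.frame(cpg = cpg_id, chr = cpg_chr, pos = round(cpg_pos),
                      gene = sprintf("GENE%04d", seq_len(n_cpg)),
                      gene_group = sample(c("TSS200", "TSS1500", "Body",
                                            "5UTR", "3UTR"), n_cpg, TRUE),
                      island_relation = sample(c("Island", "N_Shore",
                                                 "S_Shore", "OpenSea"),
                                               n_cpg, TRUE),
                      stringsAsFactors = FALSE)

  snp_chr <- character(n_snps)
  snp_pos <- numeric(n_snps)
  iv_idx <- seq_len(params$n_instrument_snps)
  snp_chr[iv_idx] <- "1"
  snp_pos[iv_idx] <- iv_idx * 2e6
  cis_offsets <- c(-5e5, 2.5e5, 6e5, -8e5, 4e5, 9e5)
  meqtl_map <- NULL
  k <- params$n_instrument_snps
  for (j in seq_len(n_meqtl_cpg)) {
    for (s in seq_len(params$n_cis_snps)) {
      k <- k + 1L
      snp_chr[k] <- cpg_chr[j]
      snp_pos[k] <- cpg_pos[j] +
        cis_offsets[(s - 1L) %% length(cis_offsets) + 1L]
      meqtl_map <- rbind(meqtl_map,
                         data.frame(cpg = cpg_id[j], snp = snp_id[k],
                                    effect_beta = params$meqtl_effect,
                                    stringsAsFactors = FALSE))
    }
  }
  if (k < n_snps) {   # background SNPs scattered away from any cis window
    bg <- (k + 1L):n_snps
    snp_chr[bg] <- as.character(2L + (bg %% 21L))
    snp_pos[bg] <- 5e5 + (bg %% 37L) * 1.1e5
  }
  geno_info <- data.frame(snp_id = snp_id, chr = snp_chr, pos = snp_pos,
                          ref = "A", alt = "B", maf = pmin(maf, 1 - maf),
                          stringsAsFactors = FALSE)
  geno <- new_genotype_matrix(dosages, geno_info)

  ## ---- exposure liability -> frequency + persistence groups -------------
  w <- params$instrument_effect
  liab <- drop(crossprod(dosages[iv_idx, , drop = FALSE] - 2 * maf[iv_idx],
                         rep(w, length(iv_idx)))) + stats::rnorm(n)
  rk <- rank(liab, ties.method = "first") / n
  freq_cut <- cumsum(c(0.387, 0.376, 0.085, 0.072, 0.027))
  exposure_freq <- findInterval(rk, freq_cut)          # 0..5
  exposure_group <- factor(ifelse(rk <= 0.231, "none",
                                  ifelse(rk > 1 - 0.303, "persistent",
                                         "inconsistent")),
                           levels = c("none", "inconsistent", "persistent"))
  x_gen <- c(none = 0, inconsistent = 0.5, persistent = 1)[
    as.character(exposure_group)]

  ## ---- cell-type proportions -------------------------------------------
  cell_means <- c(cd4t = 0.15, cd8t = 0.10, nk = 0.05, bcell = 0.05,
                  mono = 0.10, gran = 0.55)
  props <- rdirichlet1(n, cell_means * params$dirichlet_conc)
  colnames(props) <- names(cell_means)
  if (params$cellprop_exposure_effect != 0) {
    shift <- params$cellprop_exposure_effect * x_gen
    gran_new <- pmin(pmax(props[, "gran"] + shift, 0.05), 0.9)
    scale_other <- (1 - gran_new) / (1 - props[, "gran"])
    props[, colnames(props) != "gran"] <-
      props[, colnames(props) != "gran"] * scale_other
    props[, "gran"] <- gran_new
  }

  ## ---- methylation ------------------------------------------------------
  m0 <- stats::runif(n_cpg, stats::qlogis(0.2), stats::qlogis(0.8))
  cd4_load <- stats::rnorm(n_cpg, 0, 2.5)
  gran_load <- stats::rnorm(n_cpg, 0, 0.8)
  n_tech <- min(2L, params$n_ncpc)
  tech_load <- matrix(stats::rnorm(n_cpg * max(n_tech, 1L), 0, 0.02), n_cpg)
  pathway <- stats::rnorm(n)                       # latent shared factor
  path_load <- c(rep(params$pathway_sd, n_med), rep(0, n_cpg - n_med))
  b0_logit <- c(params$beta0, rep(0, n_cpg - n_med))

  cd4_c <- props[, "cd4t"] - mean(props[, "cd4t"])
  gran_c <- props[, "gran"] - mean(props[, "gran"])
  conf_m <- ce$age_m * (age - 50) + ce$sex_m * (sex == "female") +
    ce$smoking_m * smoking

  lp <- matrix(m0, n_cpg, n, byrow = FALSE) +
    outer(cd4_load, cd4_c) + outer(gran_load, gran_c) +
    (if (n_tech > 0) tech_load[, seq_len(n_tech), drop = FALSE] %*%
       t(ncpc[, seq_len(n_tech), drop = FALSE]) else 0) +
    outer(path_load, pathway) +
    outer(b0_logit, x_gen) +
    matrix(conf_m, n_cpg, n, byrow = TRUE)
  ## planted meQTL effects, converted from beta units/allele to logit scale
  ## via the logistic derivative at the CpG's baseline level
  if (!is.null(meqtl_map)) {
    for (r in seq_len(nrow(meqtl_map))) {
      j <- match(meqtl_map$cpg[r], cpg_id)
      si <- match(meqtl_map$snp[r], snp_id)
      pj <- stats::plogis(m0[j])
      lp[j, ] <- lp[j, ] + meqtl_map$effect_beta[r] / (pj * (1 - pj)) *
        (dosages[si, ] - 2 * maf[si])
    }
  }
  noise_m <- matrix(stats::rnorm(n_cpg * n, 0, params$sigma_m), n_cpg, n)
  beta_mat <- stats::plogis(lp + noise_m)
  beta_mat <- pmin(pmax(beta_mat, 1e-8), 1 - 1e-8)
  dimnames(beta_mat) <- list(cpg_id, sample_id)

  ## ---- induced beta-scale exposure effects (analysis-scale truth) -------
  gh <- gauss_hermite()
  s_marg <- sqrt(params$sigma_m^2 + params$pathway_sd^2)
  analysis <- exposure_group %in% c("none", "persistent")
  beta0_beta <- numeric(n_med)
  resid_sd_beta <- numeric(n_med)
  for (j in seq_len(n_med)) {
    lp_nox <- lp[j, ] - outer(path_load, pathway)[j, ] -
      b0_logit[j] * x_gen
    mu1 <- logit_normal_mean(lp_nox[analysis] + b0_logit[j], s_marg, gh)
    mu0 <- logit_normal_mean(lp_nox[analysis], s_marg, gh)
    beta0_beta[j] <- mean(mu1 - mu0)
    mu_obs <- logit_normal_mean(lp_nox + b0_logit[j] * x_gen, s_marg, gh)
    resid_sd_beta[j] <- stats::sd(beta_mat[j, ] - mu_obs)
  }

  ## ---- outcomes ---------------------------------------------------------
  med_part <- if (n_med > 0) {
    drop(crossprod(beta_mat[seq_len(n_med), , drop = FALSE] -
                     stats::plogis(m0[seq_len(n_med)]), params$alpha1))
  } else 0
  conf_y <- ce$age * (age - 50) + ce$sex * (sex == "female") +
    ce$smoking * smoking
  lin_pred <- params$alpha0 * x_gen + med_part + conf_y
  vacs_avg_after <- pmax(39 + lin_pred + stats::rnorm(n, 0, params$sigma_y), 0)
  vacs_at_draw <- pmax(30 + lin_pred + stats::rnorm(n, 0, params$sigma_y), 0)

  ## ---- survival ---------------------------------------------------------
  rate <- params$base_hazard * exp(params$hazard_coef * exposure_freq)
  t_event <- stats::rexp(n, rate)
  t_cens <- pmin(stats::rexp(n, params$censor_rate), 10)
  surv_years <- pmax(pmin(t_event, t_cens), 1e-3)
  event <- as.integer(t_event <= t_cens)

  samples <- data.frame(sample_id = sample_id,
                        exposure_group = exposure_group,
                        exposure_freq = exposure_freq,
                        sex = sex, age = age, race = race,
                        smoking = smoking, adherence = adherence,
                        alcohol_auditc = alcohol_auditc,
                        cannabis_freq = cannabis_freq,
                        opioid_freq = opioid_freq, wbc = wbc,
                        props, ncpc, ancestry,
                        vacs_at_draw = vacs_at_draw,
                        vacs_avg_after = vacs_avg_after,
                        surv_years = surv_years, event = event,
                        stringsAsFactors = FALSE)
  samples <- validate_sample_table(samples)

  ## ---- emulated external exposure-GWAS summary statistics ---------------
  ext_se <- 0.02
  ext_beta <- rep(w, length(iv_idx)) + stats::rnorm(length(iv_idx), 0, ext_se)
  external_stats <- data.frame(snp = snp_id[iv_idx], effect_allele = "B",
                               beta = ext_beta, se = ext_se,
                               p = 2 * stats::pnorm(-abs(ext_beta / ext_se)),
                               stringsAsFactors = FALSE)

  cd4_ranking <- data.frame(cpg = cpg_id, score = abs(cd4_load),
                            stringsAsFactors = FALSE)
  cd4_ranking <- cd4_ranking[order(-cd4_ranking$score), ]

  acme <- params$alpha1 * beta0_beta
  total_effect <- params$alpha0 + sum(acme)
  truth <- structure(list(
    mediators = data.frame(cpg = cpg_id[seq_len(n_med)],
                           alpha1 = params$alpha1,
                           beta0_logit = params$beta0,
                           beta0_beta = beta0_beta,
                           acme = acme,
                           resid_sd_beta = resid_sd_beta,
                           stringsAsFactors = FALSE),
    alpha0 = params$alpha0,
    total_effect = total_effect,
    pm_joint = if (abs(total_effect) > 1e-12) sum(acme) / total_effect
               else NA_real_,
    sigma_y = params$sigma_y,
    instrument_snps = snp_id[iv_idx],
    meqtl_map = meqtl_map,
    cd4_fraction = props[, "cd4t"],
    params = params), class = "sim_truth")

  structure(list(samples = samples, beta = beta_mat, annot = annot,
                 geno = geno, external_stats = external_stats,
                 cd4_ranking = cd4_ranking, truth = truth),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(paste0("meth_cohort: %d samples, %d CpGs, %d SNPs; ",
                     "%d true mediator CpGs\n"),
              nrow(x$samples), nrow(x$beta), nrow(x$geno$dosages),
              nrow(x$truth$mediators)))
  cat(sprintf("  groups: %s\n",
              paste(names(table(x$samples$exposure_group)),
                    table(x$samples$exposure_group), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: alpha0=%.4g, total effect=%.4g, joint PM=%.3f\n",
              x$alpha0, x$total_effect, x$pm_joint))
  cat(sprintf("  %d mediators, per-site ACME %.4g to %.4g\n",
              nrow(x$mediators), min(x$mediators$acme), max(x$mediators$acme)))
  invisible(x)
}

#' Closed-form residual correlation induced by a shared latent confounder
#'
#' A latent U ~ N(0,1) entering the mediator model with coefficient
#' `gamma_m` (on top of residual SD `sigma_m`) and the outcome model with
#' coefficient `gamma_y` (on top of residual SD `sigma_y`) induces error
#' correlation gamma_m * gamma_y / sqrt((gamma_m^2 + sigma_m^2) *
#' (gamma_y^2 + sigma_y^2)).
#'
#' @param gamma_m,gamma_y confounder loadings on mediator and outcome.
#' @param sigma_m,sigma_y residual SDs without the confounder.
#' @return the induced correlation rho*.
#' @export
induced_residual_cor <- function(gamma_m, gamma_y, sigma_m, sigma_y) {
  (gamma_m * gamma_y) /
    sqrt((gamma_m^2 + sigma_m^2) * (gamma_y^2 + sigma_y^2))
}

#' Inject an unmeasured mediator-outcome confounder
#'
#' Adds a latent standard-normal confounder U to one mediator CpG (on the
#' beta-value scale, coefficient `gamma_m`) and to the outcome
#' (`vacs_avg_after`, coefficient `gamma_y`), violating sequential
#' ignorability by a known amount: the induced residual correlation between
#' the mediator- and outcome-model errors is computed analytically from the
#' generator's noise scales (see [induced_residual_cor()]) and attached as
#' attribute `rho_star`.
#'
#' @param cohort a `meth_cohort`.
#' @param cpg mediator CpG to confound (default: first true mediator).
#' @param gamma_m,gamma_y confounder loadings (beta-value and outcome scale).
#' @return modified `meth_cohort` with attribute `rho_star`.
#' @export
inject_unmeasured_confounder <- function(cohort, gamma_m, gamma_y,
                                         cpg = cohort$truth$mediators$cpg[1]) {
  stopifnot(inherits(cohort, "meth_cohort"))
  j <- match(cpg, rownames(cohort$beta))
  if (is.na(j)) stop("cpg not found in beta matrix: ", cpg, call. = FALSE)
  n <- ncol(cohort$beta)
  u <- stats::rnorm(n)
  cohort$beta[j, ] <- pmin(pmax(cohort$beta[j, ] + gamma_m * u, 1e-8),
                           1 - 1e-8)
  cohort$samples$vacs_avg_after <- cohort$samples$vacs_avg_after + gamma_y * u
  jm <- match(cpg, cohort$truth$mediators$cpg)
  s_m <- if (!is.na(jm)) cohort$truth$mediators$resid_sd_beta[jm] else
    stats::sd(cohort$beta[j, ])
  attr(cohort, "rho_star") <- induced_residual_cor(gamma_m, gamma_y, s_m,
                                                   cohort$truth$sigma_y)
  cohort
}

#' Write a cohort's standard fixture files
#'
#' Emits the TSV/VCF files consumed by the readers in this package:
#' `samples.tsv`, `beta.tsv`, `annotation.tsv`, `genotypes.vcf`,
#' `external_stats.tsv`, `cd4_ranking.tsv` and `sim_truth.tsv` (one row per
#' true mediator).
#'
#' @param cohort a `meth_cohort`.
#' @param dir output directory (created if needed).
#' @param config optional [run_config()] recorded in TSV headers.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"), config)
  write_beta_matrix(cohort$beta, file.path(dir, "beta.tsv"), config)
  write_cpg_annotation(cohort$annot, file.path(dir, "annotation.tsv"), config)
  write_genotypes_vcf(cohort$geno, file.path(dir, "genotypes.vcf"))
  write_external_stats(cohort$external_stats,
                       file.path(dir, "external_stats.tsv"), config)
  write_tsv(cohort$cd4_ranking, file.path(dir, "cd4_ranking.tsv"), config)
  write_tsv(cohort$truth$mediators, file.path(dir, "sim_truth.tsv"), config)
  invisible(dir)
}
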