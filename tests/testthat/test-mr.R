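# Two-step MR machinery: IVW estimator, LD pruning, SNP association scans,
# cis-meQTL instruments, and the end-to-end validation runs.

test_that("IVW reduces to the Wald ratio and matches the weighted
           zero-intercept regression oracle", {
  f1 <- ivw(bx = 0.2, by = 0.05, se_by = 0.01)
  expect_equal(f1$estimate, 0.05 / 0.2, tolerance = 1e-12)
  expect_identical(f1$n_instruments, 1L)

  set.seed(3)
  for (r in 1:50) {
    k <- sample(2:12, 1)
    bx <- rnorm(k, 0.1, 0.05)
    by <- rnorm(k, 0.02, 0.05)
    se <- runif(k, 0.005, 0.05)
    f <- ivw(bx, by, se)
    wls <- lm(by ~ 0 + bx, weights = 1 / se^2)
    expect_equal(f$estimate, unname(coef(wls)["bx"]), tolerance = 1e-10)
    # sign-flip invariance per instrument
    flip <- rbinom(k, 1, 0.5) * (-2) + 1
    f2 <- ivw(bx * flip, by * flip, se)
    expect_equal(f2$estimate, f$estimate, tolerance = 1e-12)
    expect_equal(f2$se, f$se, tolerance = 1e-12)
    # CI/p definitional identities
    expect_equal(f$ci, f$estimate + c(-1.96, 1.96) * f$se, tolerance = 1e-12)
    expect_equal(f$p, 2 * pnorm(-abs(f$estimate / f$se)), tolerance = 1e-12)
  }
  expect_error(ivw(c(0, 0), c(0.1, 0.2), c(0.1, 0.1)), "identification")
  expect_error(ivw(0.1, 0.1, 0), "positive")
})

test_that("LD pruning keeps the best-ranked of correlated SNPs and verifies
           the greedy-maximality property", {
  set.seed(5)
  n <- 150
  base <- matrix(rbinom(20 * n, 2, 0.3), 20, n,
                 dimnames = list(sprintf("s%02d", 1:20), NULL))
  # duplicated SNP: only the better-ranked survives
  dup <- base[1:2, ]
  dup[2, ] <- dup[1, ]
  colnames(dup) <- sprintf("i%03d", seq_len(n))
  pr <- ld_prune(dup, c(s01 = 0.01, s02 = 0.001), r2_cut = 0.1)
  expect_identical(pr, "s02")

  # independent SNPs all survive
  colnames(base) <- sprintf("i%03d", seq_len(n))
  rk <- setNames(runif(20), rownames(base))
  kept <- ld_prune(base, rk, r2_cut = 0.999)
  expect_identical(sort(kept), sort(rownames(base)))

  # randomized 20-SNP instances with planted correlation blocks: the result
  # must satisfy the greedy-prefix property checked by an independent oracle
  for (rep in 1:10) {
    set.seed(100 + rep)
    blocks <- matrix(rnorm(5 * n), 5, n)
    dos <- matrix(0, 20, n, dimnames = list(sprintf("s%02d", 1:20), NULL))
    for (i in 1:20) {
      dos[i, ] <- blocks[sample(5, 1), ] * runif(1, 0.5, 1) +
        rnorm(n, 0, runif(1, 0.2, 1.5))
    }
    rk <- setNames(runif(20), rownames(dos))
    kept <- ld_prune(dos, rk, r2_cut = 0.1)
    # all pairwise r2 below threshold
    if (length(kept) > 1) {
      cc <- cor(t(dos[kept, ]))^2
      expect_lt(max(cc[upper.tri(cc)]), 0.1)
    }
    # every dropped SNP is blocked by a better-ranked kept SNP
    dropped <- setdiff(rownames(dos), kept)
    for (d in dropped) {
      better <- kept[rk[kept] < rk[d]]
      expect_true(any(cor(dos[d, ], t(dos[better, , drop = FALSE]))^2 >= 0.1))
    }
    # and the order is independently reproducible by a brute-force greedy
    oracle <- character(0)
    for (s in names(sort(rk))) {
      if (length(oracle) == 0 ||
          all(cor(dos[s, ], t(dos[oracle, , drop = FALSE]))^2 < 0.1)) {
        oracle <- c(oracle, s)
      }
    }
    expect_identical(kept, oracle)
  }
})

test_that("per-SNP association scan recovers effects and matches the lm
           oracle", {
  co <- shared_cohort()
  s <- as.data.frame(co$samples)
  g <- co$geno$dosages[5, match(s$sample_id, colnames(co$geno$dosages))]
  s$toy <- 0.5 * g + rnorm(nrow(s), 0, 1e-6)
  tab <- snp_assoc(co$geno, validate_sample_table(s), "toy",
                   covariates = c("age", "sex"),
                   snps = co$geno$info$snp_id[5])
  expect_equal(tab$beta, 0.5, tolerance = 1e-4)

  tab2 <- snp_assoc(co$geno, co$samples, "vacs_avg_after",
                    snps = co$geno$info$snp_id[1:5])
  for (i in 1:5) {
    s$g <- co$geno$dosages[i, match(s$sample_id,
                                    colnames(co$geno$dosages))]
    o <- summary(lm(vacs_avg_after ~ g + age + sex + race + apc1 + apc2 +
                      apc3 + apc4 + apc5, data = s))$coefficients
    expect_equal(tab2$beta[i], o["g", "Estimate"], tolerance = 1e-10)
    expect_equal(tab2$p[i], o["g", "Pr(>|t|)"], tolerance = 1e-10)
  }

  # monomorphic SNP flagged
  geno2 <- co$geno
  geno2$dosages[1, ] <- 2
  tab3 <- snp_assoc(geno2, co$samples, "vacs_avg_after",
                    snps = geno2$info$snp_id[1])
  expect_identical(tab3$flag, "monomorphic")

  # null calibration: p-values uniform under no association
  set.seed(12)
  nn <- 400
  dosn <- matrix(rbinom(600 * nn, 2, 0.3), 600, nn,
                 dimnames = list(sprintf("n%03d", 1:600),
                                 co$samples$sample_id[1:nn]))
  genon <- structure(list(dosages = dosn,
                          info = data.frame(snp_id = rownames(dosn),
                                            chr = "1", pos = 1:600,
                                            ref = "A", alt = "B",
                                            maf = 0.3)),
                     class = "genotype_matrix")
  tabn <- snp_assoc(genon, co$samples[1:nn, ], "vacs_avg_after",
                    covariates = c("age", "sex"))
  ks <- suppressWarnings(ks.test(tabn$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cis-meQTL scan respects the closed 1 Mb window and recovers
           planted meQTLs", {
  co <- shared_cohort()
  # construct a genotype set with SNPs at exact boundary distances
  s <- co$samples
  set.seed(31)
  dos <- matrix(rbinom(3 * nrow(s), 2, 0.4), 3, nrow(s),
                dimnames = list(c("b_in", "b_out", "b_otherchr"),
                                s$sample_id))
  cpg1 <- co$annot[1, ]
  info <- data.frame(snp_id = rownames(dos),
                     chr = c(cpg1$chr, cpg1$chr, "21"),
                     pos = c(cpg1$pos + 1e6, cpg1$pos + 1e6 + 1, cpg1$pos),
                     ref = "A", alt = "B", maf = 0.4,
                     stringsAsFactors = FALSE)
  gb <- structure(list(dosages = dos, info = info),
                  class = "genotype_matrix")
  b <- co$beta
  # make the boundary SNPs true meQTLs so only the window rule decides
  for (snp in rownames(dos)) {
    b[1, ] <- plogis(qlogis(b[1, ]) + 0.3 * dos[snp, ])
  }
  iv <- cis_meqtl_scan(gb, b, co$annot, s, co$annot$cpg[1], p_cut = 0.5,
                       r2_cut = 0.999)
  expect_true("b_in" %in% iv$snp)          # exactly 1 Mb: included
  expect_false("b_out" %in% iv$snp)        # 1 bp beyond: excluded
  expect_false("b_otherchr" %in% iv$snp)   # other chromosome: excluded

  # planted-meQTL recall at effect 0.05 beta-units/allele, n = 2000
  p <- sim_params(n_samples = 2000, n_cpgs = 30, n_true_mediators = 2,
                  n_meqtl_cpgs = 10, meqtl_effect = 0.05, seed = 71)
  co2 <- simulate_cohort(p)
  mm <- co2$truth$meqtl_map
  hits <- 0
  for (cpg in unique(mm$cpg)) {
    iv2 <- cis_meqtl_scan(co2$geno, co2$beta, co2$annot, co2$samples, cpg,
                          r2_cut = 0.999)
    hits <- hits + sum(mm$snp[mm$cpg == cpg] %in% iv2$snp)
  }
  expect_gte(hits / nrow(mm), 0.9)

  expect_error(cis_meqtl_scan(co$geno, co$beta, co$annot, co$samples,
                              "cg_missing"), "not found")
})

test_that("two-step MR validates a planted causal chain and stays null
           without genetic control", {
  p <- sim_params(n_samples = 5000, n_cpgs = 30, n_true_mediators = 2,
                  pathway_sd = 0, alpha1 = -0.8, beta0 = -0.35,
                  meqtl_effect = 0.08, instrument_effect = 0.18, seed = 81)
  co <- simulate_cohort(p)
  mr <- run_two_step_mr(co, co$truth$mediators$cpg)
  row <- mr$table[1, ]
  expect_lt(row$step1_p, 0.05)
  expect_lt(row$step2_p, 0.05)
  expect_true(row$concordant)
  # causal directions: exposure lowers methylation; methylation lowers
  # severity is a negative mediator effect
  expect_lt(row$step1_estimate, 0)
  expect_lt(row$step2_estimate, 0)

  # no genetic control of the exposure: step-1 CI covers 0
  p0 <- sim_params(n_samples = 2000, n_cpgs = 10, n_true_mediators = 1,
                   pathway_sd = 0, instrument_effect = 0, seed = 82)
  co0 <- simulate_cohort(p0)
  # external stats still claim instrument strength, so they pass the filter
  co0$external_stats$beta <- 0.15
  co0$external_stats$p <- 1e-8
  mr0 <- run_two_step_mr(co0, co0$truth$mediators$cpg[1])
  expect_true(mr0$table$step1_ci_lo[1] <= 0 &&
                mr0$table$step1_ci_hi[1] >= 0)
})

test_that("the both-steps intersection rule reproduces a constructed
           3-of-15 concordance", {
  p1 <- c(0.003, 0.013, 0.037, 0.048, 0.066, 0.135, 0.196, 0.220, 0.262,
          0.269, 0.284, 0.488, 0.650, 0.758, 0.841)
  p2 <- c(3.4e-06, 9.4e-03, 2.8e-04, 0.528, 3.8e-03, 3.9e-06, 0.062,
          1.5e-02, 1.4e-03, 0.615, 0.771, 0.056, 0.056, 0.234, 0.570)
  concordant <- p1 < 0.05 & p2 < 0.05
  expect_identical(sum(concordant), 3L)
})

test_that("cell-proportion MR: positive control detected, missing columns
           fatal", {
  p <- sim_params(n_samples = 2000, n_cpgs = 10, n_true_mediators = 1,
                  cellprop_exposure_effect = 0.08, seed = 91)
  co <- simulate_cohort(p)
  tab <- mr_cell_proportions(co)
  expect_lt(tab$p[tab$cell_type == "gran"], 0.05)
  expect_identical(nrow(tab), 6L)

  co$samples$gran <- NULL
  expect_error(mr_cell_proportions(co), "gran")
})
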