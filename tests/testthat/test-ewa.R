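# EWA scans, inflation diagnostics, CD4 PCs, candidate selection, and the
# other-substance confound check.

test_that("EWA matches a looped per-CpG regression oracle exactly", {
  co <- shared_cohort()
  sub <- co$beta[1:40, ]
  scan <- run_ewa(sub, co$samples, "vacs_at_draw",
                  covariates = c("sex", "age", "race", "smoking", "wbc"))
  s <- as.data.frame(co$samples)
  for (i in c(1, 7, 25, 40)) {
    s$m <- sub[i, match(s$sample_id, colnames(sub))]
    lmfit <- summary(lm(m ~ vacs_at_draw + sex + age + race + smoking + wbc,
                        data = s))$coefficients
    expect_equal(scan$table$effect[i], lmfit["vacs_at_draw", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(scan$table$se[i], lmfit["vacs_at_draw", "Std. Error"],
                 tolerance = 1e-10)
    expect_equal(scan$table$p[i], lmfit["vacs_at_draw", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("a planted mediator attains the minimum p in the exposure scan", {
  co <- simulate_cohort(sim_params(n_samples = 2000, n_cpgs = 200,
                                   n_true_mediators = 1, pathway_sd = 0,
                                   beta0 = -0.3, seed = 13))
  scan <- run_ewa(co$beta, co$samples, "exposure_persistent")
  expect_identical(scan$table$cpg[which.min(scan$table$p)],
                   co$truth$mediators$cpg[1])
})

test_that("constant CpGs are flagged, not fatal", {
  co <- simulate_cohort(sim_params(n_samples = 100, n_cpgs = 10, seed = 14))
  b <- co$beta
  b[3, ] <- 0.42
  scan <- run_ewa(b, co$samples, "vacs_at_draw")
  expect_identical(scan$table$flag[3], "constant")
  expect_equal(scan$table$p[3], 1)
  expect_equal(scan$table$effect[3], 0)
})

test_that("genomic inflation factor is definitional and calibrated", {
  expect_equal(genomic_inflation(rep(0.5, 100)), 1.0, tolerance = 1e-12)
  # all chi-square statistics equal to 1
  p1 <- pchisq(1, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(rep(p1, 10)), 1 / qchisq(0.5, 1),
               tolerance = 1e-6)
  expect_equal(genomic_inflation(rep(p1, 10)), 2.198, tolerance = 1e-3)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "\\(0,1\\]")
  set.seed(8)
  lam <- genomic_inflation(runif(10000))
  expect_gt(lam, 0.95)
  expect_lt(lam, 1.05)
})

test_that("exposure-scan lambda on null methylation is near 1", {
  p <- sim_params(n_samples = 250, n_cpgs = 20000, n_true_mediators = 0,
                  pathway_sd = 0, n_meqtl_cpgs = 0, seed = 15)
  co <- simulate_cohort(p)
  scan <- run_ewa(co$beta, co$samples, "exposure_persistent")
  expect_gt(scan$lambda, 0.9)
  expect_lt(scan$lambda, 1.1)
})

test_that("CD4 PC covariates: rank-1 case, orthogonality, and recovery of
           the simulated CD4 fraction", {
  # rank-1 submatrix -> PC1 carries 100% of the variance
  n <- 30
  set.seed(2)
  v <- runif(n)
  m <- outer(seq(0.001, 0.01, length.out = 1005), v)   # rank 1
  rownames(m) <- sprintf("cg%04d", 1:1005)
  colnames(m) <- sprintf("s%03d", 1:n)
  rk <- data.frame(cpg = rownames(m), score = 1005:1)
  pcs <- cd4_pc_covariates(m, rk)
  expect_equal(attr(pcs, "var_fraction")[1], 1.0, tolerance = 1e-8)

  co <- shared_cohort()
  pcs2 <- suppressWarnings(cd4_pc_covariates(co$beta, co$cd4_ranking,
                                             n_top = 1000))
  expect_lt(abs(sum(pcs2[, 1] * pcs2[, 2])), 1e-8)
  vf <- attr(pcs2, "var_fraction")
  expect_true(vf[1] >= vf[2])
  expect_gt(abs(cor(pcs2[, 1], co$truth$cd4_fraction)), 0.9)

  expect_error(cd4_pc_covariates(co$beta[1:50, ], co$cd4_ranking), "1000")
})

test_that("candidate selection: strict dual threshold plus forced include", {
  cpgs <- sprintf("cg%02d", 1:10)
  p1 <- c(1e-5, 1e-4, 0.5, 1e-6, 0.2, 0.001, 1e-4, 0.9, 0.3, 0.04)
  p2 <- c(1e-4, 2e-4, 1e-6, 0.5, 0.1, 1e-5, 5e-4, 0.8, 0.2, 0.03)
  cs <- select_candidates(fake_ewa(cpgs, p1), fake_ewa(cpgs, p2),
                          p_cut = 0.001)
  expect_setequal(cs$cpg, c("cg01", "cg02", "cg07"))
  # p exactly at the cut is excluded (cg06 exposure p = 0.001)
  expect_false("cg06" %in% cs$cpg)
  # symmetric in the scans
  cs_swap <- select_candidates(fake_ewa(cpgs, p2), fake_ewa(cpgs, p1),
                               p_cut = 0.001)
  expect_setequal(cs$cpg, cs_swap$cpg)
  # forced include appended with its own basis
  cs2 <- select_candidates(fake_ewa(cpgs, p1), fake_ewa(cpgs, p2),
                           p_cut = 0.001, forced = "cg10")
  expect_identical(nrow(cs2), 4L)
  expect_identical(cs2$basis[cs2$cpg == "cg10"], "forced_include")
  expect_error(select_candidates(fake_ewa(cpgs, p1), fake_ewa(cpgs, p2),
                                 forced = "cg99"), "cg99")

  # a 14-member dual-threshold intersection plus one forced CpG gives 15
  m <- 40
  ids <- sprintf("cg%03d", 1:m)
  q1 <- q2 <- rep(0.5, m)
  q1[1:14] <- 1e-5; q2[1:14] <- 1e-4
  q1[15] <- 1e-7; q2[15] <- 0.0017    # strong in one scan only
  cs3 <- select_candidates(fake_ewa(ids, q1), fake_ewa(ids, q2),
                           p_cut = 0.001, forced = ids[15])
  expect_identical(nrow(cs3), 15L)
  expect_identical(sum(cs3$basis == "both_thresholds"), 14L)
})

test_that("substance confound check flags planted confounds at ~5% null
           rate", {
  co <- shared_cohort()
  cand <- rownames(co$beta)[101:160]
  tab <- substance_confound_check(co$beta, co$samples, cand)
  # substances are generated independently of methylation
  expect_lt(mean(tab$flagged), 0.12)
  expect_identical(nrow(tab), length(cand) * 3L)

  # a CpG constructed to track alcohol use is flagged
  b <- co$beta
  s <- as.data.frame(co$samples)
  b[1, ] <- plogis(-0.5 + 0.3 * s$alcohol_auditc[
    match(colnames(b), s$sample_id)])
  tab2 <- substance_confound_check(b, co$samples, rownames(b)[1])
  expect_true(tab2$flagged[tab2$substance == "alcohol_auditc"])

  empty <- substance_confound_check(co$beta, co$samples, character(0))
  expect_identical(nrow(empty), 0L)
})
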