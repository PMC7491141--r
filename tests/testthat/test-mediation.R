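# Mediation engine: product estimator, bootstrap inference, decomposition
# identities, joint mediation, and the rho-sensitivity analysis.

test_that("point ACME equals the product of the two separate regression
           oracles", {
  co <- shared_cohort()
  cpg <- co$truth$mediators$cpg[2]
  mf <- fit_mediation(co$samples, co$beta, cpg, B = 50, seed = 1)

  s <- as.data.frame(co$samples)
  s <- s[s$exposure_group %in% c("none", "persistent"), ]
  s$x <- as.numeric(s$exposure_group == "persistent")
  s$m <- co$beta[cpg, match(s$sample_id, colnames(co$beta))]
  fml_c <- "sex + age + race + smoking + adherence + wbc + cd8t + gran +
            nk + bcell + mono"
  med <- lm(as.formula(paste("m ~ x +", fml_c)), data = s)
  out <- lm(as.formula(paste("vacs_avg_after ~ x + m +", fml_c)), data = s)
  expect_equal(mf$beta0, unname(coef(med)["x"]), tolerance = 1e-12)
  expect_equal(mf$alpha1, unname(coef(out)["m"]), tolerance = 1e-12)
  expect_equal(mf$acme, unname(coef(out)["m"] * coef(med)["x"]),
               tolerance = 1e-12)
  expect_equal(mf$ade, unname(coef(out)["x"]), tolerance = 1e-12)
})

test_that("decomposition identities hold exactly for every fit", {
  co <- shared_cohort()
  for (cpg in co$truth$mediators$cpg[1:4]) {
    mf <- fit_mediation(co$samples, co$beta, cpg, B = 20, seed = 3)
    expect_equal(mf$te, mf$ade + mf$acme, tolerance = 1e-10)
    expect_equal(mf$pm * mf$te, mf$acme, tolerance = 1e-10)
    expect_true(mf$acme_ci[1] <= mf$acme_ci[2])
  }
  d <- derive_effect_decomposition(0.3, 0)
  expect_false(d$pm_defined)
  expect_true(is.na(d$pm))
  d2 <- derive_effect_decomposition(0, 0.7)
  expect_equal(d2$pm, 0)
  expect_equal(d2$ade, 0.7)
})

test_that("null exposure-mediator path gives a null ACME with covering CI", {
  p <- sim_params(n_samples = 1200, n_cpgs = 3, n_true_mediators = 1,
                  pathway_sd = 0, alpha1 = -1, beta0 = 0, seed = 51)
  co <- simulate_cohort(p)
  mf <- fit_mediation(co$samples, co$beta, co$truth$mediators$cpg[1],
                      B = 1000, seed = 2)
  expect_lt(abs(mf$acme), 0.05)
  expect_true(mf$acme_ci[1] <= 0 && mf$acme_ci[2] >= 0)
})

test_that("bootstrap is seed-deterministic and p/CI are consistent", {
  co <- shared_cohort()
  cpg <- co$truth$mediators$cpg[1]
  a <- fit_mediation(co$samples, co$beta, cpg, B = 400, seed = 9)
  b <- fit_mediation(co$samples, co$beta, cpg, B = 400, seed = 9)
  expect_identical(a$acme_ci, b$acme_ci)
  expect_identical(a$acme_p, b$acme_p)
  expect_identical(a$engine$draws_acme, b$engine$draws_acme)
  # consistency between the percentile CI and the two-sided bootstrap p
  excl0 <- a$acme_ci[1] > 0 || a$acme_ci[2] < 0
  expect_identical(a$acme_p < 0.05, excl0)
})

test_that("a single-CpG joint fit reduces to the single-site fit", {
  co <- shared_cohort()
  cpg <- co$truth$mediators$cpg[3]
  mf <- fit_mediation(co$samples, co$beta, cpg, B = 200, seed = 5)
  jf <- fit_joint_mediation(co$samples, co$beta, cpg, B = 200, seed = 5)
  expect_equal(jf$acme, mf$acme, tolerance = 1e-12)
  expect_equal(jf$te, mf$te, tolerance = 1e-12)
  expect_identical(jf$acme_ci, mf$acme_ci)
})

test_that("joint ACME adds for independent mediators but joint PM shrinks
           below the sum for correlated ones", {
  # independent mediators: joint ~ sum of singles
  p <- sim_params(n_samples = 2000, n_cpgs = 4, n_true_mediators = 2,
                  pathway_sd = 0, alpha1 = -0.8, beta0 = -0.3, seed = 61)
  co <- simulate_cohort(p)
  cpgs <- co$truth$mediators$cpg
  singles <- lapply(cpgs, function(cg)
    fit_mediation(co$samples, co$beta, cg, B = 200, seed = 6))
  joint <- fit_joint_mediation(co$samples, co$beta, cpgs, B = 200, seed = 6)
  sum_singles <- sum(vapply(singles, function(f) f$acme, numeric(1)))
  expect_lt(abs(joint$acme - sum_singles),
            3 * sd(joint$engine$draws_acme))

  # correlated mediators (shared pathway): joint PM < sum of single PMs
  p2 <- sim_params(n_samples = 2000, n_cpgs = 6, n_true_mediators = 4,
                   pathway_sd = 0.5, seed = 62)
  co2 <- simulate_cohort(p2)
  cpgs2 <- co2$truth$mediators$cpg
  singles2 <- vapply(cpgs2, function(cg)
    fit_mediation(co2$samples, co2$beta, cg, B = 50, seed = 6)$pm,
    numeric(1))
  joint2 <- fit_joint_mediation(co2$samples, co2$beta, cpgs2, B = 50,
                                seed = 6)
  expect_lt(joint2$pm, sum(singles2))
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  m <- 1:40
  th <- vapply(m, function(k) bonferroni_threshold(0.05, k), numeric(1))
  expect_true(all(diff(th) < 0))
})

test_that("rho-sensitivity: anchored at the point estimate, monotone, one
           zero crossing, correct sign convention", {
  co <- shared_cohort()
  cpgs <- co$truth$mediators$cpg[1:6]
  for (cpg in cpgs) {
    mf <- fit_mediation(co$samples, co$beta, cpg, B = 20, seed = 7)
    sc <- sensitivity_acme(mf, boot_B = 0)
    expect_equal(sc$acme0, mf$acme, tolerance = 1e-8)
    acme_at_0 <- sc$curve$acme[abs(sc$curve$rho) < 1e-9]
    expect_equal(acme_at_0, mf$acme, tolerance = 1e-8)
    # monotone in rho, hence exactly one sign change over the grid
    expect_true(all(diff(sc$curve$acme) < 0) || all(diff(sc$curve$acme) > 0))
    expect_identical(sum(abs(diff(sign(sc$curve$acme))) > 0), 1L)
    # under this parameterization a positive ACME driven by two negative
    # paths crosses zero at negative rho
    expect_identical(sign(sc$rho_zero) * sign(mf$acme), -1)
    # the crossing is at the residual correlation, inside the grid
    expect_lt(abs(sc$rho_zero), 0.95)
  }
  mf <- fit_mediation(co$samples, co$beta, cpgs[1], B = 20, seed = 7)
  expect_error(sensitivity_acme(mf, rho_grid = c(-1, 0, 0.5)), "rho")
})

test_that("rho-sensitivity bands are seed-deterministic", {
  co <- shared_cohort()
  mf <- fit_mediation(co$samples, co$beta, co$truth$mediators$cpg[1],
                      B = 20, seed = 7)
  s1 <- sensitivity_acme(mf, boot_B = 50, seed = 4)
  s2 <- sensitivity_acme(mf, boot_B = 50, seed = 4)
  expect_identical(s1$curve, s2$curve)
  expect_true(all(s1$curve$lo <= s1$curve$acme + 1e-12))
  expect_true(all(s1$curve$hi >= s1$curve$acme - 1e-12))
})

test_that("degenerate inputs are rejected or flagged", {
  co <- shared_cohort()
  few <- co$samples[c(which(co$samples$exposure_group == "persistent")[1:5],
                      which(co$samples$exposure_group == "none")[1:30]), ]
  expect_error(fit_mediation(few, co$beta, co$truth$mediators$cpg[1],
                             B = 10, seed = 1), "each exposure group")
  expect_error(fit_mediation(co$samples, co$beta, "cg_not_there",
                             B = 10, seed = 1), "not in beta")
})
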