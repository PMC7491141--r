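# methmediate

Does DNA methylation in blood *mediate* the effect of a substance-use
exposure on HIV disease severity? `methmediate` implements the complete
analysis chain for that question, for epidemiologists and epigeneticists
working with cohort phenotype tables, methylation beta matrices and
genotype dosages:

1. **Cohort outcome models** — linear association of the severity index
   with ordinal exposure frequency, Cox proportional hazards for
   mortality, and a log-rank trend test across frequency groups.
2. **Dual epigenome-wide association (EWA) scans** — per-CpG OLS of
   methylation on the exposure and on the severity index, with cell-type,
   technical and CD4-specific principal-component adjustment, genomic
   inflation factor λ, strict dual-threshold candidate selection
   (p < 0.001 in both scans), and an other-substance confound screen.
3. **Causal mediation** — in the linear structural-equation setting with
   mediator model *M* = β₀*X* + ΣβᵢCᵢ and outcome model
   *Y* = α₀*X* + α₁*M* + Σαᵢ₊₁Cᵢ, the average causal mediation effect is
   ACME = α₁β₀, the total effect TE = α₀ + α₁β₀, and the proportion
   mediated PM = ACME/TE (joint version over multiple CpGs:
   Σⱼαⱼβ₀ⱼ). Inference is a whole-sample nonparametric bootstrap with
   percentile intervals; the ρ-sensitivity analysis expresses ACME as a
   closed-form function of the correlation ρ between the two models'
   errors and reports the ρ at which ACME = 0.
4. **Two-step epigenetic Mendelian randomization** — inverse-variance
   weighted (IVW) estimation of exposure→CpG effects with external GWAS
   instruments (step 1) and CpG→outcome effects with cis-meQTL
   instruments inside a closed 1 Mb window (step 2), with greedy LD
   pruning at r² < 0.1 and a cell-type-proportion negative control.

A synthetic-cohort generator (`simulate_cohort`) reproduces the
exposure→methylation→outcome structure with known ground truth —
cell-mixture and meQTL structure in the beta values, a shared mediator
pathway factor, weak genetic instruments on the exposure liability, and
exposure-dependent survival — and drives the package's recovery and
calibration tests.

## Worked example

```r
library(methmediate)

co <- simulate_cohort(sim_params(n_samples = 875, seed = 1))
co
#> meth_cohort: 875 samples, 2000 CpGs, 120 SNPs; 12 true mediator CpGs
#>   groups: none=202, inconsistent=407, persistent=266

cx <- fit_cox(co$samples, c("exposure_freq", "sex", "age", "race",
                            "adherence"))
cx$terms[1, c("term", "hr", "ci_lo", "ci_hi", "p")]
#>            term       hr    ci_lo    ci_hi         p
#> 1 exposure_freq 1.110173 1.014742 1.214579 0.0226601

mf <- fit_mediation(co$samples, co$beta, "cg0000001", B = 2000, seed = 1)
mf
#> Causal mediation fit for cg0000001 (n = 468, B = 2000)
#>   ACME 0.024  [0.004, 0.051]  p = 0.014
#>   PM   8.8%  [1.3%, 21.1%]  p = 0.014
#>   ADE  0.248   TE 0.272

sensitivity_acme(mf, boot_B = 0)
#> rho-sensitivity of ACME for cg0000001
#>   ACME(0) = 0.02394; rho at which ACME = 0: -0.111 (grid: -0.10)
```

Reading the output: each unit of exposure frequency raises the mortality
hazard by ~11% (HR 1.11); methylation at the planted mediator CpG carries
a positive ACME of 0.024 severity units — about 8.8% of the 0.272 total
effect of persistent exposure in this replicate — with a bootstrap CI
excluding zero; and the mediation claim would be explained away only if
the mediator- and outcome-model errors were correlated at ρ ≈ −0.11, the
sensitivity analysis's measure of robustness. The candidate-selection and
MR stages are driven the same way; see the methods vignette
(`vignettes/methylation-mediation.Rmd`) for the full pipeline and every
modelling assumption.

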