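---
title: "Methylation-mediated exposure effects: models, assumptions and design choices"
author: "methmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation-mediated exposure effects: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmediate)
```

## The scientific question

Persistent stimulant use worsens outcomes in chronic HIV infection, and one
candidate mechanism is epigenetic: long-term exposure may leave
DNA-methylation marks in blood immune cells that in turn shift the course of
disease. `methmediate` implements the full analysis chain for asking that
question quantitatively: does methylation at specific CpG sites *mediate*
the effect of a binary persistent-exposure contrast $X$ on a continuous
severity index $Y$, and does genetic evidence support the implied causal
directions?

## Models

### Cohort-level exposure-outcome models

Before any methylation is touched, the exposure-outcome association is
established on the cohort: an OLS model of the severity index on ordinal
exposure frequency (0-5) plus confounders (`fit_linear_association`), a Cox
proportional-hazards model of mortality on the same terms (`fit_cox`, Efron
tie handling), and a log-rank test for trend across the ordered frequency
groups (`km_trend_test`, scores = the questionnaire codes 0-5, statistic
$(s'(O-E))^2 / (s'Vs)$ on 1 df).

### Candidate selection by dual EWA

Two epigenome-wide scans regress methylation (beta values, the dependent
variable) on a phenotype plus adjustment covariates: once on the binary
persistent-vs-none exposure, once on the severity index. The adjustment set
is sex, age, race, smoking, medication adherence, white-blood-cell count,
five of the six estimated cell-type proportions (CD4 is the complement and
is omitted), and negative-control principal components (default 5, included
in **both** scans; the count is configurable). Because the severity index
contains the CD4 count as a component, the severity scan additionally
adjusts for the top 2 principal components of the 1000 most CD4-relevant
CpGs (`cd4_pc_covariates`); the CD4-relevance ranking is an input, which
the synthetic generator supplies from its own cell-mixture loadings.
Candidates are CpGs with $p < 0.001$ (strict inequality; ties at the
threshold are excluded) in *both* scans, with a `forced_include` mechanism
for biologically motivated additions. Scan calibration is summarized by the
genomic inflation factor $\lambda$ = median association $\chi^2$ /
$\chi^2_{1,0.5}$ (= 0.4549364). A confound screen then re-fits each
candidate against alcohol, cannabis and opioid use with the same
covariates.

### Single-site and joint mediation

In the linear structural-equation setting, with confounders $C_i$:

$$M = \beta_0 X + \textstyle\sum_i \beta_i C_i + \varepsilon_2, \qquad
  Y = \alpha_0 X + \alpha_1 M + \textstyle\sum_i \alpha_{i+1} C_i
  + \varepsilon_3.$$

The average causal mediation effect is $\mathrm{ACME} = \alpha_1\beta_0$,
the average direct effect $\alpha_0$, the total effect $\alpha_0 +
\alpha_1\beta_0$, and the proportion mediated their ratio. With several
mediators the outcome model carries all of them jointly and the joint ACME
is $\sum_j \alpha_j \beta_{0j}$. The decomposition identities
$\mathrm{TE} = \mathrm{ADE} + \mathrm{ACME}$ and
$\mathrm{PM}\cdot\mathrm{TE} = \mathrm{ACME}$ hold *exactly* for every fit
(tested to 1e-10); PM is reported unclipped and flagged undefined when
$|\mathrm{TE}| < 10^{-12}$.

Inference is a nonparametric bootstrap resampling whole samples:
percentile 95% intervals, and a two-sided p-value
$p = \max(1/B,\; 2\min(\hat F(0), 1-\hat F(0^-)))$. The percentile method
was chosen over BCa for transparency and testability; the default
$B = 10{,}000$ is configurable (all fits are deterministic given a seed).
The outcome is the *average severity index after* methylation profiling,
so the mediator measurement precedes the outcome measurement; mediation
always uses the persistent-vs-none contrast with inconsistent reporters
excluded, and requires at least 10 samples per exposure arm.

### Sensitivity to sequential ignorability

ACME identification needs sequential ignorability; its violation is indexed
by $\rho = \mathrm{corr}(\varepsilon_2, \varepsilon_3)$. In the linear case
there is a closed form: with $s_1, s_2$ the residual SDs of $Y \sim X + C$
(no mediator) and $M \sim X + C$, and $r$ the correlation of those two
residual vectors,

$$\mathrm{ACME}(\rho) = \beta_0\frac{s_1}{s_2}
  \left(r - \rho\sqrt{\frac{1-r^2}{1-\rho^2}}\right),$$

which is monotone in $\rho$, equals the point estimate at $\rho = 0$, and
crosses zero exactly once, at $\rho_0 = r$. `sensitivity_acme` evaluates
this on a grid of 0.05 over $(-0.95, 0.95)$, reports the analytic root
(and its grid rounding), and attaches pointwise bootstrap bands. Under
this parameterization a positive ACME produced by two negative paths
yields a *negative* $\rho_0$: the residual correlation inherits the sign
of the fitted mediator-outcome slope. A mediation result whose $|\rho_0|$
is small is fragile — a weak unmeasured mediator-outcome confounder could
explain it away entirely. `inject_unmeasured_confounder` closes the loop:
it adds a latent confounder with known loadings, computes the induced
$\rho^\* = \gamma_m\gamma_y / \sqrt{(\gamma_m^2+s_m^2)(\gamma_y^2+s_y^2)}$
analytically, and the sensitivity analysis is expected to locate its root
there (tested at $\rho^\* = 0.5$, recovered within $\pm 0.1$ at
$n = 5000$). Note the root equals the *confounding* correlation only when
the true mediated path is null; with real mediation the root combines both
sources, which is precisely the analysis's point.

### Two-step epigenetic Mendelian randomization

Step 1 asks whether the exposure causally shifts candidate CpGs: external
exposure-GWAS instruments (summary statistics with $p < 10^{-5}$, allele
harmonized to the cohort's ALT dosage, LD-pruned at $r^2 < 0.1$) supply
$b_x$, in-sample SNP→CpG regressions (adjusted for age, sex, race, 5
ancestry PCs) supply $b_y$. Step 2 asks whether CpGs shift the outcome:
cis-meQTLs within a closed 1 Mb window on the same chromosome with
$p < 0.01$ after pruning are instruments; SNP→CpG fits give $b_x$ and
SNP→outcome fits give $b_y$ (the step-2 outcome model adjusts for age, sex
and ancestry PCs; race can be added with a flag). Both steps use
fixed-effect inverse-variance-weighted estimation with first-order weights,

$$\hat\theta = \frac{\sum b_x b_y / se_{b_y}^2}{\sum b_x^2 / se_{b_y}^2},
\qquad SE = \Big(\sum b_x^2/se_{b_y}^2\Big)^{-1/2},$$

equivalent to the $1/se^2$-weighted zero-intercept regression of $b_y$ on
$b_x$, and reducing to the Wald ratio with one instrument. A CpG is
*concordant* when both steps reach $p < 0.05$. The same step-1 machinery
applied to the six cell-type proportions is the negative control: exposure
should not shift cell composition, so apparent methylation mediation is
not a cell-mixture artifact. LD pruning is greedy (ascending p; keep a SNP
iff $r^2$ with every kept SNP is below threshold) and computed from the
cohort's own dosages — the synthetic setting has no external reference
panel, a stated deviation from pruning against a population reference.
Step-1 estimates are per unit of the external GWAS liability scale; no
rescaling to the cohort's ordinal frequency is attempted.

## The synthetic cohort generator

`simulate_cohort` emulates the study conditions end to end, with known
ground truth for every recovery test:

* **Cohort structure.** Default $n = 875$; exposure liability = sum of 8
  weak instrument-SNP effects (0.15 per allele) plus standard normal noise;
  the liability rank is cut into the ordinal 0-5 frequency at the observed
  baseline proportions (38.7/37.6/8.5/7.2/2.7/5.3%) and into
  persistent (top 30.3%) / none (bottom 23.1%) / inconsistent groups, so
  both exposure codings share one construct. Covariates follow the cohort's
  marginals (age ~ N(50, 8), 97.5% male, 67% African-American, 53%
  smokers); cell proportions are Dirichlet with blood-typical means
  (granulocytes 55%, CD4 15%, ...).
* **Methylation.** Beta values arise on the logit scale: per-CpG baseline
  + cell-mixture loadings (CD4 and granulocyte) + technical components
  tied to the negative-control PCs + planted cis-meQTL dosage effects +
  exposure effect (mediator CpGs only) + a shared latent pathway factor
  across the mediators + N(0, 0.35) noise, then the logistic map. Because
  the analysis models *raw* beta values, the generator reports the induced
  beta-scale exposure effect $\beta_{0j}^\*$ by Gauss-Hermite integration
  of the logistic over the noise, averaged over the analysis samples —
  generating truth and regression estimands live on the same scale.
* **Outcome and survival.** $Y = \alpha_0 X + \sum_j \alpha_{1j} M_j +$
  confounders $+$ N(0, 0.5), produced twice with independent noise (at
  draw, for candidate selection; averaged after draw, for mediation).
  Survival is exponential with hazard $0.03\,e^{\log(1.10)\,\mathrm{freq}}$
  under independent censoring plus a 10-year administrative cut.
* **Effect scales.** The defaults (12 mediators, logit effects $-0.25$,
  outcome effects $-0.26$, pathway SD 0.3) are a calibration choice — no
  beta-unit effect size for the exposure is available to copy — set once so
  that single-site proportions mediated land in the observed 10-30% band
  while the *joint* proportion stays near half the total effect. The
  shared pathway factor is what makes single-site PMs sum to far more than
  100% while the joint PM does not: each single-site fit absorbs its
  correlated siblings' contributions. Setting `pathway_sd = 0` gives
  independent mediators, for which joint ACME equals the sum of singles
  (within bootstrap error) and single-site coverage tests are exact.

What the generator does **not** emulate: array chemistry, probe-level
bias, batch chips, realistic LD structure (SNPs are independent
Binomial(2, MAF) draws), non-exponential hazards, and informative
censoring. Passing tests therefore certify the estimators under the
generative model's assumptions — linear, additive, correctly specified
adjustment — not robustness to array artifacts or model misspecification
in real cohorts.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive; cis windows are closed intervals
  (a SNP at exactly 1 Mb is *in*).
* Thresholds are strict inequalities; a p-value exactly at a cut is out.
* Missing methylation is mean-imputed per CpG (`impute_beta_means`,
  count reported) before any scan, keeping scans total. The post-QC data
  the pipeline expects are complete; the policy is ours, stated here.
* Constant CpG columns in a scan are flagged with effect 0 and p 1, not
  fatal; monomorphic SNPs are flagged rows; genuinely collinear designs
  are fatal with the offending terms named; a factor level merely absent
  from an analysis subset is dropped from the design instead.
* Numeric TSV output is written at 17 significant digits so write/read
  round trips are bit exact; every output carries the run configuration
  (including the seed) in `#` header lines.
* The joint-mediation bootstrap is conditional on the fixed mediator set
  (selection is not re-run inside resamples), matching how the candidate
  set is used downstream.
* All Monte-Carlo machinery is seed-deterministic; one RNG stream drives
  the generator, with every draw at a fixed position in the sequence.

## Problem sizes used by the test and acceptance suites

The suites certify properties at desk scale: EWA oracle checks on a
600-sample, 1200-CpG cohort; null-scan inflation on 20,000 CpGs; bootstrap
coverage on 100 replicate cohorts of $n = 2000$ with $B = 2000$; type-I
error on 500 null replicates of $n = 300$ with $B = 1000$; sensitivity
recovery at $n = 5000$; MR recovery at $n = 5000$ with planted meQTL
effects of 0.08 beta-units/allele. These sizes were chosen to bound each
check's Monte-Carlo error well inside its asserted margin.

## Known limitations

* Strictly linear and additive models: no exposure-mediator interaction,
  no binary-outcome mediation, no penalized high-dimensional mediator
  selection.
* Fixed-effect IVW only — no Egger, weighted-median or pleiotropy
  diagnostics — so step-1/step-2 validity rests on the instruments'
  exclusion restrictions.
* The proportional-hazards assumption is reported as a Schoenfeld-residual
  diagnostic but not acted on.
* Weak instruments behave as weak instruments: at the default cohort size
  the step-1 MR is underpowered, which mirrors the motivating study's own
  marginal instrument strength and is why the mediation analysis, not the
  MR, carries the primary inference.
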