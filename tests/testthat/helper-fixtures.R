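# Shared fixtures, built in code. The default shared cohort is memoised so
# multiple test files can reuse one generation pass.

.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      sim_params(n_samples = 600, n_cpgs = 1200, seed = 42))
  }
  .fixture_env$cohort
}

# Minimal hand-built sample table (n rows) satisfying all invariants.
tiny_samples <- function(n = 6) {
  props <- matrix(rep(c(0.15, 0.10, 0.05, 0.05, 0.10, 0.55), each = n), n)
  colnames(props) <- c("cd4t", "cd8t", "nk", "bcell", "mono", "gran")
  df <- data.frame(
    sample_id = sprintf("T%03d", seq_len(n)),
    exposure_group = rep(c("persistent", "none", "inconsistent"),
                         length.out = n),
    exposure_freq = rep(0:5, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    age = seq(40, 60, length.out = n),
    race = rep(c("caucasian", "african_american", "other"), length.out = n),
    smoking = rep(0:1, length.out = n),
    adherence = rep(1, n),
    alcohol_auditc = rep(0:3, length.out = n),
    cannabis_freq = rep(0:1, length.out = n),
    opioid_freq = rep(0, n),
    wbc = seq(5, 8, length.out = n),
    props,
    ncpc1 = seq(-1, 1, length.out = n),
    vacs_at_draw = seq(20, 50, length.out = n),
    vacs_avg_after = seq(25, 55, length.out = n),
    surv_years = seq(1, 10, length.out = n),
    event = rep(0:1, length.out = n),
    stringsAsFactors = FALSE)
  validate_sample_table(df)
}

# Build an ewa_result-shaped object from bare p-values (for selection-rule
# tests that need scans with prescribed p).
fake_ewa <- function(cpgs, p, phenotype = "x") {
  structure(list(table = data.frame(cpg = cpgs, effect = 0, se = 1, t = 0,
                                    p = p, flag = "",
                                    stringsAsFactors = FALSE),
                 phenotype = phenotype, covariates = character(0),
                 n = length(cpgs), lambda = 1),
            class = "ewa_result")
}
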