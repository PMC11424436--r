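# Shared fixture builders. Everything is generated in code; no stored data.

# a harmonized set straight from effect vectors (bypasses file I/O and
# allele bookkeeping when a test only exercises the estimators)
make_set <- function(gamma, Gamma, se_gamma = rep(0.02, length(gamma)),
                     se_Gamma = rep(0.01, length(gamma)),
                     n_exposure = 4162, n_outcome = 1201909,
                     snp = sprintf("snp%03d", seq_along(gamma))) {
  df <- data.frame(
    snp = snp, chr = "1", pos = seq_along(gamma) * 1e6,
    ea = "A", oa = "G",
    gamma = gamma, se_gamma = se_gamma,
    p_gamma = 2 * pnorm(-abs(gamma / se_gamma)),
    eaf_exposure = 0.3, n_exposure = n_exposure,
    Gamma = Gamma, se_Gamma = se_Gamma,
    p_Gamma = 2 * pnorm(-abs(Gamma / se_Gamma)),
    eaf_outcome = 0.3, n_outcome = n_outcome,
    flipped = FALSE, palindromic_kept = FALSE,
    stringsAsFactors = FALSE
  )
  medmr:::.as_harmonized(df)
}

# random estimator fixture with known slope
random_set <- function(n, seed, theta = 0.2, se_gamma = 0.02,
                       se_Gamma = 0.01) {
  medmr:::.with_seed(seed, {
    gamma <- runif(n, 0.1, 0.4) * sample(c(-1, 1), n, replace = TRUE)
    Gamma <- rnorm(n, theta * gamma, se_Gamma)
    make_set(gamma, Gamma, rep(se_gamma, n), rep(se_Gamma, n))
  })
}

# a small valid summary-table data frame
toy_summary_df <- function(n = 3, seed = 1) {
  medmr:::.with_seed(seed, {
    df <- data.frame(
      snp = sprintf("rs%d", seq_len(n)), chr = "5", pos = seq_len(n) * 1000,
      ea = "A", oa = "G", eaf = runif(n, 0.1, 0.9),
      beta = rnorm(n, 0, 0.1), se = runif(n, 0.01, 0.05),
      pval = NA_real_, n = 4162L,
      stringsAsFactors = FALSE
    )
    df$pval <- 2 * pnorm(-abs(df$beta / df$se))
    df
  })
}

# harmonized instrument set from a simulated study, restricted to a role,
# without running the full cascade
study_set <- function(study, roles = "instrument") {
  set <- harmonize(study$exposure, study$outcome)
  keep <- study$truth$snp_roles[set$snp] %in% roles
  medmr:::.subset_harmonized(set, keep)
}
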