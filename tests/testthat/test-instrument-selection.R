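# fixtures here override p-values freely; silence the consistency warning
make_table <- function(df) suppressWarnings(summary_table(df, trait_id = "t"))

test_that("p-value selection uses a strict threshold", {
  df <- toy_summary_df(3)
  df$pval <- c(1e-9, 5e-8, 1e-4)
  tab <- make_table(df)
  expect_equal(nrow(select_by_pvalue(tab, 5e-8)), 1)   # boundary excluded
  expect_equal(nrow(select_by_pvalue(tab, 1e-5)), 2)
  empty <- select_by_pvalue(tab, 1e-300)
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "summary_table")
})

test_that("greedy clumping keeps the smallest-p SNP of each LD clump", {
  df <- toy_summary_df(2)
  df$pos <- c(1000, 2000)
  df$pval <- c(1e-10, 1e-8)
  ld <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2,
               dimnames = list(df$snp, df$snp))
  kept <- ld_clump(make_table(df), ld, r2_max = 0.001, window_bp = 1e7)
  expect_equal(kept$snp, "rs1")

  ld2 <- matrix(c(1, 0.01, 0.01, 1), 2, dimnames = list(df$snp, df$snp))
  expect_equal(nrow(ld_clump(make_table(df), ld2)), 2)  # r2 = 1e-4

  # 10-SNP perfect-LD block: exactly the minimum-p SNP survives
  df10 <- toy_summary_df(10, seed = 3)
  df10$pos <- seq(1000, by = 100, length.out = 10)
  ld10 <- matrix(1, 10, 10, dimnames = list(df10$snp, df10$snp))
  kept10 <- ld_clump(make_table(df10), ld10)
  expect_equal(nrow(kept10), 1)
  expect_equal(kept10$snp, df10$snp[which.min(df10$pval)])

  # SNPs outside the window are untouched even at perfect LD
  df10$pos <- seq(1e6, by = 2e7, length.out = 10)
  expect_equal(nrow(ld_clump(make_table(df10), ld10, window_bp = 1e7)), 10)
})

test_that("harmonization aligns alleles, flips swapped strands, and drops
           irreconcilable pairs", {
  e <- toy_summary_df(5)
  e$ea <- c("A", "A", "A", "C", "A")
  e$oa <- c("G", "T", "G", "A", "G")
  e$eaf <- c(0.3, 0.5, 0.3, 0.2, 0.3)
  o <- e
  o$ea <- c("G", "A", "T", "C", "A")   # swapped / palindrome / complement / same / incompatible
  o$oa <- c("A", "T", "C", "A", "C")
  o$beta <- c(0.05, 0.1, 0.07, 0.02, 0.04)
  o$eaf <- c(0.7, 0.5, 0.3, 0.2, 0.3)
  set <- harmonize(make_table(e), make_table(o))
  # palindrome dropped by default; incompatible dropped
  expect_setequal(set$snp, c("rs1", "rs3", "rs4"))
  expect_equal(set$Gamma[set$snp == "rs1"], -0.05)    # swap -> negated
  expect_true(set$flipped[set$snp == "rs1"])
  expect_equal(set$Gamma[set$snp == "rs3"], 0.07)     # strand complement only
  expect_false(set$flipped[set$snp == "rs3"])
  expect_equal(attr(set, "dropped")$reason,
               c("palindromic", "incompatible_alleles"))
})

test_that("palindromic SNPs obey the frequency-rescue rule", {
  e <- toy_summary_df(3)
  e$ea <- "A"; e$oa <- "T"
  e$eaf <- c(0.10, 0.50, 0.10)
  o <- e
  o$eaf <- c(0.10, 0.50, 0.90)
  o$beta <- c(0.2, 0.2, 0.2)
  set <- harmonize(make_table(e), make_table(o), palindrome = "rescue",
                   palindrome_eaf_band = c(0.42, 0.58))
  # same-side frequencies: kept unflipped; mid-band: dropped;
  # opposite sides: kept flipped
  expect_setequal(set$snp, c("rs1", "rs3"))
  expect_equal(set$Gamma[set$snp == "rs1"], 0.2)
  expect_false(set$flipped[set$snp == "rs1"])
  expect_equal(set$Gamma[set$snp == "rs3"], -0.2)
  expect_true(set$flipped[set$snp == "rs3"])
  # default mode drops all three
  expect_equal(nrow(harmonize(make_table(e), make_table(o))), 0)
})

test_that("harmonization is idempotent on an already-aligned pair", {
  st <- simulate_study(truth_config(n_snps = 15, c_prime = -0.1, seed = 4,
                                    swap_prob = 0))
  set1 <- harmonize(st$exposure, st$outcome)
  set2 <- harmonize(st$exposure, st$outcome)
  expect_identical(set1, set2)
  expect_false(any(set1$flipped))
})

test_that("flipping every allele and beta of the outcome leaves estimates
           unchanged (sign coherence)", {
  st <- simulate_study(truth_config(n_snps = 12, c_prime = -0.15, seed = 8))
  out <- as.data.frame(st$outcome)
  tmp <- out$ea; out$ea <- out$oa; out$oa <- tmp
  out$beta <- -out$beta
  out$eaf <- 1 - out$eaf
  flipped_tab <- summary_table(out, "outcome")
  b1 <- mr_ivw(harmonize(st$exposure, st$outcome))$beta
  b2 <- mr_ivw(harmonize(st$exposure, flipped_tab))$beta
  expect_equal(b1, b2, tolerance = 1e-15)
})

test_that("F-statistic arithmetic and the weak-instrument filter", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0.05, 0.05), 1)
  set <- make_set(gamma = c(0.3, 0.02), Gamma = c(0.06, 0.004),
                  se_gamma = c(0.02, 0.02))
  fw <- filter_weak_instruments(set, f_min = 10)
  expect_equal(fw$set$snp, "snp001")
  expect_equal(fw$excluded, "snp002")
})

test_that("weak-instrument exclusion rate matches its noncentral-chi-square
           oracle", {
  # 12 instruments, one with true F ~ 4; F_j ~ chi2_1(ncp = true F)
  gammas <- c(rep(0.2, 11), 0.048)
  cfg0 <- truth_config(n_snps = 12, n_instruments = 12, gamma = gammas,
                       maf_range = c(0.3, 0.3), c_prime = -0.1,
                       eaf_noise = FALSE, swap_prob = 0)
  se <- 1 / sqrt(cfg0$n_x * 2 * 0.3 * 0.7)
  expected_kept <- sum(pchisq(10, df = 1, ncp = (gammas / se)^2,
                              lower.tail = FALSE))
  reps <- 150
  kept <- vapply(seq_len(reps), function(r) {
    cfg <- cfg0
    cfg$seed <- 100 + r
    st <- simulate_study(cfg)
    set <- harmonize(st$exposure, st$outcome)
    nrow(filter_weak_instruments(set)$set)
  }, numeric(1))
  expect_lt(abs(mean(kept) - expected_kept), 0.25)
  expect_gt(expected_kept, 10.5)  # the one weak instrument is usually lost
})

test_that("Steiger filtering excludes variance-explained reversals only", {
  # plug-in arithmetic: strong exposure signal, weak outcome signal
  set <- make_set(gamma = c(0.24, 0.1), Gamma = c(0.0014, 0.1),
                  se_gamma = c(0.024, 0.02), se_Gamma = c(0.0014, 0.02))
  r2e <- (0.24 / 0.024)^2 / ((0.24 / 0.024)^2 + 4162 - 2)
  r2o <- 1 / (1 + 1201909 - 2)
  expect_equal(r2e, medmr:::.steiger_r2(0.24, 0.024, 4162))
  st1 <- steiger_filter(medmr:::.subset_harmonized(set, 1))
  expect_length(st1$excluded, 0)

  # exact tie is kept (strict inequality)
  tie <- make_set(gamma = 0.2, Gamma = 0.2, se_gamma = 0.02,
                  se_Gamma = 0.02, n_exposure = 5000, n_outcome = 5000)
  expect_length(steiger_filter(tie)$excluded, 0)

  # a generator-planted reverse-causal SNP is excluded
  stdy <- simulate_study(truth_config(n_snps = 12, n_rev = 1,
                                      c_prime = -0.003, seed = 21))
  set2 <- study_set(stdy, roles = c("instrument", "reverse"))
  st2 <- steiger_filter(set2)
  expect_true(stdy$truth$reverse_ids %in% st2$excluded)
})

test_that("blocklist and Bonferroni exclusions behave and report counts", {
  set <- random_set(12, seed = 31)
  expect_identical(apply_blocklist(set, character(0))$set, set)
  all_gone <- apply_blocklist(set, set$snp)
  expect_equal(nrow(all_gone$set), 0)
  expect_error(mr_ivw(all_gone$set), "empty")
  # the 12 -> 8 structure of a published selenium instrument cascade
  bl <- apply_blocklist(set, set$snp[1:4])
  expect_equal(nrow(bl$set), 8)

  # Bonferroni: planted direct-outcome SNPs fall below alpha/m
  set2 <- random_set(10, seed = 32, theta = 0)
  df <- as.data.frame(set2)
  df$p_Gamma <- 0.5
  df$p_Gamma[c(2, 5, 9)] <- 1e-6
  set2 <- medmr:::.as_harmonized(df)
  bf <- bonferroni_outcome_filter(set2, m = 1000, alpha = 0.05)
  expect_setequal(bf$excluded, df$snp[c(2, 5, 9)])
  # 1e-4 survives alpha/m = 5e-5
  df$p_Gamma[2] <- 1e-4
  expect_false(df$snp[2] %in%
                 bonferroni_outcome_filter(medmr:::.as_harmonized(df),
                                           m = 1000)$excluded)
})

test_that("the cascade is monotone and its report counts match the sets", {
  for (seed in c(3, 14, 27)) {
    st <- simulate_study(truth_config(n_snps = 30, n_instruments = 8,
                                      c_prime = -0.003, seed = seed))
    res <- select_instruments(st$exposure, st$outcome, seed = seed)
    counts <- res$report$n_snp
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[length(counts)], nrow(res$set))
  }
})
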