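test_that("product-of-coefficients arithmetic, including published rows", {
  expect_equal(mediation_effect(0.5, 0.2), 0.1)
  expect_equal(mediation_effect(0, 3.2), 0)
  # Cyclin-H row of the bundled published screen, from its printed ORs
  expect_equal(mediation_effect(log(1.068), log(0.998)),
               -1.3170723e-4, tolerance = 1e-6)

  expect_equal(mediation_ratio(0.5, 0.1, 0.2), 0.25)
  expect_error(mediation_ratio(0.5, 0.1, 0), "undefined")
  expect_equal(100 * mediation_ratio(log(1.068), log(0.998), log(0.997)),
               4.3837, tolerance = 1e-4)
  expect_equal(100 * mediation_ratio(log(0.672), log(1.001), log(0.997)),
               13.2234, tolerance = 1e-4)
})

test_that("the ratio is invariant to rescaling all effects", {
  for (k in c(0.1, 3, 100)) {
    expect_equal(mediation_ratio(0.4 * k, -0.2 * k, 0.5 * k^2),
                 mediation_ratio(0.4, -0.2, 0.5))
  }
})

test_that("delta-method SE of the product matches a Monte-Carlo oracle", {
  expect_equal(mediation_se(1, 0.1, 1, 0.1), sqrt(0.02))
  expect_equal(mediation_se(0, 0.1, 0, 0.1), 0)
  expect_gt(mediation_se(0, 0.1, 0, 0.1, exact = TRUE), 0)

  medmr:::.with_seed(23, {
    a <- 1; b <- -0.6; se_a <- 0.05; se_b <- 0.04
    prod_draws <- rnorm(1e5, a, se_a) * rnorm(1e5, b, se_b)
    expect_lt(abs(mediation_se(a, se_a, b, se_b) - sd(prod_draws)) /
                sd(prod_draws), 0.05)
  })
})

test_that("classification is a pure function of p-values and signs", {
  expect_equal(classify_mediation(0.01, 0.02, 0.5, 0.2, 0.3), "partial")
  expect_equal(classify_mediation(0.01, 0.02, 0.5, 0.2, -0.3),
               "inconsistent")
  expect_equal(classify_mediation(0.2, 0.02, 0.5, 0.2, 0.3), "none")
  expect_equal(classify_mediation(0.01, 0.2, 0.5, 0.2, 0.3), "none")
  # vectorized
  expect_equal(classify_mediation(c(0.01, 0.3), c(0.01, 0.01),
                                  c(1, 1), c(1, 1), c(1, 1)),
               c("partial", "none"))
})

test_that("total_effect records the Egger fallback under directional
           pleiotropy", {
  st_clean <- simulate_study(truth_config(n_snps = 20, c_prime = -0.003,
                                          seed = 41))
  tot <- total_effect(st_clean$exposure, st_clean$outcome, seed = 41)
  expect_equal(tot$extras$method_choice, "ivw_re")
  expect_s3_class(tot$extras$selection_report, "data.frame")

  # a wide instrument-strength spread gives the Egger intercept the
  # leverage it needs (narrow spreads leave it unidentified)
  st_pleio <- simulate_study(truth_config(
    n_snps = 20, gamma = seq(0.15, 0.7, length.out = 8),
    c_prime = -0.003, pleio_mode = "directional",
    pleio_mean = 0.03, pleio_sd = 0.002, seed = 43))
  tot2 <- total_effect(st_pleio$exposure, st_pleio$outcome, seed = 43,
                       presso = FALSE, bonferroni_m = NA)
  expect_equal(tot2$extras$method_choice, "egger")
  expect_equal(tot2$method, "egger")
})

test_that("screening classifies true, inconsistent, and inestimable
           mediators correctly", {
  # a mediator whose indirect effect opposes the total effect
  cfg <- truth_config(n_snps = 30, alpha = c(Mo = 0.3), b = c(Mo = 0.01),
                      c_prime = -0.01, seed = 47)
  st <- simulate_study(cfg)
  tot <- total_effect(st$exposure, st$outcome, seed = 47, bonferroni_m = NA)
  scr <- screen_mediators(st$exposure, st$mediators, st$outcome,
                          total = tot, seed = 47)
  expect_equal(nrow(scr$results), 1)
  expect_equal(scr$results$classification, "inconsistent")
  expect_false(scr$results$direction_consistent)

  # no QTLs: the mediator has no instruments of its own
  cfg2 <- truth_config(n_snps = 30, alpha = c(M1 = 0), b = c(M1 = 0),
                       c_prime = -0.1, n_qtl = 0, seed = 48)
  st2 <- simulate_study(cfg2)
  tot2 <- total_effect(st2$exposure, st2$outcome, seed = 48,
                       bonferroni_m = NA)
  scr2 <- screen_mediators(st2$exposure, st2$mediators, st2$outcome,
                           total = tot2, seed = 48)
  expect_equal(scr2$results$classification, "not_estimable")
  expect_equal(scr2$results$n_snp_step2, 0)
  # output row count always equals input mediator count
  expect_equal(nrow(scr2$results), length(st2$mediators))
})

test_that("estimated indirect effects plus the direct effect recover theta
           at very large n", {
  # step-1 effects kept small enough that the exposure's instruments stay
  # below the suggestive tier in the mediator scans, so the mediators'
  # own QTLs are the step-2 instruments
  cfg <- truth_config(n_snps = 40, n_instruments = 8,
                      alpha = c(M1 = 0.02, M2 = -0.018),
                      b = c(M1 = -0.9, M2 = 0.8),
                      c_prime = -0.2676, n_x = 1e6, n_m = 1e6, n_y = 1e6,
                      delta_qtl = 0.1, seed = 51)
  expect_equal(truth_theta(cfg), -0.3)
  st <- simulate_study(cfg)
  tot <- mr_ivw(study_set(st), mode = "random")
  # equal-strength QTL panels leave the Egger slope unidentified, so the
  # intercept test fires spuriously at its nominal rate; tighten its level
  # for this consistency check
  scr <- screen_mediators(st$exposure, st$mediators, st$outcome,
                          total = tot, seed = 51, egger_alpha = 0.01)
  expect_lt(abs(tot$beta + 0.3) / 0.3, 0.05)
  truth_ab <- c(-0.018, -0.0144)
  expect_true(all(abs(scr$results$mediation_effect - truth_ab) <
                    0.05 * abs(truth_ab) + 0.01))
  direct <- tot$beta - sum(scr$results$mediation_effect)
  expect_lt(abs(direct + 0.2676), 0.05 * 0.3)
})

test_that("null-mediator panels produce almost no partial calls", {
  partials <- 0L
  tests <- 0L
  for (r in 1:40) {
    cfg <- truth_config(n_snps = 40,
                        alpha = c(N1 = 0, N2 = 0, N3 = 0, N4 = 0, N5 = 0),
                        b = c(N1 = 0, N2 = 0, N3 = 0, N4 = 0, N5 = 0),
                        c_prime = -0.1, seed = 9000 + r)
    st <- simulate_study(cfg)
    tot <- mr_ivw(study_set(st), mode = "random")
    scr <- screen_mediators(st$exposure, st$mediators, st$outcome,
                            total = tot, presso = FALSE, seed = r)
    partials <- partials + sum(scr$results$classification == "partial")
    tests <- tests + nrow(scr$results)
  }
  # two-step nominal screening: expected rate ~ alpha^2 / 2
  expect_lte(partials, 4)
  expect_equal(tests, 200L)
})
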