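test_that("Wald ratio arithmetic and its delta-method standard error", {
  est <- wald_ratio(0.1, 0.02, -0.02, 0.01)
  expect_equal(est$beta, -0.2)
  expect_equal(est$se, 0.1)
  expect_error(wald_ratio(0, 0.02, 0.1, 0.01), "degenerate")

  # second-order SE against a Monte-Carlo oracle on random inputs
  medmr:::.with_seed(99, {
    for (i in 1:5) {
      g <- runif(1, 0.2, 0.5); G <- runif(1, -0.2, 0.2)
      sg <- runif(1, 0.005, 0.02); sG <- runif(1, 0.005, 0.02)
      draws <- rnorm(2e5, G, sG) / rnorm(2e5, g, sg)
      se2 <- wald_ratio(g, sg, G, sG, second_order = TRUE)$se
      expect_lt(abs(se2 - sd(draws)) / sd(draws), 0.05)
    }
  })
})

test_that("IVW reduces to the Wald ratio for one SNP and to the exact
           slope for a perfect fit", {
  one <- make_set(gamma = 0.2, Gamma = 0.05)
  expect_warning(est <- mr_ivw(one), "single instrument")
  expect_equal(est$beta, 0.25)
  expect_equal(est$se, 0.01 / 0.2)

  g <- c(0.1, -0.2, 0.3, 0.15)
  perfect <- make_set(gamma = g, Gamma = 0.4 * g)
  fe <- mr_ivw(perfect, mode = "fixed")
  re <- mr_ivw(perfect, mode = "random")
  expect_equal(fe$beta, 0.4, tolerance = 1e-12)
  expect_equal(fe$extras$Q, 0, tolerance = 1e-20)
  expect_equal(fe$se, re$se)   # multiplier floored at 1
})

test_that("IVW fixed equals the zero-intercept WLS oracle on random
           fixtures", {
  for (seed in 1:100) {
    set <- random_set(8, seed = seed, theta = 0.3)
    fit <- lm(Gamma ~ gamma - 1, data = as.data.frame(set),
              weights = 1 / set$se_Gamma^2)
    est <- mr_ivw(set, mode = "fixed")
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-12)
    # unscaled WLS standard error (lm scales by residual sigma)
    se_wls <- sqrt(1 / sum(set$gamma^2 / set$se_Gamma^2))
    expect_equal(est$se, se_wls, tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact linear law and collapses to IVW without
           an intercept", {
  g <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  set <- make_set(gamma = g, Gamma = 0.01 + 0.3 * g)
  est <- mr_egger(set)
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$extras$intercept, 0.01, tolerance = 1e-12)
  expect_equal(est$extras$overdispersion, 1)  # zero residuals floor at 1

  for (seed in 1:20) {
    set2 <- random_set(8, seed = 200 + seed)
    expect_equal(mr_egger(set2, fit_intercept = FALSE)$beta,
                 mr_ivw(set2, mode = "fixed")$beta, tolerance = 1e-12)
  }
  expect_error(mr_egger(random_set(2, 1)), "at least 3")
})

test_that("weighted median interpolates cumulative weight 0.5", {
  set <- make_set(gamma = c(1, 1, 1), Gamma = c(0.1, 0.2, 0.9),
                  se_gamma = rep(1e-6, 3), se_Gamma = rep(1, 3))
  est <- mr_weighted_median(set, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2)

  same <- make_set(gamma = c(0.1, 0.2, 0.4), Gamma = c(0.03, 0.06, 0.12),
                   se_gamma = rep(1e-4, 3))
  est2 <- mr_weighted_median(same, n_boot = 200, seed = 2)
  expect_equal(est2$beta, 0.3, tolerance = 1e-9)
  expect_lt(est2$se, 0.15)

  # always inside the ratio range
  for (seed in 1:25) {
    s <- random_set(7, seed = 400 + seed)
    r <- s$Gamma / s$gamma
    wm <- mr_weighted_median(s, n_boot = 10, seed = seed)$beta
    expect_gte(wm, min(r)); expect_lte(wm, max(r))
  }
})

test_that("Cochran's Q arithmetic and perfect-fit degeneracy", {
  g <- c(0.2, 0.3, 0.25)
  set <- make_set(gamma = g, Gamma = 0.5 * g)
  q <- cochran_q(set)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$pvalue, 1)
  expect_equal(q$df, 2)

  pm <- make_set(gamma = c(1, 1), Gamma = c(1, -1),
                 se_gamma = rep(1e-6, 2), se_Gamma = c(1, 1))
  expect_equal(cochran_q(pm, beta_ref = 0)$Q, 2)
})

test_that("leave-one-out flags the observation driving the fit", {
  g <- seq(0.1, 0.6, length.out = 6)
  exact <- make_set(gamma = g, Gamma = 0.2 * g)
  loo <- leave_one_out(exact)
  expect_equal(nrow(loo), 6)
  expect_equal(loo$beta, rep(0.2, 6), tolerance = 1e-12)

  G <- 0.2 * g; G[4] <- G[4] + 0.2   # gross outlier
  spiked <- make_set(gamma = g, Gamma = G)
  loo2 <- leave_one_out(spiked)
  full <- mr_ivw(spiked)$beta
  expect_equal(which.max(abs(loo2$beta - full)), 4)
  expect_equal(nrow(leave_one_out(make_set(g[1:3], G[1:3]))), 3)
})

test_that("the overall Steiger direction test sums variance explained", {
  set <- make_set(gamma = rep(0.25, 6), Gamma = rep(0.001, 6),
                  se_gamma = rep(0.024, 6), se_Gamma = rep(0.0014, 6))
  d <- steiger_direction(set)
  expect_true(d$direction_correct)
  expect_gt(d$r2_exposure, d$r2_outcome)

  tie <- make_set(gamma = 0.2, Gamma = 0.2, se_gamma = 0.02,
                  se_Gamma = 0.02, n_exposure = 1000, n_outcome = 1000)
  expect_false(steiger_direction(tie)$direction_correct)  # strict
})

test_that("power formula: null calibration, monotonicity, and simulation
           agreement", {
  expect_equal(mr_power(1e5, 0.02, beta = 0, alpha = 0.05), 0.05)
  ns <- c(1e4, 5e4, 2e5, 1e6)
  pw <- vapply(ns, mr_power, numeric(1), r2_xz = 0.02, beta = 0.01)
  expect_true(all(diff(pw) > 0))

  # IVW rejection rate matches the formula
  n_y <- 5e4; beta <- 0.02
  f <- 0.3
  gamma <- rep(0.2, 8)
  r2 <- sum(2 * f * (1 - f) * gamma^2)
  predicted <- mr_power(n_y, r2, beta)
  se_y <- 1 / sqrt(n_y * 2 * f * (1 - f))
  rej <- medmr:::.with_seed(17, {
    vapply(1:1000, function(i) {
      G <- rnorm(8, beta * gamma, se_y)
      est <- mr_ivw(make_set(gamma, G, se_gamma = rep(1e-6, 8),
                             se_Gamma = rep(se_y, 8)), mode = "fixed")
      est$pvalue < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - predicted), 0.05)
})

test_that("all estimators are sign-equivariant and RE never undercuts FE", {
  for (seed in 1:15) {
    set <- random_set(8, seed = 500 + seed, theta = 0.25)
    neg <- as.data.frame(set)
    neg$Gamma <- -neg$Gamma
    neg <- medmr:::.as_harmonized(neg)

    ivw_p <- mr_ivw(set); ivw_n <- mr_ivw(neg)
    expect_equal(ivw_n$beta, -ivw_p$beta)
    expect_equal(ivw_n$se, ivw_p$se)
    expect_gte(ivw_p$se, mr_ivw(set, mode = "fixed")$se)

    eg_p <- mr_egger(set); eg_n <- mr_egger(neg)
    expect_equal(eg_n$beta, -eg_p$beta)
    expect_equal(eg_n$extras$intercept, -eg_p$extras$intercept)
    expect_equal(eg_n$se, eg_p$se)

    wm_p <- mr_weighted_median(set, n_boot = 50, seed = seed)
    wm_n <- mr_weighted_median(neg, n_boot = 50, seed = seed)
    expect_equal(wm_n$beta, -wm_p$beta)

    rp_p <- mr_raps(set); rp_n <- mr_raps(neg)
    expect_equal(rp_n$beta, -rp_p$beta, tolerance = 1e-6)
  }
})

test_that("plot-data exports are structurally consistent with the
           estimates", {
  set <- random_set(8, seed = 77, theta = 0.3)
  ests <- list(ivw_re = mr_ivw(set), egger = mr_egger(set))
  pd <- export_plot_data(set, ests)
  expect_equal(nrow(pd$scatter), 8)
  expect_true(all(pd$funnel$precision > 0))
  summary_rows <- pd$forest[pd$forest$summary, ]
  expect_equal(summary_rows$beta[summary_rows$label == "ivw_re"],
               ests$ivw_re$beta)
  expect_equal(unique(pd$funnel$reference), ests$ivw_re$beta)
})
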