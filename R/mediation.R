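#' Total (exposure-to-outcome) causal effect with the full cascade
#'
#' Runs the instrument-selection cascade and then the primary estimator:
#' random-effects IVW, replaced by the MR-Egger slope when the Egger
#' intercept test detects directional pleiotropy (intercept p below
#' `egger_alpha` with at least three instruments).
#'
#' @param exposure,outcome `summary_table`s.
#' @param ... Passed to [select_instruments()].
#' @param conf_level Confidence level.
#' @param egger_alpha Intercept-test level triggering the Egger fallback.
#' @return An `mr_estimate`; extras carry `method_choice`
#'   (`"ivw_re"`/`"egger"`), the `selection_report`, the final `set`, and
#'   the Egger intercept test when available.
#' @export
total_effect <- function(exposure, outcome, ..., conf_level = 0.95,
                         egger_alpha = 0.05) {
  sel <- select_instruments(exposure, outcome, ...)
  set <- sel$set
  if (nrow(set) < 1) {
    stop("insufficient instruments after selection cascade (0 remain)")
  }
  est <- mr_ivw(set, mode = "random", conf_level = conf_level)
  choice <- "ivw_re"
  if (nrow(set) >= 3) {
    eg <- mr_egger(set, conf_level = conf_level)
    est$extras$egger_intercept <- eg$extras$intercept
    est$extras$egger_intercept_p <- eg$extras$intercept_p
    if (eg$extras$intercept_p < egger_alpha) {
      est_new <- eg
      est_new$extras <- c(est_new$extras, est$extras["Q"], est$extras["Q_pvalue"])
      est <- est_new
      choice <- "egger"
    }
  }
  est$extras$method_choice <- choice
  est$extras$selection_report <- sel$report
  est$extras$set <- set
  est
}

#' Mediation (indirect) effect: product of coefficients
#'
#' @param a Step-1 effect (exposure on mediator).
#' @param b Step-2 effect (mediator on outcome).
#' @return `a * b`.
#' @export
mediation_effect <- function(a, b) a * b

#' Mediation proportion: indirect over total effect
#'
#' Signed ratio `a*b / theta`; may be negative or exceed 1 when mediators
#' act against each other or against the direct effect.
#'
#' @param a,b Step-1 and step-2 effects.
#' @param theta Total effect; must be nonzero.
#' @return `a * b / theta`.
#' @export
mediation_ratio <- function(a, b, theta) {
  if (any(theta == 0)) stop("mediation ratio undefined: total effect is zero")
  a * b / theta
}

#' Delta-method standard error of a product of coefficients
#'
#' First-order: `sqrt(a^2 se_b^2 + b^2 se_a^2)`; the exact-product variant
#' adds `se_a^2 se_b^2`. Degenerate at `a = b = 0` under the first-order
#' form (returns 0).
#'
#' @param a,se_a,b,se_b Effects and their standard errors.
#' @param exact Include the `se_a^2 se_b^2` term?
#' @return Standard error of `a*b`.
#' @export
mediation_se <- function(a, se_a, b, se_b, exact = FALSE) {
  stopifnot(all(se_a > 0), all(se_b > 0))
  v <- a^2 * se_b^2 + b^2 * se_a^2
  if (exact) v <- v + se_a^2 * se_b^2
  sqrt(v)
}

#' Classify a mediator from its two step results
#'
#' `"partial"` when both steps are significant at `alpha` and the indirect
#' effect's sign agrees with the total effect; `"inconsistent"` when both
#' steps are significant but the signs oppose; `"none"` otherwise.
#'
#' @param p_a,p_b Step p-values.
#' @param a,b,theta Effects.
#' @param alpha Per-step significance level.
#' @return Character scalar.
#' @export
classify_mediation <- function(p_a, p_b, a, b, theta, alpha = 0.05) {
  both <- p_a < alpha & p_b < alpha
  consistent <- sign(a * b) == sign(theta) & a * b != 0 & theta != 0
  ifelse(both & consistent, "partial",
         ifelse(both, "inconsistent", "none"))
}

#' Screen a mediator panel with two-step MR
#'
#' For each mediator: step 1 estimates the exposure effect on the mediator
#' using the exposure's instruments (genome-wide tier); step 2 estimates
#' the mediator effect on the outcome using the mediator's own instruments
#' selected at the suggestive tier (`step2_threshold`), each step running
#' the selection cascade and the primary estimator of [total_effect()].
#' Mediators significant in both steps with sign-consistent indirect effect
#' are classified `"partial"`. Mediators with no surviving instruments are
#' reported as `"not_estimable"` rather than raising.
#'
#' The Bonferroni outcome filter defaults off in step 2: a mediator with a
#' genuine outcome effect makes its own QTLs legitimately
#' outcome-associated, which is exactly what that filter would remove. Set
#' `step2_bonferroni_m` to a denominator to enable it.
#'
#' @param exposure Exposure `summary_table`.
#' @param mediators Named list of mediator `summary_table`s.
#' @param outcome Outcome `summary_table`.
#' @param total Optional precomputed total-effect `mr_estimate`; computed
#'   from the tables when `NULL`.
#' @param alpha_step Per-step significance level.
#' @param step1_threshold,step2_threshold Instrument p-value tiers.
#' @param step2_bonferroni_m `NA` (default) to skip the Bonferroni outcome
#'   filter in step 2, `NULL` for the set-size denominator, or a count.
#' @param mtc Multiple-testing correction applied to each step's p-values
#'   across the panel: `"none"` (default), `"bonferroni"`, or `"bh"`.
#' @param presso Run PRESSO inside the per-step cascades?
#' @param egger_alpha Egger-fallback intercept level.
#' @param seed Seed for the stochastic cascade stages.
#' @param ... Further arguments for [select_instruments()] (both steps).
#' @return List with `results` (one row per mediator: step effects, SEs,
#'   p-values, mediation effect/SE/proportion, direction flag,
#'   classification) and `reports` (per-mediator selection reports).
#' @export
screen_mediators <- function(exposure, mediators, outcome, total = NULL,
                             alpha_step = 0.05,
                             step1_threshold = 5e-8,
                             step2_threshold = 1e-5,
                             step2_bonferroni_m = NA,
                             mtc = c("none", "bonferroni", "bh"),
                             presso = TRUE, egger_alpha = 0.05,
                             seed = 1, ...) {
  mtc <- match.arg(mtc)
  stopifnot(length(mediators) >= 1)
  if (is.null(names(mediators))) {
    names(mediators) <- vapply(mediators, trait_id, character(1))
  }
  if (is.null(total)) {
    total <- total_effect(exposure, outcome, pval_threshold = step1_threshold,
                          presso = presso, seed = seed,
                          egger_alpha = egger_alpha, ...)
  }
  theta <- total$beta

  one_step <- function(from, to, threshold, bonferroni_m) {
    sel <- select_instruments(from, to, pval_threshold = threshold,
                              presso = presso, bonferroni_m = bonferroni_m,
                              seed = seed, ...)
    if (nrow(sel$set) < 1) {
      return(list(est = NULL, report = sel$report, n = 0L))
    }
    est <- mr_ivw(sel$set, mode = "random")
    method <- "ivw_re"
    if (nrow(sel$set) >= 3) {
      eg <- mr_egger(sel$set)
      if (eg$extras$intercept_p < egger_alpha) {
        est <- eg
        method <- "egger"
      }
    }
    list(est = est, report = sel$report, n = nrow(sel$set), method = method)
  }

  reports <- list()
  rows <- lapply(names(mediators), function(nm) {
    s1 <- one_step(exposure, mediators[[nm]], step1_threshold,
                   bonferroni_m = step2_bonferroni_m)
    s2 <- one_step(mediators[[nm]], outcome, step2_threshold,
                   bonferroni_m = step2_bonferroni_m)
    reports[[nm]] <<- list(step1 = s1$report, step2 = s2$report)
    if (is.null(s1$est) || is.null(s2$est)) {
      return(data.frame(
        mediator = nm, n_snp_step1 = s1$n, n_snp_step2 = s2$n,
        a = NA_real_, se_a = NA_real_, p_a = NA_real_,
        b = NA_real_, se_b = NA_real_, p_b = NA_real_,
        theta = theta, se_theta = total$se, p_theta = total$pvalue,
        mediation_effect = NA_real_, mediation_se = NA_real_,
        ratio = NA_real_, direction_consistent = NA,
        classification = "not_estimable",
        method_step1 = if (is.null(s1$est)) NA_character_ else s1$method,
        method_step2 = if (is.null(s2$est)) NA_character_ else s2$method,
        stringsAsFactors = FALSE))
    }
    a <- s1$est$beta; b <- s2$est$beta
    data.frame(
      mediator = nm, n_snp_step1 = s1$n, n_snp_step2 = s2$n,
      a = a, se_a = s1$est$se, p_a = s1$est$pvalue,
      b = b, se_b = s2$est$se, p_b = s2$est$pvalue,
      theta = theta, se_theta = total$se, p_theta = total$pvalue,
      mediation_effect = mediation_effect(a, b),
      mediation_se = mediation_se(a, s1$est$se, b, s2$est$se),
      ratio = if (theta != 0) mediation_ratio(a, b, theta) else NA_real_,
      direction_consistent = sign(a * b) == sign(theta) &
        a * b != 0 & theta != 0,
      classification = NA_character_,
      method_step1 = s1$method, method_step2 = s2$method,
      stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)

  estimable <- is.na(results$classification)
  p_a <- results$p_a; p_b <- results$p_b
  if (mtc != "none") {
    method <- if (mtc == "bh") "BH" else "bonferroni"
    p_a <- stats::p.adjust(p_a, method = method)
    p_b <- stats::p.adjust(p_b, method = method)
    results$p_a_adj <- p_a
    results$p_b_adj <- p_b
  }
  cls <- classify_mediation(p_a, p_b, results$a, results$b, results$theta,
                            alpha = alpha_step)
  results$classification[estimable] <- cls[estimable]
  rownames(results) <- NULL
  list(results = results, reports = reports, total = total)
}
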