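#' Construct an MR estimate object
#'
#' Internal-facing constructor shared by all estimators; kept exported so
#' downstream code can build comparable objects.
#'
#' @param method Method label (`"wald"`, `"ivw_fe"`, `"ivw_re"`, `"egger"`,
#'   `"wm"`, `"raps"`).
#' @param beta,se Point estimate and standard error.
#' @param n_snp Number of instruments used.
#' @param conf_level Confidence level for the interval.
#' @param df Degrees of freedom for a t reference distribution, or `NULL`
#'   for the normal.
#' @param extras Named list of method-specific extras.
#' @return An `mr_estimate` list with `beta`, `se`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_snp`, `method`, `conf_level`, `extras`.
#' @export
mr_estimate <- function(method, beta, se, n_snp, conf_level = 0.95,
                        df = NULL, extras = list()) {
  stopifnot(se >= 0)
  if (is.null(df)) {
    q <- stats::qnorm(1 - (1 - conf_level) / 2)
    p <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  } else {
    q <- stats::qt(1 - (1 - conf_level) / 2, df)
    p <- if (se > 0) 2 * stats::pt(-abs(beta / se), df) else as.numeric(beta == 0)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - q * se, ci_high = beta + q * se,
                 pvalue = max(p, .Machine$double.xmin), n_snp = n_snp,
                 conf_level = conf_level, df = df, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s, %d SNP(s)]: beta = %.4g (%.4g to %.4g), se = %.4g, p = %.3g\n",
              x$method, x$n_snp, x$beta, x$ci_low, x$ci_high, x$se, x$pvalue))
  if (x$method == "egger" && !is.null(x$extras$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g, p = %.3g)\n",
                x$extras$intercept, x$extras$intercept_se,
                x$extras$intercept_p))
  }
  invisible(x)
}

#' Wald ratio for a single instrument
#'
#' `beta = Gamma / gamma` with first-order standard error
#' `se_Gamma / |gamma|`; the second-order option adds the delta-method term
#' from the uncertainty in the SNP-exposure effect.
#'
#' @param gamma,se_gamma SNP-exposure effect and SE.
#' @param Gamma,se_Gamma SNP-outcome effect and SE.
#' @param second_order Include the `Gamma^2 se_gamma^2 / gamma^4` term?
#' @param conf_level Confidence level.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       second_order = FALSE, conf_level = 0.95) {
  if (gamma == 0) stop("degenerate instrument: gamma = 0")
  beta <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    se_Gamma / abs(gamma)
  }
  mr_estimate("wald", beta, se, n_snp = 1L, conf_level = conf_level)
}

# per-SNP Wald ratios and their first-order variances
.ratios <- function(set) {
  list(ratio = set$Gamma / set$gamma,
       var = set$se_Gamma^2 / set$gamma^2)
}

#' Inverse-variance weighted estimator
#'
#' Fixed-effect: `beta = sum(w g G) / sum(w g^2)` with `w = 1/se_Gamma^2`
#' and `se = 1/sqrt(sum(w g^2))` — identical to a zero-intercept weighted
#' least-squares fit of the SNP-outcome on the SNP-exposure effects. The
#' multiplicative random-effects model scales the SE by
#' `max(1, sqrt(Q/(n-1)))`; its interval and p-value use a t reference with
#' `n - 1` degrees of freedom, since the overdispersion factor is itself
#' estimated from the same handful of instruments (typically eight). The
#' fixed-effect model uses the normal reference. A single-SNP set degrades
#' to the Wald ratio with a warning.
#'
#' @param set A `harmonized_set` (or data frame with `gamma`, `se_gamma`,
#'   `Gamma`, `se_Gamma`).
#' @param mode `"random"` (primary) or `"fixed"`.
#' @param conf_level Confidence level.
#' @return An `mr_estimate`; extras carry `Q`, `Q_df`, `Q_pvalue` and the
#'   overdispersion multiplier.
#' @export
mr_ivw <- function(set, mode = c("random", "fixed"), conf_level = 0.95) {
  mode <- match.arg(mode)
  n <- nrow(set)
  if (n == 0) stop("empty instrument set")
  if (n == 1) {
    warning("single instrument: IVW degrades to the Wald ratio",
            call. = FALSE)
    est <- wald_ratio(set$gamma, set$se_gamma, set$Gamma, set$se_Gamma,
                      conf_level = conf_level)
    est$method <- if (mode == "random") "ivw_re" else "ivw_fe"
    return(est)
  }
  w <- 1 / set$se_Gamma^2
  sxx <- sum(w * set$gamma^2)
  beta <- sum(w * set$gamma * set$Gamma) / sxx
  se_fe <- 1 / sqrt(sxx)
  Q <- sum(w * (set$Gamma - beta * set$gamma)^2)
  df <- n - 1
  mult <- max(1, sqrt(Q / df))
  extras <- list(Q = Q, Q_df = df,
                 Q_pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
                 overdispersion = mult)
  if (mode == "fixed") {
    mr_estimate("ivw_fe", beta, se_fe, n, conf_level, extras = extras)
  } else {
    mr_estimate("ivw_re", beta, se_fe * mult, n, conf_level, df = df,
                extras = extras)
  }
}

#' MR-Egger regression
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, weights `1/se_Gamma^2`, after orienting
#' every SNP so that its exposure effect is non-negative. The slope is the
#' causal estimate; the intercept estimates directional pleiotropy.
#' Standard errors carry a multiplicative overdispersion factor
#' `max(1, sqrt(RSS/(n-2)))`; inference uses the t distribution with
#' `n - 2` degrees of freedom.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param conf_level Confidence level.
#' @param fit_intercept If `FALSE`, the intercept is constrained to zero
#'   and the slope algebraically equals the fixed-effect IVW estimate.
#' @return An `mr_estimate` with extras `intercept`, `intercept_se`,
#'   `intercept_p` (when fitted).
#' @export
mr_egger <- function(set, conf_level = 0.95, fit_intercept = TRUE) {
  n <- nrow(set)
  if (fit_intercept && n < 3) {
    stop("MR-Egger needs at least 3 instruments, got ", n)
  }
  flip <- sign(set$gamma)
  flip[flip == 0] <- 1
  g <- set$gamma * flip
  G <- set$Gamma * flip
  w <- 1 / set$se_Gamma^2
  X <- if (fit_intercept) cbind(1, g) else cbind(g)
  df <- n - ncol(X)
  xtwx_inv <- solve(crossprod(X, w * X))
  coef <- unname(drop(xtwx_inv %*% crossprod(X, w * G)))
  rss <- sum(w * (G - drop(X %*% coef))^2)
  sigma <- if (df > 0) sqrt(rss / df) else 0
  mult <- max(1, sigma)
  unscaled_se <- unname(sqrt(diag(xtwx_inv)))
  slope_row <- if (fit_intercept) 2 else 1
  beta <- coef[slope_row]
  se <- unscaled_se[slope_row] * mult
  extras <- list(overdispersion = mult)
  if (fit_intercept) {
    i_se <- unscaled_se[1] * mult
    i_beta <- coef[1]
    extras$intercept <- i_beta
    extras$intercept_se <- i_se
    extras$intercept_p <- if (i_se > 0) {
      2 * stats::pt(-abs(i_beta / i_se), df)
    } else as.numeric(i_beta == 0)
  }
  mr_estimate("egger", beta, se, n, conf_level, df = df, extras = extras)
}

#' Weighted-median estimator
#'
#' Orders the per-SNP Wald ratios, weights them by their inverse first-order
#' variances, and linearly interpolates the ratio at cumulative weight 0.5
#' (using mid-interval cumulative weights, so three equal-weight ratios give
#' exactly the middle one). The standard error comes from a parametric
#' bootstrap: SNP effects are resampled from their normal sampling
#' distributions and the estimator recomputed.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap (local RNG stream).
#' @param conf_level Confidence level.
#' @return An `mr_estimate` with `extras$n_boot`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1,
                               conf_level = 0.95) {
  n <- nrow(set)
  if (n < 3) stop("weighted median needs at least 3 instruments, got ", n)
  est <- .wm_point(set$gamma, set$Gamma, set$se_Gamma)
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- stats::rnorm(n, set$gamma, set$se_gamma)
      G <- stats::rnorm(n, set$Gamma, set$se_Gamma)
      .wm_point(g, G, set$se_Gamma)
    }, numeric(1))
  })
  mr_estimate("wm", est, stats::sd(boots), n, conf_level,
              extras = list(n_boot = n_boot))
}

.wm_point <- function(gamma, Gamma, se_Gamma) {
  ratio <- Gamma / gamma
  w <- gamma^2 / se_Gamma^2
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(ratio[1])
  if (cum[length(cum)] <= 0.5) return(ratio[length(ratio)])
  stats::approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (ratio_j - beta_ref)^2)` with inverse-variance weights on
#' the per-SNP Wald ratios (first-order), referred to a chi-square with
#' `n - 1` degrees of freedom.
#'
#' @param set A `harmonized_set` with at least 2 SNPs.
#' @param beta_ref Reference causal estimate; defaults to fixed-effect IVW.
#' @return List with `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(set, beta_ref = NULL) {
  n <- nrow(set)
  if (n < 2) stop("Cochran's Q needs at least 2 instruments")
  if (is.null(beta_ref)) beta_ref <- mr_ivw(set, mode = "fixed")$beta
  r <- .ratios(set)
  Q <- sum((r$ratio - beta_ref)^2 / r$var)
  df <- n - 1
  list(Q = Q, df = df, pvalue = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Leave-one-out analysis
#'
#' Recomputes the primary (random-effects IVW) estimate with each SNP
#' excluded in turn, in input order.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param conf_level Confidence level.
#' @return Data frame with one row per excluded SNP: `excluded`, `beta`,
#'   `se`, `ci_low`, `ci_high`, `pvalue`, `n_snp`.
#' @export
leave_one_out <- function(set, conf_level = 0.95) {
  n <- nrow(set)
  if (n < 3) stop("leave-one-out needs at least 3 instruments")
  rows <- lapply(seq_len(n), function(i) {
    est <- mr_ivw(.subset_harmonized(set, -i), mode = "random",
                  conf_level = conf_level)
    data.frame(excluded = set$snp[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overall Steiger direction test
#'
#' Sums per-SNP variance explained (`r^2 = t^2/(t^2 + n - 2)`) across the
#' instrument set for each trait; the assumed exposure-to-outcome direction
#' is supported when the exposure sum is strictly larger.
#'
#' @param set A `harmonized_set` with sample sizes.
#' @return List with `direction_correct`, `r2_exposure`, `r2_outcome`.
#' @export
steiger_direction <- function(set) {
  stopifnot(all(set$n_exposure > 2), all(set$n_outcome > 2))
  r2_exp <- sum(.steiger_r2(set$gamma, set$se_gamma, set$n_exposure))
  r2_out <- sum(.steiger_r2(set$Gamma, set$se_Gamma, set$n_outcome))
  list(direction_correct = r2_exp > r2_out,
       r2_exposure = r2_exp, r2_outcome = r2_out)
}

#' Approximate statistical power of a two-sample MR analysis
#'
#' Normal approximation for a continuous standardized outcome:
#' `power = Phi(|beta| sqrt(n r2) - z) + Phi(-|beta| sqrt(n r2) - z)` with
#' `z` the upper `alpha/2` normal quantile.
#'
#' @param n_outcome Outcome-study sample size.
#' @param r2_xz Variance of the exposure explained by the instruments.
#' @param beta True causal effect (SD per SD).
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
mr_power <- function(n_outcome, r2_xz, beta, alpha = 0.05) {
  stopifnot(n_outcome > 0, r2_xz > 0, r2_xz < 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(beta) * sqrt(n_outcome * r2_xz)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Export scatter, funnel, and forest plot data
#'
#' Produces the data behind the three standard MR displays without
#' rendering them: per-SNP effect pairs with fitted lines per method
#' (scatter), per-SNP ratios against precision with the IVW reference
#' (funnel), and per-SNP ratio intervals plus summary rows (forest).
#'
#' @param set A `harmonized_set`.
#' @param estimates Named list of `mr_estimate` objects (e.g. from
#'   [mr_ivw()], [mr_egger()]).
#' @param conf_level Confidence level for per-SNP intervals.
#' @return List of data frames `scatter`, `fits`, `funnel`, `forest`.
#' @export
export_plot_data <- function(set, estimates, conf_level = 0.95) {
  stopifnot(length(estimates) > 0)
  if (is.null(names(estimates))) {
    names(estimates) <- vapply(estimates, `[[`, character(1), "method")
  }
  r <- .ratios(set)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  scatter <- data.frame(snp = set$snp, gamma = set$gamma,
                        se_gamma = set$se_gamma, Gamma = set$Gamma,
                        se_Gamma = set$se_Gamma, stringsAsFactors = FALSE)
  fits <- do.call(rbind, lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    data.frame(method = nm, slope = e$beta,
               intercept = if (!is.null(e$extras$intercept))
                 e$extras$intercept else 0,
               stringsAsFactors = FALSE)
  }))
  ivw_beta <- if ("ivw_re" %in% fits$method) {
    fits$slope[fits$method == "ivw_re"][1]
  } else fits$slope[1]
  funnel <- data.frame(snp = set$snp, ratio = r$ratio,
                       precision = 1 / sqrt(r$var),
                       reference = ivw_beta, stringsAsFactors = FALSE)
  forest <- rbind(
    data.frame(label = set$snp, beta = r$ratio,
               ci_low = r$ratio - q * sqrt(r$var),
               ci_high = r$ratio + q * sqrt(r$var),
               summary = FALSE, stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(estimates), function(nm) {
      e <- estimates[[nm]]
      data.frame(label = nm, beta = e$beta, ci_low = e$ci_low,
                 ci_high = e$ci_high, summary = TRUE,
                 stringsAsFactors = FALSE)
    }))
  )
  list(scatter = scatter, fits = fits, funnel = funnel, forest = forest)
}
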