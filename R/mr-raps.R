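.raps_psi <- function(loss, k) {
  switch(loss,
    simple = list(
      psi = function(x) x,
      dpsi = function(x) rep(1, length(x)),
      delta = 1),
    huber = list(
      psi = function(x) pmin(pmax(x, -k), k),
      dpsi = function(x) as.numeric(abs(x) <= k),
      # E[psi(Z) Z] for standard normal Z
      delta = {
        f <- function(z) pmin(pmax(z, -k), k) * z * stats::dnorm(z)
        stats::integrate(f, -Inf, Inf)$value
      }),
    tukey = list(
      psi = function(x) ifelse(abs(x) < k, x * (1 - (x / k)^2)^2, 0),
      dpsi = function(x) ifelse(abs(x) < k,
                                (1 - (x / k)^2) * (1 - 5 * (x / k)^2), 0),
      delta = {
        f <- function(z) ifelse(abs(z) < k, z * (1 - (z / k)^2)^2, 0) * z *
          stats::dnorm(z)
        stats::integrate(f, -Inf, Inf)$value
      })
  )
}

#' Robust adjusted profile score estimator
#'
#' Solves the adjusted profile estimating equation
#' `sum(psi(t_j) * d_j) = 0` with standardized residuals
#' `t_j = (Gamma_j - beta * gamma_j) / sigma_j`,
#' `sigma_j^2 = se_Gamma_j^2 + beta^2 * se_gamma_j^2 + tau2`, and
#' `d_j = -d t_j / d beta`; `psi` is the chosen robust score. With
#' overdispersion on, the systematic-pleiotropy variance `tau2` is solved
#' jointly from the second moment condition
#' `sum(psi(t_j) t_j - delta) = 0` (with `delta = E[psi(Z) Z]` under the
#' standard normal) and floored at zero. The standard error is the
#' M-estimation sandwich. Root finding is deterministic: starts are taken
#' from the fixed-effect IVW, the weighted median and zero, with an
#' expanding bisection bracket.
#'
#' @param set A `harmonized_set` with at least 3 SNPs.
#' @param loss `"huber"` (default, tuning constant 1.345), `"simple"`, or
#'   `"tukey"` (tuning constant 4.685).
#' @param k Tuning constant override.
#' @param overdispersion Solve for `tau2` jointly?
#' @param conf_level Confidence level.
#' @return An `mr_estimate` with extras `tau2` and `loss`.
#' @export
mr_raps <- function(set, loss = c("huber", "simple", "tukey"), k = NULL,
                    overdispersion = TRUE, conf_level = 0.95) {
  loss <- match.arg(loss)
  n <- nrow(set)
  if (n < 3) stop("MR-RAPS needs at least 3 instruments, got ", n)
  if (is.null(k)) k <- switch(loss, huber = 1.345, tukey = 4.685, simple = Inf)
  fam <- .raps_psi(loss, k)

  g <- set$gamma; G <- set$Gamma
  s2g <- set$se_gamma^2; s2G <- set$se_Gamma^2

  score <- function(beta, tau2) {
    sig2 <- s2G + beta^2 * s2g + tau2
    sig <- sqrt(sig2)
    t <- (G - beta * g) / sig
    d <- (g * sig2 + (G - beta * g) * beta * s2g) / (sig2 * sig)
    sum(fam$psi(t) * d)
  }
  overdisp_gap <- function(beta, tau2) {
    sig <- sqrt(s2G + beta^2 * s2g + tau2)
    t <- (G - beta * g) / sig
    sum(fam$psi(t) * t - fam$delta)
  }

  starts <- unique(c(mr_ivw(set, mode = "fixed")$beta,
                     tryCatch(.wm_point(g, G, set$se_Gamma),
                              error = function(e) NULL), 0))
  # the profile score is not monotone in beta (bounded psi, ratio-like
  # geometry), so walk outward from each start on a fine grid and take the
  # sign change closest to the start
  solve_beta <- function(tau2) {
    for (s in starts) {
      step <- max(abs(s), 0.1) / 50
      grid <- s + step * (-500:500)
      vals <- vapply(grid, score, numeric(1), tau2 = tau2)
      finite <- is.finite(vals)
      flip <- which(finite[-length(vals)] & finite[-1] &
                      sign(vals[-length(vals)]) != sign(vals[-1]))
      if (length(flip) > 0) {
        nearest <- flip[which.min(abs(grid[flip] - s))]
        return(stats::uniroot(score, c(grid[nearest], grid[nearest + 1]),
                              tau2 = tau2, tol = 1e-12)$root)
      }
    }
    stop("MR-RAPS estimating equation has no sign change near starts [",
         paste(format(starts), collapse = ", "), "]")
  }

  tau2 <- 0
  beta <- solve_beta(tau2)
  if (overdispersion) {
    for (iter in 1:50) {
      gap0 <- overdisp_gap(beta, 0)
      if (gap0 <= 0) {
        tau2_new <- 0   # floor: data are underdispersed at tau2 = 0
      } else {
        upper <- stats::var(G - beta * g) + max(s2G)
        for (i in 1:40) {
          if (overdisp_gap(beta, upper) < 0) break
          upper <- upper * 2
        }
        tau2_new <- stats::uniroot(function(t2) overdisp_gap(beta, t2),
                                   c(0, upper), tol = 1e-14)$root
      }
      beta_new <- solve_beta(tau2_new)
      done <- abs(beta_new - beta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      beta <- beta_new; tau2 <- tau2_new
      if (done) break
    }
  }

  # M-estimation sandwich with tau2 held fixed
  sig2 <- s2G + beta^2 * s2g + tau2
  sig <- sqrt(sig2)
  t <- (G - beta * g) / sig
  d <- (g * sig2 + (G - beta * g) * beta * s2g) / (sig2 * sig)
  A <- sum(fam$dpsi(t) * d^2)
  B <- sum(fam$psi(t)^2 * d^2)
  if (A <= 0) stop("MR-RAPS sandwich variance is degenerate")
  se <- sqrt(B) / A

  mr_estimate("raps", beta, se, n, conf_level,
              extras = list(tau2 = tau2, loss = loss, k = k,
                            overdispersion = overdispersion))
}
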