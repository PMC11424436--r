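#' Ground-truth configuration for a simulated mediation-MR study
#'
#' Describes the linear structural model X -> M_k -> Y from which synthetic
#' exposure, mediator, and outcome GWAS summary tables are generated.
#' Instrument SNPs carry true per-allele effects `gamma` on the exposure;
#' each mediator k responds to the exposure with slope `alpha[k]` and acts
#' on the outcome with slope `b[k]`; `c_prime` is the direct
#' exposure-to-outcome effect, so the total effect is
#' `theta = c_prime + sum(alpha * b)`. Mediators additionally carry their
#' own independent QTLs (`n_qtl` SNPs of effect `delta_qtl` each), the
#' analogue of cis-pQTLs, which are what the mediator-to-outcome step
#' instruments in practice.
#'
#' Traits and genotypes are standardized, so a SNP with allele frequency f
#' in a study of size n has standard error `1/sqrt(n * 2f(1-f))` — the
#' "per 1 SD" effect scale, giving realistically tiny SEs at biobank-scale
#' n. Default sample sizes mirror a selenium exposure GWAS (n = 4,162), a
#' plasma-proteome panel (n = 3,301), and an eGFR meta-analysis
#' (n = 1,201,909).
#'
#' @param n_snps Total SNPs in the shared universe.
#' @param n_instruments Number of (lead) exposure instruments.
#' @param maf_range Interval within (0, 0.5] from which allele frequencies
#'   are drawn uniformly.
#' @param gamma True SNP-to-exposure effects for the instruments (length
#'   `n_instruments`); default evenly spaced magnitudes 0.15-0.30 with
#'   alternating sign, giving single-SNP F-statistics of roughly 30-190 at
#'   the default exposure sample size — strong instruments that reliably
#'   clear the genome-wide tier, as a published selenium instrument set
#'   does.
#' @param alpha Named numeric vector of exposure-to-mediator effects, one
#'   per mediator (may be empty: no mediators).
#' @param b Mediator-to-outcome effects, same length/names as `alpha`.
#' @param c_prime Direct exposure-to-outcome effect.
#' @param pleio_mode `"none"`, `"balanced"` (mean-zero) or `"directional"`
#'   horizontal pleiotropy added to instruments' outcome effects.
#' @param pleio_sd,pleio_mean Pleiotropy scale and (directional) mean.
#' @param n_rev Number of reverse-causal SNPs: true outcome effect
#'   `gamma_rev`, with an induced exposure effect `theta_rev * gamma_rev`.
#' @param n_outlier Number of instruments whose outcome effect is inflated
#'   by `outlier_mult` outcome standard errors (planted pleiotropic
#'   outliers).
#' @param outlier_mult Outlier offset in units of the SNP's outcome SE.
#' @param gamma_rev,theta_rev Reverse-causal SNP parameters; the defaults
#'   make such a SNP detectable at the suggestive exposure tier while its
#'   variance explained remains clearly larger in the outcome.
#' @param n_qtl,delta_qtl Per-mediator independent QTL count and effect.
#' @param n_x,n_m,n_y Sample sizes of the exposure, mediator and outcome
#'   studies.
#' @param swap_prob Probability that a non-exposure table reports a SNP in
#'   the opposite allele orientation (alleles swapped, beta negated, EAF
#'   complemented) — exercised by harmonization.
#' @param eaf_noise If `TRUE`, reported EAFs get binomial sampling noise per
#'   study.
#' @param ld_block_size If > 1, each lead instrument is expanded into an LD
#'   block of this many SNPs (proxies with attenuated effects), and the
#'   matching LD matrix is attached to the study so clumping is testable.
#' @param ld_block_r2 Squared correlation between a lead and its proxies.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A `truth_config` list.
#' @export
truth_config <- function(n_snps = 60, n_instruments = 8,
                         maf_range = c(0.2, 0.5),
                         gamma = NULL,
                         alpha = numeric(0), b = numeric(0),
                         c_prime = -0.003,
                         pleio_mode = c("none", "balanced", "directional"),
                         pleio_sd = 0, pleio_mean = 0,
                         n_rev = 0, n_outlier = 0, outlier_mult = 10,
                         gamma_rev = 0.15, theta_rev = 0.7,
                         n_qtl = 5, delta_qtl = 0.3,
                         n_x = 4162, n_m = 3301, n_y = 1201909,
                         swap_prob = 0.3, eaf_noise = TRUE,
                         ld_block_size = 1, ld_block_r2 = 0.9,
                         seed = 1) {
  pleio_mode <- match.arg(pleio_mode)
  if (is.null(gamma)) {
    gamma <- seq(0.15, 0.3, length.out = n_instruments) *
      rep_len(c(1, -1), n_instruments)
  }
  stopifnot(length(gamma) == n_instruments,
            all(is.finite(gamma)),
            length(alpha) == length(b),
            all(is.finite(alpha)), all(is.finite(b)), is.finite(c_prime),
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_x >= 2, n_m >= 2, n_y >= 2,
            n_outlier <= n_instruments,
            ld_block_size >= 1, ld_block_r2 > 0, ld_block_r2 <= 1)
  n_med <- length(alpha)
  if (n_med > 0 && is.null(names(alpha))) {
    names(alpha) <- names(b) <- sprintf("M%02d", seq_len(n_med))
  } else if (n_med > 0) {
    names(b) <- names(alpha)
  }
  needed <- n_instruments * ld_block_size + n_med * n_qtl + n_rev
  if (n_snps < needed) {
    stop("n_snps (", n_snps, ") too small for the configured structure (",
         needed, " structured SNPs)")
  }
  structure(list(
    n_snps = n_snps, n_instruments = n_instruments, maf_range = maf_range,
    gamma = gamma, alpha = alpha, b = b, c_prime = c_prime,
    pleio_mode = pleio_mode, pleio_sd = pleio_sd, pleio_mean = pleio_mean,
    n_rev = n_rev, n_outlier = n_outlier, outlier_mult = outlier_mult,
    gamma_rev = gamma_rev, theta_rev = theta_rev,
    n_qtl = n_qtl, delta_qtl = delta_qtl,
    n_x = n_x, n_m = n_m, n_y = n_y,
    swap_prob = swap_prob, eaf_noise = eaf_noise,
    ld_block_size = ld_block_size, ld_block_r2 = ld_block_r2,
    seed = seed
  ), class = "truth_config")
}

#' Total effect implied by a truth configuration
#' @param cfg A `truth_config`.
#' @return `c_prime + sum(alpha * b)`.
#' @export
truth_theta <- function(cfg) cfg$c_prime + sum(cfg$alpha * cfg$b)

# per-allele SE for a standardized trait
.marginal_se <- function(n, f) 1 / sqrt(n * 2 * f * (1 - f))

# run expr with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a three-table mediation-MR study with known truth
#'
#' Generates exposure, per-mediator, and outcome GWAS summary tables under
#' the structural model described in [truth_config()]. Marginal true
#' effects: an instrument j with exposure effect `gamma_j` has mediator-k
#' effect `alpha_k * gamma_j` and outcome effect `theta * gamma_j` plus any
#' pleiotropy/outlier term; a mediator QTL has outcome effect
#' `b_k * delta_qtl`; reverse-causal SNPs act on the outcome directly with
#' an induced exposure effect; all other SNPs are null. Observed effects are
#' `Normal(true, se^2)` with `se = 1/sqrt(n * 2 f (1-f))`; p-values are
#' two-sided normal. Deterministic given `cfg$seed`.
#'
#' @param cfg A [truth_config()].
#' @return A `simulated_study`: list with `exposure`, `mediators` (named
#'   list), `outcome` (all `summary_table`s), `truth` (the config plus
#'   per-SNP role/true-effect bookkeeping), `ld` (instrument-block LD
#'   matrix, or `NULL` when blocks are disabled), and `derived` (theta and
#'   the exact mediation table).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  .with_seed(cfg$seed, .simulate_study_impl(cfg))
}

.simulate_study_impl <- function(cfg) {
  n_med <- length(cfg$alpha)
  theta <- truth_theta(cfg)
  bs <- cfg$ld_block_size
  r_block <- sqrt(cfg$ld_block_r2)

  # --- SNP universe layout -------------------------------------------------
  n_inst_all <- cfg$n_instruments * bs
  roles <- c(rep("instrument", n_inst_all),
             if (n_med > 0) rep(sprintf("qtl:%s", names(cfg$alpha)),
                                each = cfg$n_qtl),
             rep("reverse", cfg$n_rev))
  roles <- c(roles, rep("null", cfg$n_snps - length(roles)))
  n <- cfg$n_snps
  snp <- sprintf("snp%04d", seq_len(n))
  chr <- as.character(((seq_len(n) - 1) %% 22) + 1)
  pos <- 1e6 + ((seq_len(n) - 1) %/% 22) * 5e7
  # proxies sit next to their lead on the same chromosome
  lead_of <- rep(NA_integer_, n)
  if (bs > 1) {
    idx <- seq_len(n_inst_all)
    lead <- ((idx - 1) %/% bs) * bs + 1
    lead_of[idx] <- lead
    chr[idx] <- chr[lead]
    pos[idx] <- pos[lead] + (idx - lead) * 1000
  }

  f <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
  ea <- sample(.bases, n, replace = TRUE)
  oa <- vapply(ea, function(a) {
    sample(setdiff(.bases, c(a, .complement(a))), 1)
  }, character(1))

  # --- true marginal effects ----------------------------------------------
  x_true <- numeric(n)      # SNP -> exposure
  inst_idx <- which(roles == "instrument")
  if (bs == 1) {
    x_true[inst_idx] <- cfg$gamma
  } else {
    lead_gamma <- rep(cfg$gamma, each = bs)
    atten <- rep(c(1, rep(r_block, bs - 1)), cfg$n_instruments)
    x_true[inst_idx] <- lead_gamma * atten
  }
  rev_idx <- which(roles == "reverse")
  x_true[rev_idx] <- cfg$theta_rev * cfg$gamma_rev

  m_true <- matrix(0, n, n_med)   # SNP -> mediator_k
  if (n_med > 0) {
    colnames(m_true) <- names(cfg$alpha)
    for (k in seq_len(n_med)) {
      m_true[, k] <- cfg$alpha[k] * x_true
      qtl_idx <- which(roles == sprintf("qtl:%s", names(cfg$alpha)[k]))
      m_true[qtl_idx, k] <- m_true[qtl_idx, k] + cfg$delta_qtl
    }
  }

  y_true <- theta * x_true
  if (n_med > 0) {
    # QTL -> outcome only through its mediator
    for (k in seq_len(n_med)) {
      qtl_idx <- which(roles == sprintf("qtl:%s", names(cfg$alpha)[k]))
      y_true[qtl_idx] <- y_true[qtl_idx] +
        cfg$b[k] * (m_true[qtl_idx, k] - cfg$alpha[k] * x_true[qtl_idx])
    }
  }
  y_true[rev_idx] <- cfg$gamma_rev   # reverse path dominates

  pleio <- numeric(n)
  if (cfg$pleio_mode != "none" && length(inst_idx) > 0) {
    mu <- if (cfg$pleio_mode == "directional") cfg$pleio_mean else 0
    pleio[inst_idx] <- stats::rnorm(length(inst_idx), mu, cfg$pleio_sd)
  }
  y_true <- y_true + pleio

  se_y_all <- .marginal_se(cfg$n_y, f)
  outlier_idx <- integer(0)
  if (cfg$n_outlier > 0) {
    lead_positions <- if (bs == 1) inst_idx else inst_idx[seq(1, n_inst_all, by = bs)]
    outlier_idx <- lead_positions[seq_len(cfg$n_outlier)]
    y_true[outlier_idx] <- y_true[outlier_idx] +
      cfg$outlier_mult * se_y_all[outlier_idx]
  }

  # --- observation layer ---------------------------------------------------
  base <- data.frame(snp = snp, chr = chr, pos = as.integer(pos),
                     ea = ea, oa = oa, stringsAsFactors = FALSE)
  observe <- function(true_beta, n_study, trait, swap = TRUE) {
    se <- .marginal_se(n_study, f)
    beta <- stats::rnorm(n, true_beta, se)
    eaf <- if (cfg$eaf_noise) {
      stats::rbinom(n, 2L * as.integer(min(n_study, 5e5)), f) /
        (2 * as.integer(min(n_study, 5e5)))
    } else f
    df <- base
    df$eaf <- eaf
    df$beta <- beta
    df$se <- se
    df$pval <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300)
    df$n <- as.integer(n_study)
    if (swap && cfg$swap_prob > 0) {
      flip <- stats::runif(n) < cfg$swap_prob
      tmp <- df$ea[flip]
      df$ea[flip] <- df$oa[flip]
      df$oa[flip] <- tmp
      df$beta[flip] <- -df$beta[flip]
      df$eaf[flip] <- 1 - df$eaf[flip]
    }
    summary_table(df, trait_id = trait)
  }

  exposure <- observe(x_true, cfg$n_x, "exposure", swap = FALSE)
  mediators <- list()
  if (n_med > 0) {
    mediators <- lapply(seq_len(n_med), function(k) {
      observe(m_true[, k], cfg$n_m, names(cfg$alpha)[k])
    })
    names(mediators) <- names(cfg$alpha)
  }
  outcome <- observe(y_true, cfg$n_y, "outcome")

  ld <- NULL
  if (bs > 1) {
    ids <- snp[inst_idx]
    ld <- diag(length(ids))
    dimnames(ld) <- list(ids, ids)
    for (i in seq_along(inst_idx)) {
      for (j in seq_along(inst_idx)) {
        if (i != j && lead_of[inst_idx[i]] == lead_of[inst_idx[j]]) {
          ld[i, j] <- r_block
        }
      }
    }
  }

  truth <- cfg
  truth$snp_roles <- stats::setNames(roles, snp)
  truth$true_effects <- data.frame(
    snp = snp, exposure = x_true, outcome = y_true,
    stringsAsFactors = FALSE)
  if (n_med > 0) truth$true_effects <- cbind(truth$true_effects, m_true)
  truth$instrument_ids <- snp[inst_idx]
  truth$reverse_ids <- snp[rev_idx]
  truth$outlier_ids <- snp[outlier_idx]
  truth$confounder_ids <- character(0)

  study <- list(exposure = exposure, mediators = mediators,
                outcome = outcome, truth = truth, ld = ld,
                derived = list(theta = theta,
                               mediation = .truth_mediation(cfg)))
  class(study) <- "simulated_study"
  study
}

.truth_mediation <- function(cfg) {
  theta <- truth_theta(cfg)
  n_med <- length(cfg$alpha)
  if (n_med == 0) {
    return(data.frame(mediator = character(0), a = numeric(0),
                      b = numeric(0), ab = numeric(0),
                      proportion = numeric(0), proportion_defined = logical(0),
                      stringsAsFactors = FALSE))
  }
  ab <- cfg$alpha * cfg$b
  defined <- theta != 0
  data.frame(mediator = names(cfg$alpha), a = unname(cfg$alpha),
             b = unname(cfg$b), ab = unname(ab),
             proportion = if (defined) unname(ab / theta) else NA_real_,
             proportion_defined = defined,
             stringsAsFactors = FALSE)
}

#' Exact mediation table implied by a study's ground truth
#'
#' Pure arithmetic on the true structural parameters: per mediator, the
#' step-1 effect a, step-2 effect b, mediation effect `a*b`, and mediation
#' proportion `a*b / theta`. When the total effect is exactly zero the
#' proportion is undefined and flagged.
#'
#' @param study A `simulated_study`.
#' @return Data frame with columns `mediator`, `a`, `b`, `ab`, `proportion`,
#'   `proportion_defined`.
#' @export
truth_mediation_table <- function(study) {
  stopifnot(inherits(study, "simulated_study"))
  study$derived$mediation
}

#' Plant confounder-linked instruments and return the matching blocklist
#'
#' Gives `k` lead instruments an extra direct outcome effect (the signature
#' of a confounder-associated variant that a PhenoScanner-style lookup would
#' catch) and returns their ids as the ground-truth blocklist.
#'
#' @param study A `simulated_study`.
#' @param k Number of instruments to contaminate.
#' @param effect Extra outcome effect added to each (per-allele, SD scale).
#' @return List with elements `study` (modified) and `blocklist` (ids).
#' @export
plant_confounder_snps <- function(study, k, effect = 0.01) {
  stopifnot(inherits(study, "simulated_study"),
            k >= 0, k <= study$truth$n_instruments)
  if (k == 0) return(list(study = study, blocklist = character(0)))
  bs <- study$truth$ld_block_size
  leads <- study$truth$instrument_ids
  if (bs > 1) leads <- leads[seq(1, length(leads), by = bs)]
  ids <- leads[seq_len(k)]
  out <- study$outcome
  i <- match(ids, out$snp)
  out$beta[i] <- out$beta[i] + effect
  out$pval[i] <- pmax(2 * stats::pnorm(-abs(out$beta[i] / out$se[i])), 1e-300)
  study$outcome <- summary_table(as.data.frame(out), trait_id = trait_id(out))
  j <- match(ids, study$truth$true_effects$snp)
  study$truth$true_effects$outcome[j] <-
    study$truth$true_effects$outcome[j] + effect
  study$truth$confounder_ids <- ids
  list(study = study, blocklist = ids)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated mediation-MR study: ", x$truth$n_snps, " SNPs, ",
      x$truth$n_instruments, " instruments, ", length(x$mediators),
      " mediator(s); theta = ", format(x$derived$theta), "\n", sep = "")
  invisible(x)
}

#' Write all tables of a simulated study to a directory
#'
#' @param study A `simulated_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary(study$exposure, file.path(dir, "exposure.tsv"))
  write_summary(study$outcome, file.path(dir, "outcome.tsv"))
  if (length(study$mediators) > 0) {
    dir.create(file.path(dir, "mediators"), showWarnings = FALSE)
    for (nm in names(study$mediators)) {
      write_summary(study$mediators[[nm]],
                    file.path(dir, "mediators", paste0(nm, ".tsv")))
    }
  }
  invisible(dir)
}
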