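.complement <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

.is_palindromic <- function(ea, oa) .complement(ea) == oa

# deterministic ordering used by every greedy step: p-value, then id
.order_by_p <- function(pval, snp) order(pval, snp)

#' Keep SNPs below a significance threshold
#'
#' @param table A `summary_table`.
#' @param threshold P-value threshold; rows with `pval < threshold`
#'   (strictly) are kept. Conventional tiers are `5e-8` (genome-wide) and
#'   `1e-5` (suggestive).
#' @return Filtered `summary_table`.
#' @export
select_by_pvalue <- function(table, threshold = 5e-8) {
  stopifnot(inherits(table, "summary_table"),
            threshold > 0, threshold < 1)
  .subset_summary(table, table$pval < threshold)
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining SNP with the smallest p-value (ties broken
#' by id) and removes every SNP with `r^2 > r2_max` within `window_bp` of it
#' on the same chromosome. SNPs absent from the LD matrix are treated as
#' independent.
#'
#' @param table A `summary_table`.
#' @param ld Symmetric correlation matrix with SNP ids as dimnames (entries
#'   are r, not r^2), or `NULL` for no LD information.
#' @param r2_max Maximum allowed squared correlation between kept SNPs.
#' @param window_bp Clumping window in base pairs.
#' @return Clumped `summary_table`.
#' @export
ld_clump <- function(table, ld = NULL, r2_max = 0.001, window_bp = 1e7) {
  stopifnot(inherits(table, "summary_table"))
  if (nrow(table) <= 1) return(table)
  df <- as.data.frame(table)
  ord <- .order_by_p(df$pval, df$snp)
  df <- df[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(df))
  kept <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    near <- alive & df$chr == df$chr[i] & abs(df$pos - df$pos[i]) <= window_bp
    if (!any(near)) next
    idx <- which(near)
    if (is.null(ld)) {
      r2 <- rep(0, length(idx))
    } else {
      r2 <- vapply(idx, function(j) {
        a <- df$snp[i]; b <- df$snp[j]
        if (a %in% rownames(ld) && b %in% colnames(ld)) ld[a, b]^2 else 0
      }, numeric(1))
    }
    alive[idx[r2 > r2_max]] <- FALSE
  }
  kept_ids <- df$snp[kept]
  .subset_summary(table, table$snp %in% kept_ids)
}

#' Harmonize two summary tables onto a shared effect allele
#'
#' Aligns the second study's effects to the exposure study's effect allele
#' for every shared SNP. Allele pairs that match directly are kept; pairs
#' that match after swapping effect/other alleles have the second study's
#' beta negated and EAF complemented; pairs that match only after strand
#' complementing are complemented first and then treated the same way;
#' irreconcilable pairs are dropped. Palindromic SNPs (A/T or C/G) cannot be
#' resolved from alleles alone: by default they are dropped outright; in
#' `"rescue"` mode they are kept when both studies' EAFs fall outside the
#' ambiguity band, with the allele frequencies deciding the orientation
#' (same side of 0.5 in both studies: unflipped; opposite sides: flipped).
#'
#' @param exposure,other `summary_table`s for the exposure and the second
#'   trait (outcome or mediator).
#' @param palindrome `"drop"` (default) or `"rescue"`.
#' @param palindrome_eaf_band EAF interval within which a palindromic SNP is
#'   considered ambiguous even in rescue mode.
#' @return A `harmonized_set`: data frame with per-SNP exposure effects
#'   (`gamma`, `se_gamma`, `p_gamma`), aligned second-study effects
#'   (`Gamma`, `se_Gamma`, `p_Gamma`), frequencies, sample sizes and
#'   provenance flags (`flipped`, `palindromic_kept`). Attribute `dropped`
#'   records excluded ids and reasons.
#' @export
harmonize <- function(exposure, other, palindrome = c("drop", "rescue"),
                      palindrome_eaf_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "summary_table"),
            inherits(other, "summary_table"))
  palindrome <- match.arg(palindrome)
  shared <- intersect(exposure$snp, other$snp)
  if (length(shared) == 0) {
    stop("no shared SNPs between '", trait_id(exposure), "' and '",
         trait_id(other), "'")
  }
  e <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  o <- as.data.frame(other)[match(shared, other$snp), ]

  n <- length(shared)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flipped <- rep(FALSE, n)
  pal_kept <- rep(FALSE, n)
  o_beta <- o$beta
  o_eaf <- o$eaf

  for (i in seq_len(n)) {
    pal_e <- .is_palindromic(e$ea[i], e$oa[i])
    if (pal_e) {
      # allele codes cannot orient a palindrome; frequencies must
      pair_ok <- (o$ea[i] %in% c(e$ea[i], e$oa[i])) &&
        (o$oa[i] %in% c(e$ea[i], e$oa[i])) && o$ea[i] != o$oa[i]
      if (!pair_ok) {
        keep[i] <- FALSE; reason[i] <- "incompatible_alleles"; next
      }
      if (palindrome == "drop") {
        keep[i] <- FALSE; reason[i] <- "palindromic"; next
      }
      band <- palindrome_eaf_band
      ambiguous <- function(f) {
        is.na(f) || (f > band[1] && f < band[2])
      }
      if (ambiguous(e$eaf[i]) || ambiguous(o$eaf[i])) {
        keep[i] <- FALSE; reason[i] <- "palindromic_ambiguous"; next
      }
      same_side <- (e$eaf[i] < 0.5) == (o$eaf[i] < 0.5)
      if (!same_side) {
        o_beta[i] <- -o_beta[i]
        o_eaf[i] <- 1 - o_eaf[i]
        flipped[i] <- TRUE
      }
      pal_kept[i] <- TRUE
      next
    }
    oe <- o$ea[i]; oo <- o$oa[i]
    if (oe == e$ea[i] && oo == e$oa[i]) {
      next
    } else if (oe == e$oa[i] && oo == e$ea[i]) {
      o_beta[i] <- -o_beta[i]
      if (!is.na(o_eaf[i])) o_eaf[i] <- 1 - o_eaf[i]
      flipped[i] <- TRUE
    } else {
      ce <- unname(.complement(oe)); co <- unname(.complement(oo))
      if (ce == e$ea[i] && co == e$oa[i]) {
        # strand complement, same orientation
      } else if (ce == e$oa[i] && co == e$ea[i]) {
        o_beta[i] <- -o_beta[i]
        if (!is.na(o_eaf[i])) o_eaf[i] <- 1 - o_eaf[i]
        flipped[i] <- TRUE
      } else {
        keep[i] <- FALSE; reason[i] <- "incompatible_alleles"
      }
    }
  }

  set <- data.frame(
    snp = shared, chr = e$chr, pos = e$pos, ea = e$ea, oa = e$oa,
    gamma = e$beta, se_gamma = e$se, p_gamma = e$pval,
    eaf_exposure = e$eaf, n_exposure = e$n,
    Gamma = o_beta, se_Gamma = o$se, p_Gamma = o$pval,
    eaf_outcome = o_eaf, n_outcome = o$n,
    flipped = flipped, palindromic_kept = pal_kept,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(set) <- NULL
  structure(set,
            exposure_id = trait_id(exposure), outcome_id = trait_id(other),
            dropped = data.frame(snp = shared[!keep],
                                 reason = reason[!keep],
                                 stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}

.empty_harmonized <- function(exposure_id = "exposure",
                              outcome_id = "outcome") {
  df <- data.frame(
    snp = character(0), chr = character(0), pos = integer(0),
    ea = character(0), oa = character(0),
    gamma = numeric(0), se_gamma = numeric(0), p_gamma = numeric(0),
    eaf_exposure = numeric(0), n_exposure = integer(0),
    Gamma = numeric(0), se_Gamma = numeric(0), p_Gamma = numeric(0),
    eaf_outcome = numeric(0), n_outcome = integer(0),
    flipped = logical(0), palindromic_kept = logical(0),
    stringsAsFactors = FALSE)
  .as_harmonized(df, exposure_id, outcome_id)
}

.as_harmonized <- function(df, exposure_id = "exposure",
                           outcome_id = "outcome") {
  structure(df, exposure_id = exposure_id, outcome_id = outcome_id,
            dropped = data.frame(snp = character(0), reason = character(0)),
            class = unique(c("harmonized_set", class(df))))
}

.subset_harmonized <- function(set, keep) {
  out <- as.data.frame(set)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            exposure_id = attr(set, "exposure_id"),
            outcome_id = attr(set, "outcome_id"),
            dropped = attr(set, "dropped"),
            class = c("harmonized_set", "data.frame"))
}

#' Single-SNP instrument-strength F-statistic
#'
#' The usual summary-data approximation `(beta/se)^2`; values below 10
#' conventionally flag weak instruments.
#'
#' @param gamma,se_gamma SNP-exposure effect and its standard error.
#' @return F-statistic (vectorized).
#' @export
f_statistic <- function(gamma, se_gamma) {
  stopifnot(all(se_gamma > 0))
  (gamma / se_gamma)^2
}

#' Remove weak instruments by F-statistic
#'
#' @param set A `harmonized_set`.
#' @param f_min Minimum single-SNP F; SNPs with `F < f_min` are removed.
#' @return List with `set` (filtered) and `excluded` (ids).
#' @export
filter_weak_instruments <- function(set, f_min = 10) {
  f <- f_statistic(set$gamma, set$se_gamma)
  keep <- f >= f_min
  list(set = .subset_harmonized(set, keep), excluded = set$snp[!keep])
}

# variance explained by one SNP from its t-statistic and sample size
.steiger_r2 <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality filter
#'
#' Computes, per SNP, the variance explained in the exposure and in the
#' second trait (`r^2 = t^2 / (t^2 + n - 2)`), and excludes SNPs explaining
#' strictly more variance in the second trait — the signature of a variant
#' whose primary effect runs the wrong way.
#'
#' @param set A `harmonized_set` with sample sizes for both studies.
#' @return List with `set` (filtered) and `excluded` (ids).
#' @export
steiger_filter <- function(set) {
  stopifnot(all(set$n_exposure > 2), all(set$n_outcome > 2))
  r2_exp <- .steiger_r2(set$gamma, set$se_gamma, set$n_exposure)
  r2_out <- .steiger_r2(set$Gamma, set$se_Gamma, set$n_outcome)
  keep <- !(r2_out > r2_exp)
  list(set = .subset_harmonized(set, keep), excluded = set$snp[!keep])
}

#' Remove blocklisted SNPs
#'
#' Stand-in for PhenoScanner-style confounder lookups: SNPs whose ids appear
#' in the blocklist are removed.
#'
#' @param set A `harmonized_set`.
#' @param blocklist Character vector of SNP ids (possibly empty).
#' @return List with `set` (filtered) and `excluded` (ids actually present).
#' @export
apply_blocklist <- function(set, blocklist) {
  keep <- !(set$snp %in% blocklist)
  list(set = .subset_harmonized(set, keep), excluded = set$snp[!keep])
}

#' Bonferroni exclusion of outcome-associated SNPs
#'
#' Excludes instruments whose outcome p-value falls below `alpha / m` —
#' variants plausibly acting on the outcome directly rather than through
#' the exposure.
#'
#' @param set A `harmonized_set`.
#' @param m Bonferroni denominator; defaults to the number of SNPs in the
#'   set.
#' @param alpha Family-wise error target.
#' @return List with `set` (filtered) and `excluded` (ids).
#' @export
bonferroni_outcome_filter <- function(set, m = nrow(set), alpha = 0.05) {
  stopifnot(m >= 1)
  keep <- !(set$p_Gamma < alpha / m)
  list(set = .subset_harmonized(set, keep), excluded = set$snp[!keep])
}

#' Full instrument-selection cascade
#'
#' Runs the selection pipeline in a fixed order: p-value threshold, LD
#' clumping, harmonization, F-statistic filter, MR-PRESSO outlier removal,
#' Steiger directionality filter, blocklist exclusion, and Bonferroni
#' exclusion of outcome-associated SNPs. Stages that need more SNPs than
#' remain (PRESSO needs 4) are skipped with a note in the report.
#'
#' @param exposure,outcome `summary_table`s.
#' @param ld Optional LD matrix for clumping.
#' @param pval_threshold Exposure significance threshold.
#' @param r2_max,window_bp Clumping parameters.
#' @param palindrome,palindrome_eaf_band See [harmonize()].
#' @param f_min Minimum instrument F-statistic.
#' @param presso Run MR-PRESSO outlier removal at selection time?
#' @param presso_n_sim,presso_alpha MR-PRESSO simulation count and outlier
#'   significance level.
#' @param steiger Apply the Steiger directionality filter?
#' @param blocklist Character vector of SNP ids to exclude (or `NULL`).
#' @param bonferroni_m Bonferroni denominator (`NULL`: size of the current
#'   set; `NA`: skip the stage).
#' @param alpha Significance level for the Bonferroni stage.
#' @param seed Seed for the PRESSO null simulations.
#' @return List with `set` (the final `harmonized_set`) and `report` (a
#'   `selection_report` data frame of per-stage counts and excluded ids).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               pval_threshold = 5e-8,
                               r2_max = 0.001, window_bp = 1e7,
                               palindrome = "drop",
                               palindrome_eaf_band = c(0.42, 0.58),
                               f_min = 10,
                               presso = TRUE, presso_n_sim = 1000,
                               presso_alpha = 0.05,
                               steiger = TRUE,
                               blocklist = NULL,
                               bonferroni_m = NULL, alpha = 0.05,
                               seed = 1) {
  stages <- list()
  note <- function(stage, count, excluded = character(0), skipped = FALSE) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_snp = count,
      excluded = paste(excluded, collapse = ";"),
      skipped = skipped, stringsAsFactors = FALSE)
  }
  note("initial", nrow(exposure))

  tab <- select_by_pvalue(exposure, pval_threshold)
  note("pvalue", nrow(tab))

  clumped <- ld_clump(tab, ld = ld, r2_max = r2_max, window_bp = window_bp)
  note("clump", nrow(clumped), setdiff(tab$snp, clumped$snp))

  if (nrow(clumped) == 0 ||
      length(intersect(clumped$snp, outcome$snp)) == 0) {
    set <- .empty_harmonized(trait_id(exposure), trait_id(outcome))
    note("harmonize", 0, clumped$snp)
    for (stage in c("f_statistic", "presso", "steiger", "blocklist",
                    "bonferroni")) {
      note(stage, 0, skipped = TRUE)
    }
    report <- do.call(rbind, stages)
    class(report) <- c("selection_report", "data.frame")
    return(list(set = set, report = report))
  }

  set <- harmonize(clumped, outcome, palindrome = palindrome,
                   palindrome_eaf_band = palindrome_eaf_band)
  note("harmonize", nrow(set), attr(set, "dropped")$snp)

  fw <- filter_weak_instruments(set, f_min = f_min)
  set <- fw$set
  note("f_statistic", nrow(set), fw$excluded)

  if (presso && nrow(set) >= 4) {
    pr <- mr_presso(set, n_sim = presso_n_sim, outlier_alpha = presso_alpha,
                    seed = seed, distortion = FALSE)
    out_ids <- pr$outlier_ids
    set <- .subset_harmonized(set, !(set$snp %in% out_ids))
    note("presso", nrow(set), out_ids)
  } else {
    note("presso", nrow(set), skipped = TRUE)
  }

  if (steiger) {
    st <- steiger_filter(set)
    set <- st$set
    note("steiger", nrow(set), st$excluded)
  } else {
    note("steiger", nrow(set), skipped = TRUE)
  }

  if (!is.null(blocklist)) {
    bl <- apply_blocklist(set, blocklist)
    set <- bl$set
    note("blocklist", nrow(set), bl$excluded)
  } else {
    note("blocklist", nrow(set), skipped = TRUE)
  }

  if (is.null(bonferroni_m) || !is.na(bonferroni_m)) {
    m <- if (is.null(bonferroni_m)) max(nrow(set), 1) else bonferroni_m
    bf <- bonferroni_outcome_filter(set, m = m, alpha = alpha)
    set <- bf$set
    note("bonferroni", nrow(set), bf$excluded)
  } else {
    note("bonferroni", nrow(set), skipped = TRUE)
  }

  report <- do.call(rbind, stages)
  class(report) <- c("selection_report", "data.frame")
  list(set = set, report = report)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized instrument set: ", nrow(x), " SNP(s) [",
      attr(x, "exposure_id"), " -> ", attr(x, "outcome_id"), "]\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}
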