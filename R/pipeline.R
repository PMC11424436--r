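#' Render a publication-style mediation table
#'
#' Formats mediation-screen rows the way mediation-MR reports print them:
#' exponentiated effects ("OR" columns, `exp(beta)` of a linear SD-scale
#' beta) with 95% intervals, per-step p-values, a TRUE/FALSE direction
#' flag, the classification, and the mediation proportion as a percentage
#' with two decimals.
#'
#' @param results Mediation results data frame from [screen_mediators()].
#' @param conf_level Confidence level for the intervals.
#' @return Data frame of formatted strings, one row per mediator.
#' @export
render_mediation_table <- function(results, conf_level = 0.95) {
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  or_ci <- function(beta, se) {
    ifelse(is.na(beta), "NA",
           sprintf("%.3f(%.3f~%.3f)", exp(beta),
                   exp(beta - q * se), exp(beta + q * se)))
  }
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
  data.frame(
    Mediator = results$mediator,
    `X-Y` = or_ci(results$theta, results$se_theta),
    `P_XY` = fmt_p(results$p_theta),
    `X-M` = or_ci(results$a, results$se_a),
    `P_XM` = fmt_p(results$p_a),
    `M-Y` = or_ci(results$b, results$se_b),
    `P_MY` = fmt_p(results$p_b),
    Mediating.direction = ifelse(is.na(results$direction_consistent), "NA",
                                 ifelse(results$direction_consistent,
                                        "TRUE", "FALSE")),
    Mediating.effect = results$classification,
    Mediating.ratio = ifelse(is.na(results$ratio), "NA",
                             sprintf("%.2f%%", 100 * results$ratio)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Run the full mediation-MR pipeline
#'
#' Orchestrates simulate-or-load, instrument selection, the total-effect
#' MR, the two-step mediation screen, optional gene-set enrichment of the
#' partial mediators, and report assembly. All outputs are tab-delimited
#' tables plus a machine-readable `manifest.json`; given the same
#' configuration and seed the run directory is byte-identical.
#'
#' The configuration is a named list (or a YAML file path) with elements:
#' \describe{
#'   \item{simulate}{List of [truth_config()] arguments, or `NULL` when
#'     `inputs` is given.}
#'   \item{inputs}{List of file paths: `exposure`, `outcome`, `mediators`
#'     (a directory of TSVs or a vector of paths), optional `ld`,
#'     `blocklist`, `gmt`.}
#'   \item{selection}{Arguments for [select_instruments()].}
#'   \item{mediation}{Arguments for [screen_mediators()]
#'     (`alpha_step`, `step2_threshold`, `step2_bonferroni_m`, `mtc`).}
#'   \item{enrichment}{List with `gmt` path and `adjust`.}
#'   \item{seed}{Integer seed for every stochastic stage.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  manifest <- list(package = "medmr",
                   version = as.character(utils::packageVersion("medmr")),
                   seed = seed, stages = list())
  stage_done <- function(name, info) {
    manifest$stages[[name]] <<- info
  }

  fail <- function(stage, err) {
    say(stage, paste("ERROR:", conditionMessage(err)))
    stage_done(stage, list(status = "error",
                           message = conditionMessage(err)))
    manifest$status <- "error"
    writeLines(log_lines, log_path)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  # --- load or simulate ----------------------------------------------------
  blocklist <- NULL
  tryCatch({
    if (!is.null(config$simulate)) {
      cfg_args <- config$simulate
      cfg_args$seed <- if (is.null(cfg_args$seed)) seed else cfg_args$seed
      if (!is.null(cfg_args$alpha)) cfg_args$alpha <- unlist(cfg_args$alpha)
      if (!is.null(cfg_args$b)) cfg_args$b <- unlist(cfg_args$b)
      if (!is.null(cfg_args$gamma)) cfg_args$gamma <- unlist(cfg_args$gamma)
      if (!is.null(cfg_args$maf_range))
        cfg_args$maf_range <- unlist(cfg_args$maf_range)
      cfg <- do.call(truth_config, cfg_args)
      study <- simulate_study(cfg)
      exposure <- study$exposure
      outcome <- study$outcome
      mediators <- study$mediators
      ld <- study$ld
      write_study(study, file.path(out_dir, "data"))
      .write_tsv(truth_mediation_table(study),
                 file.path(out_dir, "truth_mediation.tsv"))
      say("data", sprintf("simulated study: %d SNPs, %d mediator(s)",
                          cfg$n_snps, length(mediators)))
      stage_done("data", list(status = "ok", source = "simulated",
                              n_snps = cfg$n_snps,
                              n_mediators = length(mediators),
                              theta_true = truth_theta(cfg)))
    } else {
      inp <- config$inputs
      exposure <- read_summary(inp$exposure, trait_id = "exposure")
      outcome <- read_summary(inp$outcome, trait_id = "outcome")
      med_paths <- inp$mediators
      if (length(med_paths) == 1 && dir.exists(med_paths)) {
        med_paths <- list.files(med_paths, pattern = "\\.tsv$",
                                full.names = TRUE)
      }
      mediators <- lapply(med_paths, read_summary)
      names(mediators) <- vapply(mediators, trait_id, character(1))
      ld <- if (!is.null(inp$ld)) read_ld_matrix(inp$ld) else NULL
      if (!is.null(inp$blocklist)) blocklist <- read_blocklist(inp$blocklist)
      say("data", sprintf("loaded %d mediator table(s)", length(mediators)))
      stage_done("data", list(status = "ok", source = "files",
                              n_mediators = length(mediators)))
    }
  }, error = function(e) fail("data", e))

  sel_args <- if (is.null(config$selection)) list() else config$selection
  sel_args$ld <- ld
  sel_args$blocklist <- blocklist
  sel_args$seed <- seed

  med_args <- if (is.null(config$mediation)) list() else config$mediation

  # --- total effect --------------------------------------------------------
  total <- tryCatch({
    tot <- do.call(total_effect, c(list(exposure, outcome), sel_args))
    .write_tsv(tot$extras$selection_report,
               file.path(out_dir, "selection_report.tsv"))
    .write_tsv(as.data.frame(tot$extras$set),
               file.path(out_dir, "instruments.tsv"))
    est_tab <- data.frame(method = tot$method, beta = tot$beta, se = tot$se,
                          ci_low = tot$ci_low, ci_high = tot$ci_high,
                          pvalue = tot$pvalue, n_snp = tot$n_snp)
    .write_tsv(est_tab, file.path(out_dir, "total_effect.tsv"))
    say("total_effect", sprintf("%s beta = %.4g (p = %.3g), %d SNP(s)",
                                tot$extras$method_choice, tot$beta,
                                tot$pvalue, tot$n_snp))
    stage_done("total_effect",
               list(status = "ok", method = tot$extras$method_choice,
                    beta = tot$beta, se = tot$se, pvalue = tot$pvalue,
                    n_snp = tot$n_snp,
                    thresholds = sel_args[setdiff(names(sel_args),
                                                  c("ld", "blocklist"))]))
    # diagnostics + plot data on the final instrument set
    set <- tot$extras$set
    if (nrow(set) >= 3) {
      ests <- list(ivw_re = mr_ivw(set, "random"),
                   ivw_fe = mr_ivw(set, "fixed"),
                   egger = mr_egger(set),
                   wm = mr_weighted_median(set, seed = seed),
                   raps = mr_raps(set))
      comp <- do.call(rbind, lapply(ests, function(e) {
        data.frame(method = e$method, beta = e$beta, se = e$se,
                   ci_low = e$ci_low, ci_high = e$ci_high,
                   pvalue = e$pvalue, stringsAsFactors = FALSE)
      }))
      .write_tsv(comp, file.path(out_dir, "estimator_comparison.tsv"))
      pd <- export_plot_data(set, ests)
      dir.create(file.path(out_dir, "plotdata"), showWarnings = FALSE)
      for (nm in names(pd)) {
        .write_tsv(pd[[nm]], file.path(out_dir, "plotdata",
                                       paste0(nm, ".tsv")))
      }
      .write_tsv(leave_one_out(set),
                 file.path(out_dir, "leave_one_out.tsv"))
    }
    tot
  }, error = function(e) fail("total_effect", e))

  # --- mediation screen ----------------------------------------------------
  screen <- NULL
  if (length(mediators) > 0) {
    screen <- tryCatch({
      pass <- sel_args[setdiff(names(sel_args),
                               c("seed", "bonferroni_m", "pval_threshold"))]
      if (!is.null(sel_args$pval_threshold) &&
          is.null(med_args$step1_threshold)) {
        med_args$step1_threshold <- sel_args$pval_threshold
      }
      scr <- do.call(screen_mediators,
                     c(list(exposure, mediators, outcome, total = total,
                            seed = seed),
                       med_args, pass))
      .write_tsv(scr$results, file.path(out_dir, "mediation.tsv"))
      .write_tsv(render_mediation_table(scr$results),
                 file.path(out_dir, "mediation_rendered.tsv"))
      n_partial <- sum(scr$results$classification == "partial")
      say("mediation", sprintf("%d/%d mediator(s) classified partial",
                               n_partial, nrow(scr$results)))
      stage_done("mediation", list(status = "ok",
                                   n_mediators = nrow(scr$results),
                                   n_partial = n_partial,
                                   parameters = med_args))
      scr
    }, error = function(e) fail("mediation", e))
  } else {
    .write_tsv(data.frame(mediator = character(0)),
               file.path(out_dir, "mediation.tsv"))
    say("mediation", "no mediators configured; empty table written")
    stage_done("mediation", list(status = "ok", n_mediators = 0,
                                 n_partial = 0))
  }

  # --- enrichment ----------------------------------------------------------
  gmt_path <- config$enrichment$gmt
  if (!is.null(gmt_path) && !is.null(screen)) {
    tryCatch({
      sets <- read_gmt(gmt_path)
      partial <- screen$results$mediator[
        screen$results$classification == "partial"]
      universe <- screen$results$mediator
      adj <- config$enrichment$adjust
      enr <- hypergeom_enrich(partial, sets, universe,
                              adjust = if (is.null(adj)) "BH" else adj)
      .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      say("enrichment", sprintf("%d set(s) tested against %d-symbol universe",
                                nrow(enr), length(universe)))
      stage_done("enrichment", list(status = "ok", n_sets = nrow(enr),
                                    n_query = length(partial),
                                    n_universe = length(universe)))
    }, error = function(e) fail("enrichment", e))
  } else {
    stage_done("enrichment", list(status = "skipped"))
  }

  manifest$status <- "ok"
  writeLines(log_lines, log_path)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
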