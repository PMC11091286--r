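#' Study configuration for the full MR + mediation pipeline
#'
#' Bundles input locations (or a simulation block), selection
#' thresholds, estimator settings and the master seed for a complete
#' bidirectional MR study with optional mediation screening.
#'
#' @param exposure,outcome either file paths (read with `dialect`) or
#'   summary-statistic data frames; alternatively supply `simulate`, a
#'   [sim_config()], and both are generated.
#' @param mediators optional named list of mediator summary statistics
#'   (paths or data frames).
#' @param dialect dialect for file inputs.
#' @param p_threshold,clump,ld_path,blocklist_path,f_formula,f_min,n_exposure
#'   instrument-selection settings; `ld_path`/`blocklist_path` are read
#'   with [read_ld_table()] / [read_blocklist()].
#' @param ivw_model,n_boot,presso_n_sim estimator settings.
#' @param palindrome_eaf_limit harmonization setting.
#' @param run_reverse run the reverse-direction analysis.
#' @param seed master seed; all stage seeds derive from it via
#'   [split_seed()].
#' @param exposure_label,outcome_label trait labels used in reports.
#' @param output_dir optional directory; when set, [run_study()] writes
#'   TSV/JSON reports there.
#' @return list of class `study_config`.
#' @export
study_config <- function(exposure = NULL, outcome = NULL, mediators = NULL,
                         simulate = NULL, dialect = "default",
                         p_threshold = 5e-8, clump = clump_spec(),
                         ld_path = NULL, blocklist_path = NULL,
                         f_formula = "ratio", f_min = 10,
                         n_exposure = NULL,
                         ivw_model = "multiplicative_random",
                         n_boot = 1000, presso_n_sim = 1000,
                         palindrome_eaf_limit = 0.42,
                         run_reverse = TRUE, seed,
                         exposure_label = "exposure",
                         outcome_label = "outcome",
                         output_dir = NULL) {
  if (missing(seed)) stop("master seed is mandatory", call. = FALSE)
  if (is.null(simulate) && (is.null(exposure) || is.null(outcome))) {
    stop("supply exposure and outcome inputs, or a simulate block",
         call. = FALSE)
  }
  stopifnot(p_threshold > 0, p_threshold <= 1, f_min >= 0,
            n_boot >= 1, presso_n_sim >= 500)
  structure(
    list(exposure = exposure, outcome = outcome, mediators = mediators,
         simulate = simulate, dialect = dialect,
         p_threshold = p_threshold, clump = clump, ld_path = ld_path,
         blocklist_path = blocklist_path, f_formula = f_formula,
         f_min = f_min, n_exposure = n_exposure, ivw_model = ivw_model,
         n_boot = n_boot, presso_n_sim = presso_n_sim,
         palindrome_eaf_limit = palindrome_eaf_limit,
         run_reverse = run_reverse, seed = as.integer(seed),
         exposure_label = exposure_label, outcome_label = outcome_label,
         output_dir = output_dir),
    class = "study_config"
  )
}

resolve_input <- function(x, dialect) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) read_sumstats(x, dialect)
  else if (is.data.frame(x)) validate_sumstats(x)
  else stop("input must be a file path or data frame", call. = FALSE)
}

#' Run a complete MR study
#'
#' Executes, in order: instrument selection (significance filter, LD
#' clumping, blocklist exclusion, F screening), harmonization, the four
#' univariable estimators, Cochran's Q, the Egger intercept test,
#' MR-PRESSO, leave-one-out, the reverse-direction analysis, and — when
#' mediators are configured — a two-step mediation screen using the
#' forward IVW estimate as the total effect. Stage failures are caught
#' and recorded with the stage name; partial results are preserved.
#' Exit state reflects execution, never significance.
#'
#' @param config a [study_config()].
#' @return list of class `study_report` with elements `forward` (an
#'   `mr_direction_report`), `presso`, `leave_one_out`, `reverse`,
#'   `mediation` (when configured), `errors` (named stage messages),
#'   `config`, `seed` and `version`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  if (!is.null(config$simulate)) {
    sim <- simulate_pair(config$simulate)
    exposure <- sim$exposure; outcome <- sim$outcome
  } else {
    exposure <- resolve_input(config$exposure, config$dialect)
    outcome <- resolve_input(config$outcome, config$dialect)
    sim <- NULL
  }
  ld <- if (!is.null(config$ld_path)) read_ld_table(config$ld_path) else NULL
  blocklist <- if (!is.null(config$blocklist_path)) {
    read_blocklist(config$blocklist_path)
  } else NULL

  forward <- stage("forward", mr_direction(
    exposure, outcome, direction = "forward",
    exposure_label = config$exposure_label,
    outcome_label = config$outcome_label,
    p_threshold = config$p_threshold, spec = config$clump, ld = ld,
    blocklist = blocklist, n = config$n_exposure,
    f_formula = config$f_formula, f_min = config$f_min,
    seed = split_seed(config$seed, 1), n_boot = config$n_boot,
    palindrome_eaf_limit = config$palindrome_eaf_limit))

  presso <- NULL; loo <- NULL
  if (!is.null(forward) && forward$status == "ok") {
    j <- nrow(kept_pairs(forward$set))
    if (j >= 4) {
      presso <- stage("mr_presso", mr_presso(
        forward$set, n_sim = config$presso_n_sim,
        seed = split_seed(config$seed, 3)))
    }
    if (j >= 3) {
      loo <- stage("leave_one_out", leave_one_out(forward$set))
    }
  }

  reverse <- NULL
  if (config$run_reverse) {
    reverse <- stage("reverse", reverse_mr(
      exposure, outcome, p_threshold = config$p_threshold,
      spec = config$clump, ld = ld, blocklist = blocklist,
      f_formula = config$f_formula, f_min = config$f_min,
      seed = split_seed(config$seed, 2), n_boot = config$n_boot,
      palindrome_eaf_limit = config$palindrome_eaf_limit,
      exposure_label = config$exposure_label,
      outcome_label = config$outcome_label))
  }

  mediation <- NULL
  if (!is.null(config$mediators) && length(config$mediators) &&
      !is.null(forward) && forward$status == "ok") {
    med_list <- lapply(config$mediators, resolve_input,
                       dialect = config$dialect)
    te_est <- forward$estimates$ivw
    mediation <- stage("mediation", mediation_screen(
      exposure, med_list, outcome, te = te_est$beta, se_te = te_est$se,
      p_threshold = config$p_threshold, spec = config$clump, ld = ld,
      f_min = config$f_min,
      palindrome_eaf_limit = config$palindrome_eaf_limit))
  }

  report <- structure(
    list(forward = forward, presso = presso, leave_one_out = loo,
         reverse = reverse, mediation = mediation,
         simulation_truth = if (!is.null(sim)) sim$truth else NULL,
         errors = errors, config = config, seed = config$seed,
         version = as.character(utils::packageVersion("mrmediate"))),
    class = "study_report"
  )
  if (!is.null(config$output_dir)) write_study_report(report,
                                                      config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("MR study report (seed", x$seed, ")\n")
  if (!is.null(x$forward)) print(x$forward)
  if (!is.null(x$presso)) print(x$presso)
  if (!is.null(x$reverse)) print(x$reverse)
  if (length(x$errors)) {
    cat("Stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Render the report's principal tables
#'
#' Produces (1) a per-method estimates table with odds-ratio columns,
#' (2) a mediation decomposition table (Exposure, Mediator, Outcome,
#' IE, DE, TE, IE/TE, Pval — plus the SE columns), and (3) the
#' leave-one-out listing. Effects are formatted to 3 decimals, values
#' below 0.001 in scientific notation (e.g. `2.952E-04`).
#'
#' @param report a `study_report`.
#' @return list with `estimates`, `mediation` (or `NULL`),
#'   `leave_one_out` (or `NULL`), each a data frame of formatted
#'   character columns alongside key numeric ones.
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "study_report"))
  est_tab <- NULL
  if (!is.null(report$forward) && report$forward$status == "ok") {
    raw <- estimates_table(report$forward$estimates)
    est_tab <- data.frame(
      method = raw$method, n_snp = raw$n_snp,
      beta = format_effect(raw$beta),
      or = formatC(round(raw$or, 3), format = "f", digits = 3),
      or_ci_low = formatC(round(raw$or_ci_low, 3), format = "f", digits = 3),
      or_ci_high = formatC(round(raw$or_ci_high, 3), format = "f",
                           digits = 3),
      pval = format_pval(raw$pval),
      stringsAsFactors = FALSE
    )
  }
  med_tab <- NULL
  if (!is.null(report$mediation)) {
    s <- report$mediation$screen
    med_tab <- data.frame(
      Exposure = report$config$exposure_label,
      Mediator = s$mediator,
      Outcome = report$config$outcome_label,
      IE = format_effect(s$ie), DE = format_effect(s$de),
      TE = format_effect(s$te),
      `IE/TE` = format_effect(s$prop),
      Pval = format_pval(s$pval_ie),
      pass = s$pass, check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  loo_tab <- NULL
  if (!is.null(report$leave_one_out)) {
    l <- report$leave_one_out
    loo_tab <- data.frame(
      omitted = l$omitted, n_snp = l$n_snp,
      beta = format_effect(l$beta),
      ci = paste0("[", format_effect(l$ci_low), ", ",
                  format_effect(l$ci_high), "]"),
      pval = format_pval(l$pval), influential = l$influential,
      stringsAsFactors = FALSE
    )
  }
  list(estimates = est_tab, mediation = med_tab, leave_one_out = loo_tab)
}

#' Render a mediation decomposition row in the published table style
#'
#' @param result a `mediation_result`.
#' @param exposure,mediator,outcome display labels (defaults from the
#'   result's own labels).
#' @return one-row data frame with columns Exposure, Mediator, Outcome,
#'   IE, DE, TE, IE/TE, Pval (formatted strings).
#' @export
mediation_row <- function(result, exposure = NULL, mediator = NULL,
                          outcome = NULL) {
  stopifnot(inherits(result, "mediation_result"))
  lab <- result$labels
  data.frame(
    Exposure = exposure %||% lab[["exposure"]] %||% "exposure",
    Mediator = mediator %||% lab[["mediator"]] %||% "mediator",
    Outcome = outcome %||% lab[["outcome"]] %||% "outcome",
    IE = format_effect(result$ie), DE = format_effect(result$de),
    TE = format_effect(result$te), `IE/TE` = format_effect(result$prop),
    Pval = format_pval(result$pval_ie),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report to TSV and JSON files
#'
#' Emits `estimates.tsv`, `harmonized.tsv`, `leave_one_out.tsv`,
#' `mediation.tsv` (as available) and `report.json` (full numeric
#' results, provenance counts, seeds and version) under `dir`.
#'
#' @param report a `study_report`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- report_tables(report)
  if (!is.null(tabs$estimates)) {
    utils::write.table(tabs$estimates, file.path(dir, "estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$forward) && report$forward$status == "ok") {
    write_harmonized(report$forward$set, file.path(dir, "harmonized.tsv"))
  }
  if (!is.null(tabs$leave_one_out)) {
    utils::write.table(tabs$leave_one_out,
                       file.path(dir, "leave_one_out.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tabs$mediation)) {
    utils::write.table(tabs$mediation, file.path(dir, "mediation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  json <- report_to_json(report)
  writeLines(json, file.path(dir, "report.json"))
  invisible(dir)
}

estimate_to_list <- function(e) {
  if (is.null(e)) return(NULL)
  list(method = e$method, beta = e$beta, se = e$se, ci_low = e$ci_low,
       ci_high = e$ci_high, pval = e$pval, n_snp = e$n_snp,
       or = exp(e$beta), or_ci_low = exp(e$ci_low),
       or_ci_high = exp(e$ci_high))
}

report_to_json <- function(report) {
  direction_to_list <- function(d) {
    if (is.null(d)) return(NULL)
    out <- list(direction = d$direction, status = d$status,
                exposure = d$exposure_label, outcome = d$outcome_label,
                selection = d$selection)
    if (d$status == "ok") {
      out$n_snp <- nrow(kept_pairs(d$set))
      out$estimates <- lapply(d$estimates, estimate_to_list)
      if (!is.null(d$heterogeneity)) {
        out$heterogeneity <- unclass(d$heterogeneity)
      }
    }
    out
  }
  payload <- list(
    version = report$version, seed = report$seed,
    forward = direction_to_list(report$forward),
    reverse = direction_to_list(report$reverse),
    presso = if (!is.null(report$presso)) list(
      observed_rss = report$presso$observed_rss,
      global_pval = report$presso$global_pval,
      outliers = report$presso$outliers,
      distortion_pct = report$presso$distortion_pct,
      n_sim = report$presso$n_sim, seed = report$presso$seed
    ) else NULL,
    mediation = if (!is.null(report$mediation))
      report$mediation$screen else NULL,
    errors = report$errors
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
}
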