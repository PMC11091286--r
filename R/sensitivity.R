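#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j (theta_j - beta)^2)` over the Wald ratios at a supplied
#' causal estimate, referred to a chi-square distribution with J - 1
#' degrees of freedom. At the fixed-effect IVW point estimate this is
#' identical to the weighted residual sum of squares of the equivalent
#' through-origin regression. A p-value below 0.05 conventionally flags
#' heterogeneity across instruments.
#'
#' @param set a `harmonized_set` with at least 2 instruments.
#' @param at an `mr_estimate` (or bare numeric) giving the causal effect
#'   at which to evaluate Q; defaults to the fixed-effect IVW estimate.
#' @return list of class `heterogeneity_result`: `q`, `df`, `pval`.
#' @export
cochran_q <- function(set, at = NULL) {
  wr <- wald_ratios(set)
  j <- nrow(wr)
  if (j < 2L) stop("Cochran's Q requires at least 2 instruments",
                   call. = FALSE)
  beta <- if (is.null(at)) {
    sum(wr$weight * wr$theta) / sum(wr$weight)
  } else if (inherits(at, "mr_estimate")) at$beta else as.numeric(at)
  q <- sum(wr$weight * (wr$theta - beta)^2)
  structure(
    list(q = q, df = j - 1L,
         pval = stats::pchisq(q, j - 1, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept, its SE and p-value from [mr_egger()] as a
#' stand-alone diagnostic: an intercept distinguishable from zero
#' indicates directional horizontal pleiotropy.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @return list with `intercept`, `se`, `pval`, `n_snp`.
#' @export
egger_intercept_test <- function(set) {
  e <- mr_egger(set)
  list(intercept = e$extras$intercept, se = e$extras$intercept_se,
       pval = e$extras$intercept_pval, n_snp = e$n_snp)
}

# Leave-one-out fixed-effect IVW slopes for every omitted SNP at once,
# from running totals (weights w = (bx/se_y)^2, so this is the weighted
# through-origin slope).
loo_ivw_beta <- function(bx, by, se_y) {
  w <- (bx / se_y)^2
  th <- by / bx
  (sum(w * th) - w * th) / (sum(w) - w)
}

#' MR-PRESSO global pleiotropy and outlier test
#'
#' Compares the observed residual sum of squares,
#' `RSS = sum_j (outcome_beta_j - beta_ivw(-j) * exposure_beta_j)^2`
#' with `beta_ivw(-j)` the fixed-effect IVW estimate excluding SNP j, to
#' its parametric null distribution: in each of `n_sim` simulations both
#' exposure and outcome effects are redrawn from normal sampling
#' distributions centred on the fitted leave-one-out predictions (the
#' exposure effects on their observed values) and the RSS recomputed.
#' The global p-value uses the add-one Monte-Carlo estimator
#' `(1 + #{sim >= obs}) / (n_sim + 1)`, so it is never exactly zero.
#' Each SNP's own residual term is referred to its simulated
#' distribution the same way, Bonferroni-adjusted by default; SNPs with
#' adjusted p below `outlier_alpha` are flagged, and when any are
#' flagged an IVW estimate with them removed is reported alongside the
#' percent change from the uncorrected estimate.
#'
#' @param set a `harmonized_set` with at least 4 instruments.
#' @param n_sim number of simulations (at least 500; default 1000).
#' @param seed integer seed (mandatory).
#' @param outlier_alpha per-SNP significance level after adjustment.
#' @param adjust multiplicity adjustment for per-SNP p-values, passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @return list of class `presso_result`: `observed_rss`, `global_pval`,
#'   `per_snp` (data frame of raw and adjusted p-values), `outliers`
#'   (rsIDs), `corrected_estimate` (an `mr_estimate`, `NULL` when no
#'   outliers), `distortion_pct`, `n_sim`, `seed`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed, outlier_alpha = 0.05,
                      adjust = "bonferroni") {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_sim < 500) stop("n_sim must be at least 500", call. = FALSE)
  p <- as_pairs(set)
  j <- nrow(p)
  if (j < 4L) stop("insufficient instruments for MR-PRESSO", call. = FALSE)

  bx <- p$exposure_beta; by <- p$outcome_beta
  sx <- p$exposure_se; sy <- p$outcome_se
  beta_loo <- loo_ivw_beta(bx, by, sy)
  obs_terms <- (by - beta_loo * bx)^2
  observed_rss <- sum(obs_terms)

  sims <- with_local_seed(seed, {
    term_exceed <- numeric(j)
    rss_exceed <- 0
    for (s in seq_len(n_sim)) {
      bx_s <- stats::rnorm(j, bx, sx)
      by_s <- stats::rnorm(j, beta_loo * bx, sy)
      bl_s <- loo_ivw_beta(bx_s, by_s, sy)
      terms_s <- (by_s - bl_s * bx_s)^2
      rss_exceed <- rss_exceed + (sum(terms_s) >= observed_rss)
      term_exceed <- term_exceed + (terms_s >= obs_terms)
    }
    list(rss_exceed = rss_exceed, term_exceed = term_exceed)
  })

  global_pval <- (1 + sims$rss_exceed) / (n_sim + 1)
  raw_p <- (1 + sims$term_exceed) / (n_sim + 1)
  adj_p <- stats::p.adjust(raw_p, method = adjust)
  outliers <- p$snp_id[adj_p < outlier_alpha]

  corrected <- NULL
  distortion <- NA_real_
  uncorrected <- mr_ivw(set)
  if (length(outliers)) {
    keep <- !p$snp_id %in% outliers
    sub <- new_harmonized_set(p[keep, , drop = FALSE],
                              exposure_label(set), outcome_label(set))
    corrected <- mr_ivw(sub)
    distortion <- 100 * (corrected$beta - uncorrected$beta) /
      abs(uncorrected$beta)
  }
  structure(
    list(observed_rss = observed_rss, global_pval = global_pval,
         per_snp = data.frame(snp_id = p$snp_id, pval_raw = raw_p,
                              pval_adj = adj_p, stringsAsFactors = FALSE),
         outliers = outliers, corrected_estimate = corrected,
         uncorrected_estimate = uncorrected,
         distortion_pct = distortion, n_sim = n_sim, seed = seed,
         outlier_alpha = outlier_alpha, adjust = adjust),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: observed RSS = %.4g, global p = %.4g (%d sims)\n",
              x$observed_rss, x$global_pval, x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "),
        sprintf("(corrected IVW beta %.4g, %+.1f%% change)\n",
                x$corrected_estimate$beta, x$distortion_pct))
  } else cat("  no outliers detected\n")
  invisible(x)
}

exposure_label <- function(set) {
  if (inherits(set, "harmonized_set")) set$exposure_label else "exposure"
}
outcome_label <- function(set) {
  if (inherits(set, "harmonized_set")) set$outcome_label else "outcome"
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the causal effect with each instrument omitted in turn,
#' plus the all-SNP row. An omission is flagged influential when the
#' re-estimate leaves the full-set 95% CI or flips sign.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param method estimator to re-run: `"ivw"` (default), `"egger"`,
#'   `"weighted_median"`, or `"weighted_mode"`.
#' @param seed integer seed, required for the bootstrap-based methods.
#' @param ... further arguments passed to the estimator.
#' @return data frame of class `loo_table`: columns `omitted` ("none"
#'   for the all-SNP row), `n_snp`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `pval`, `influential`.
#' @export
leave_one_out <- function(set, method = "ivw", seed = NULL, ...) {
  p <- as_pairs(set)
  j <- nrow(p)
  if (j < 3L) stop("leave-one-out requires at least 3 instruments",
                   call. = FALSE)
  fit <- function(pairs, stream) {
    sub <- new_harmonized_set(pairs, exposure_label(set), outcome_label(set))
    switch(method,
           ivw = mr_ivw(sub, ...),
           egger = mr_egger(sub),
           weighted_median = mr_weighted_median(
             sub, seed = split_seed(seed, stream), ...),
           weighted_mode = mr_weighted_mode(
             sub, seed = split_seed(seed, stream), ...),
           stop("unknown method: ", method, call. = FALSE))
  }
  if (method %in% c("weighted_median", "weighted_mode") && is.null(seed)) {
    stop("seed is required for bootstrap-based methods", call. = FALSE)
  }
  full <- fit(p, 0L)
  rows <- lapply(seq_len(j), function(i) {
    e <- fit(p[-i, , drop = FALSE], i)
    data.frame(omitted = p$snp_id[i], n_snp = e$n_snp, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    data.frame(omitted = "none", n_snp = full$n_snp, beta = full$beta,
               se = full$se, ci_low = full$ci_low, ci_high = full$ci_high,
               pval = full$pval, stringsAsFactors = FALSE))))
  out$influential <- out$omitted != "none" &
    (out$beta < full$ci_low | out$beta > full$ci_high |
       sign(out$beta) != sign(full$beta))
  rownames(out) <- NULL
  class(out) <- c("loo_table", class(out))
  out
}

#' Reverse-direction MR analysis
#'
#' Runs the identical selection/harmonization/estimation pipeline with
#' exposure and outcome roles exchanged, to probe reverse causation.
#' When the former outcome has no genome-wide-significant instruments
#' after selection, a structured "no-instruments" result is returned
#' rather than an error.
#'
#' @param exposure_sumstats,outcome_sumstats full summary statistics of
#'   the original exposure and outcome (the reverse analysis selects
#'   instruments from `outcome_sumstats`).
#' @param p_threshold,spec,ld,blocklist,n,f_formula,f_min selection
#'   settings as in [select_instruments()], applied to the new exposure.
#' @param seed master seed for stochastic stages.
#' @param n_boot bootstrap draws.
#' @param palindrome_eaf_limit harmonization setting.
#' @param exposure_label,outcome_label labels of the ORIGINAL roles;
#'   the report swaps them.
#' @return list of class `mr_direction_report` with `direction =
#'   "reverse"`, and either `status = "ok"` plus `set`, `estimates`,
#'   `heterogeneity`, or `status = "no-instruments"`.
#' @export
reverse_mr <- function(exposure_sumstats, outcome_sumstats,
                       p_threshold = 5e-8, spec = clump_spec(), ld = NULL,
                       blocklist = NULL, n = NULL, f_formula = "ratio",
                       f_min = 10, seed = 1L, n_boot = 1000,
                       palindrome_eaf_limit = 0.42,
                       exposure_label = "exposure",
                       outcome_label = "outcome") {
  mr_direction(outcome_sumstats, exposure_sumstats,
               direction = "reverse",
               exposure_label = outcome_label,
               outcome_label = exposure_label,
               p_threshold = p_threshold, spec = spec, ld = ld,
               blocklist = blocklist, n = n, f_formula = f_formula,
               f_min = f_min, seed = seed, n_boot = n_boot,
               palindrome_eaf_limit = palindrome_eaf_limit)
}

# Shared single-direction analysis used by the forward pipeline and
# reverse_mr.
mr_direction <- function(exposure_sumstats, outcome_sumstats, direction,
                         exposure_label, outcome_label,
                         p_threshold = 5e-8, spec = clump_spec(), ld = NULL,
                         blocklist = NULL, n = NULL, f_formula = "ratio",
                         f_min = 10, seed = 1L, n_boot = 1000,
                         palindrome_eaf_limit = 0.42) {
  sel <- select_instruments(exposure_sumstats, p_threshold = p_threshold,
                            spec = spec, ld = ld, blocklist = blocklist,
                            n = n, f_formula = f_formula, f_min = f_min)
  base <- list(direction = direction, exposure_label = exposure_label,
               outcome_label = outcome_label, selection = sel$provenance,
               fstat_report = sel$fstat_report)
  if (nrow(sel$records) == 0L) {
    return(structure(c(base, list(status = "no-instruments")),
                     class = "mr_direction_report"))
  }
  set <- tryCatch(
    harmonize(sel$records, outcome_sumstats,
              palindrome_eaf_limit = palindrome_eaf_limit,
              exposure_label = exposure_label,
              outcome_label = outcome_label),
    error = function(e) NULL
  )
  if (is.null(set) || nrow(kept_pairs(set)) == 0L) {
    return(structure(c(base, list(status = "no-instruments")),
                     class = "mr_direction_report"))
  }
  ests <- mr_all_methods(set, seed = seed, n_boot = n_boot)
  het <- if (nrow(kept_pairs(set)) >= 2) cochran_q(set) else NULL
  structure(c(base, list(status = "ok", set = set, estimates = ests,
                         heterogeneity = het)),
            class = "mr_direction_report")
}

#' @export
print.mr_direction_report <- function(x, ...) {
  cat(sprintf("%s MR: %s -> %s [%s]\n", x$direction, x$exposure_label,
              x$outcome_label, x$status))
  if (x$status == "ok") for (e in x$estimates) print(e)
  invisible(x)
}
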