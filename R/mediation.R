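#' Delta-method (Sobel) standard error of a product of coefficients
#'
#' First-order SE of `beta_a * beta_b`:
#' `sqrt(beta_b^2 se_a^2 + beta_a^2 se_b^2)`. With
#' `second_order = TRUE` the exact-variance term `se_a^2 se_b^2` is
#' added under the square root (off by default; the first-order form is
#' the conventional Sobel SE).
#'
#' @param beta_a,se_a first coefficient and its SE.
#' @param beta_b,se_b second coefficient and its SE.
#' @param second_order include the `se_a^2 se_b^2` term.
#' @return the standard error of the product (non-negative).
#' @export
#' @examples
#' sobel_se(0.5, 0.1, 0.2, 0.05)  # ~0.032016
sobel_se <- function(beta_a, se_a, beta_b, se_b, second_order = FALSE) {
  stopifnot(se_a >= 0, se_b >= 0)
  v <- beta_b^2 * se_a^2 + beta_a^2 * se_b^2
  if (second_order) v <- v + se_a^2 * se_b^2
  sqrt(v)
}

#' Two-step MR effect decomposition
#'
#' Decomposes the total effect of the exposure on the outcome into an
#' indirect effect through a mediator and a direct effect:
#' the indirect effect is the product of coefficients
#' `ie = beta_a * beta_b` (exposure-to-mediator times
#' mediator-to-outcome), the direct effect is `de = te - ie`, and the
#' proportion mediated is `ie / te`. The IE standard error is the
#' delta-method product SE ([sobel_se()]); the proportion's SE treats
#' IE and TE as independent (separate two-sample datasets):
#' `se_prop = sqrt(se_ie^2/te^2 + ie^2 se_te^2 / te^4)`. The IE p-value
#' is two-sided normal on `ie / se_ie`.
#'
#' The identity `ie + de = te` holds to machine precision in every
#' result. When `te = 0` the proportion fields are `NA` and
#' `flags` contains `"undefined-proportion"`; a proportion outside
#' `[0, 1]` sets an `"inconsistent-mediation"` flag but is still
#' reported.
#'
#' @param beta_a,se_a exposure-to-mediator effect and SE.
#' @param beta_b,se_b mediator-to-outcome effect and SE (conditional on
#'   the exposure when estimated by [mvmr_ivw()]).
#' @param te,se_te total effect of exposure on outcome and its SE.
#' @param second_order passed to [sobel_se()].
#' @param labels optional named list/vector (`exposure`, `mediator`,
#'   `outcome`) echoed into the result.
#' @return list of class `mediation_result` with fields `beta_a`,
#'   `se_a`, `beta_b`, `se_b`, `te`, `se_te`, `ie`, `se_ie`, `de`,
#'   `prop`, `se_prop`, `pval_ie`, `flags`, `labels`.
#' @export
two_step <- function(beta_a, se_a, beta_b, se_b, te, se_te,
                     second_order = FALSE, labels = NULL) {
  stopifnot(is.finite(beta_a), is.finite(beta_b), is.finite(te),
            se_a >= 0, se_b >= 0, se_te >= 0)
  ie <- beta_a * beta_b
  de <- te - ie
  se_ie <- sobel_se(beta_a, se_a, beta_b, se_b, second_order = second_order)
  pval_ie <- if (se_ie > 0) pval_from_effect(ie, se_ie) else
    ifelse(ie == 0, 1, 0)
  flags <- character(0)
  if (te == 0) {
    prop <- NA_real_; se_prop <- NA_real_
    flags <- c(flags, "undefined-proportion")
  } else {
    prop <- ie / te
    se_prop <- sqrt(se_ie^2 / te^2 + ie^2 * se_te^2 / te^4)
    if (prop < 0 || prop > 1) flags <- c(flags, "inconsistent-mediation")
  }
  structure(
    list(beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
         te = te, se_te = se_te, ie = ie, se_ie = se_ie, de = de,
         prop = prop, se_prop = se_prop, pval_ie = pval_ie,
         flags = flags, labels = labels),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  lab <- if (!is.null(x$labels)) {
    paste0(x$labels[["exposure"]], " -> ", x$labels[["mediator"]],
           " -> ", x$labels[["outcome"]], ": ")
  } else ""
  cat(sprintf("%sIE = %.4g (SE %.4g, p = %.3g), DE = %.4g, TE = %.4g",
              lab, x$ie, x$se_ie, x$pval_ie, x$de, x$te))
  if (!is.na(x$prop)) cat(sprintf(", IE/TE = %.3f", x$prop))
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Screen candidate mediators by two-step MR
#'
#' For each candidate mediator: step one estimates the
#' exposure-to-mediator effect (`beta_a`) by IVW using the exposure's
#' instruments against the mediator's summary statistics; step two
#' estimates the mediator-to-outcome effect (`beta_b`) using the
#' mediator's own instruments — by default conditional on the exposure
#' through multivariable IVW, or univariable IVW when
#' `step_two = "univariable"`. A mediator passes the screen when
#' `beta_a`, `beta_b` and the indirect effect are all significant at
#' `alpha`. No multiplicity correction is applied across candidates by
#' default; set `adjust` to a [stats::p.adjust()] method to correct the
#' IE p-values.
#'
#' @param exposure_sumstats exposure GWAS summary statistics (full, so
#'   instruments can be selected).
#' @param mediators named list of mediator GWAS summary-statistic data
#'   frames.
#' @param outcome_sumstats outcome GWAS summary statistics.
#' @param te,se_te total effect of exposure on outcome and SE (e.g.
#'   from the forward IVW fit).
#' @param p_threshold,spec,ld,f_min instrument-selection settings used
#'   for both the exposure's and each mediator's instruments.
#' @param step_two `"mvmr"` (default) or `"univariable"`.
#' @param alpha screening significance level (default 0.05).
#' @param adjust optional p.adjust method applied to IE p-values across
#'   candidates (default `"none"`).
#' @param palindrome_eaf_limit harmonization setting.
#' @return list with `results` (named list of `mediation_result`; a
#'   candidate with no usable instruments appears with flag
#'   `"no-instruments"` and `NA` effects) and `screen` (data frame with
#'   per-candidate estimates, p-values and `pass`).
#' @export
mediation_screen <- function(exposure_sumstats, mediators, outcome_sumstats,
                             te, se_te, p_threshold = 5e-8,
                             spec = clump_spec(), ld = NULL, f_min = 10,
                             step_two = c("mvmr", "univariable"),
                             alpha = 0.05, adjust = "none",
                             palindrome_eaf_limit = 0.42) {
  step_two <- match.arg(step_two)
  stopifnot(length(te) == 1, length(se_te) == 1)
  exp_sel <- select_instruments(exposure_sumstats, p_threshold = p_threshold,
                                spec = spec, ld = ld, f_min = f_min)
  if (nrow(exp_sel$records) == 0L) {
    stop("exposure has no instruments after selection", call. = FALSE)
  }
  if (is.null(names(mediators))) {
    names(mediators) <- paste0("mediator_", seq_along(mediators))
  }
  results <- list()
  for (med_name in names(mediators)) {
    med_ss <- mediators[[med_name]]
    res <- tryCatch(
      screen_one_mediator(exp_sel$records, exposure_sumstats, med_ss,
                          med_name, outcome_sumstats, te, se_te,
                          p_threshold, spec, ld, f_min, step_two,
                          palindrome_eaf_limit),
      error = function(e) {
        structure(list(beta_a = NA_real_, se_a = NA_real_,
                       beta_b = NA_real_, se_b = NA_real_,
                       te = te, se_te = se_te, ie = NA_real_,
                       se_ie = NA_real_, de = NA_real_, prop = NA_real_,
                       se_prop = NA_real_, pval_ie = NA_real_,
                       flags = c("no-instruments", conditionMessage(e)),
                       labels = list(mediator = med_name)),
                  class = "mediation_result")
      })
    results[[med_name]] <- res
  }
  pa <- vapply(results, function(r)
    if (is.na(r$beta_a)) NA_real_ else pval_from_effect(r$beta_a, r$se_a),
    numeric(1))
  pb <- vapply(results, function(r)
    if (is.na(r$beta_b)) NA_real_ else pval_from_effect(r$beta_b, r$se_b),
    numeric(1))
  pie <- vapply(results, function(r) r$pval_ie, numeric(1))
  pie_adj <- pie
  ok <- !is.na(pie)
  pie_adj[ok] <- stats::p.adjust(pie[ok], method = adjust)
  screen <- data.frame(
    mediator = names(results),
    beta_a = vapply(results, `[[`, numeric(1), "beta_a"),
    beta_b = vapply(results, `[[`, numeric(1), "beta_b"),
    ie = vapply(results, `[[`, numeric(1), "ie"),
    de = vapply(results, `[[`, numeric(1), "de"),
    te = te,
    prop = vapply(results, `[[`, numeric(1), "prop"),
    pval_a = pa, pval_b = pb, pval_ie = pie, pval_ie_adj = pie_adj,
    no_instruments = vapply(results, function(r)
      "no-instruments" %in% r$flags, logical(1)),
    stringsAsFactors = FALSE
  )
  screen$pass <- !screen$no_instruments &
    !is.na(pa) & pa < alpha & !is.na(pb) & pb < alpha &
    !is.na(pie_adj) & pie_adj < alpha
  rownames(screen) <- NULL
  list(results = results, screen = screen)
}

screen_one_mediator <- function(exp_instruments, exposure_sumstats, med_ss,
                                med_name, outcome_sumstats, te, se_te,
                                p_threshold, spec, ld, f_min, step_two,
                                palindrome_eaf_limit) {
  # Step one: exposure -> mediator on the exposure's instruments.
  set_a <- harmonize(exp_instruments, med_ss,
                     palindrome_eaf_limit = palindrome_eaf_limit,
                     exposure_label = "exposure", outcome_label = med_name)
  if (nrow(kept_pairs(set_a)) == 0L) stop("no step-one instruments")
  est_a <- mr_ivw(set_a)

  # Step two: mediator -> outcome on the mediator's own instruments.
  med_sel <- select_instruments(med_ss, p_threshold = p_threshold,
                                spec = spec, ld = ld, f_min = f_min)
  if (nrow(med_sel$records) == 0L) stop("no step-two instruments")
  set_b <- harmonize(med_sel$records, outcome_sumstats,
                     palindrome_eaf_limit = palindrome_eaf_limit,
                     exposure_label = med_name, outcome_label = "outcome")
  kb <- kept_pairs(set_b)
  if (nrow(kb) == 0L) stop("no step-two instruments after harmonization")

  est_b <- NULL
  if (step_two == "mvmr") {
    # Conditional effect of the mediator given the exposure: attach the
    # exposure's effect at the mediator's instruments, harmonized to
    # the same effect-allele coding as the instrument set (zero-filled
    # when a SNP is absent from the exposure GWAS or unalignable).
    exp_beta <- rep(0, nrow(kb))
    set_e <- tryCatch(
      harmonize(med_sel$records, exposure_sumstats,
                palindrome_eaf_limit = palindrome_eaf_limit),
      error = function(e) NULL)
    if (!is.null(set_e)) {
      ke <- kept_pairs(set_e)
      m <- match(kb$snp_id, ke$snp_id)
      hit <- !is.na(m)
      exp_beta[hit] <- ke$outcome_beta[m[hit]]
    }
    x <- cbind(mediator = kb$exposure_beta, exposure = exp_beta)
    est_b <- tryCatch(
      mvmr_ivw(kb$outcome_beta, kb$outcome_se, x)[[1]],
      error = function(e) NULL  # collinear/degenerate: fall back below
    )
  }
  if (is.null(est_b)) est_b <- mr_ivw(set_b)

  two_step(beta_a = est_a$beta, se_a = est_a$se,
           beta_b = est_b$beta, se_b = est_b$se,
           te = te, se_te = se_te,
           labels = list(exposure = "exposure", mediator = med_name,
                         outcome = "outcome"))
}
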