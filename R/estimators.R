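# 95% interval multiplier fixed across all methods for consistency
CI_Z <- 1.959964

new_mr_estimate <- function(method, beta, se, pval, n_snp, extras = list()) {
  stopifnot(is.finite(beta))
  structure(
    list(method = method, beta = beta, se = se,
         ci_low = beta - CI_Z * se, ci_high = beta + CI_Z * se,
         pval = pval, n_snp = n_snp, extras = extras),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$method, x$n_snp, x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.null(x$extras$intercept)) {
    cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
                x$extras$intercept, x$extras$intercept_se,
                x$extras$intercept_pval))
  }
  invisible(x)
}

#' Per-SNP Wald ratios
#'
#' The Wald ratio for one instrument is the SNP-outcome effect divided
#' by the SNP-exposure effect, with first-order standard error
#' `outcome_se / |exposure_beta|` (exposure-side sampling error is
#' ignored, the usual no-measurement-error approximation) and
#' inverse-variance weight `1 / se_theta^2`.
#'
#' @param set a `harmonized_set` (or its kept-pairs data frame).
#' @return data frame with `snp_id`, `theta`, `se_theta`, `weight`.
#' @export
wald_ratios <- function(set) {
  p <- as_pairs(set)
  if (any(p$exposure_beta == 0)) {
    stop("zero exposure effect for SNP(s): ",
         paste(p$snp_id[p$exposure_beta == 0], collapse = ", "),
         call. = FALSE)
  }
  theta <- p$outcome_beta / p$exposure_beta
  se_theta <- p$outcome_se / abs(p$exposure_beta)
  data.frame(snp_id = p$snp_id, theta = theta, se_theta = se_theta,
             weight = 1 / se_theta^2, stringsAsFactors = FALSE)
}

as_pairs <- function(set) {
  if (inherits(set, "harmonized_set")) kept_pairs(set)
  else if (is.data.frame(set)) set
  else stop("expected a harmonized_set or pairs data frame", call. = FALSE)
}

#' Inverse-variance weighted causal estimate
#'
#' Pools per-SNP Wald ratios by their inverse variances:
#' `beta = sum(w theta) / sum(w)` with `w = 1/se_theta^2`. The fixed
#' standard error is `1/sqrt(sum(w))`; under the default multiplicative
#' random-effects model it is inflated by `max(1, sqrt(Q/(J-1)))`, where
#' Q is Cochran's Q at the IVW point estimate, so heterogeneity widens
#' but never narrows the interval. Algebraically this is the weighted
#' through-origin regression of outcome effects on exposure effects with
#' weights `1/outcome_se^2`.
#'
#' @param set a `harmonized_set`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return an `mr_estimate`; `extras$scale` holds the SE inflation
#'   factor and `extras$q`, `extras$q_df`, `extras$q_pval` Cochran's Q.
#' @export
mr_ivw <- function(set, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  wr <- wald_ratios(set)
  j <- nrow(wr)
  if (j == 0L) stop("no instruments", call. = FALSE)
  if (j == 1L && model == "multiplicative_random") {
    warning("single instrument: falling back to fixed-effect IVW",
            call. = FALSE)
    model <- "fixed"
  }
  w <- wr$weight
  beta <- sum(w * wr$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (wr$theta - beta)^2)
  scale <- if (model == "multiplicative_random") {
    max(1, sqrt(q / (j - 1)))
  } else 1
  se <- se_fixed * scale
  pval <- pval_from_effect(beta, se)
  new_mr_estimate("ivw", beta, se, pval, j,
                  extras = list(model = model, scale = scale, q = q,
                                q_df = j - 1,
                                q_pval = if (j >= 2)
                                  stats::pchisq(q, j - 1, lower.tail = FALSE)
                                else NA_real_))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure
#' effects with an intercept, weights `1/outcome_se^2`. Instruments are
#' oriented internally so every exposure effect is positive (the
#' estimator is defined up to this orientation; the caller's data are
#' not modified). The slope is the causal estimate under the InSIDE
#' assumption; a nonzero intercept indicates directional horizontal
#' pleiotropy. Standard errors use a multiplicative random-effects
#' residual scale bounded below by 1, and p-values use the t
#' distribution with J - 2 degrees of freedom.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @return an `mr_estimate` for the slope; `extras` carries
#'   `intercept`, `intercept_se`, `intercept_pval` and `scale`.
#' @export
mr_egger <- function(set) {
  p <- as_pairs(set)
  j <- nrow(p)
  if (j < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  sgn <- ifelse(p$exposure_beta < 0, -1, 1)
  bx <- sgn * p$exposure_beta
  by <- sgn * p$outcome_beta
  w <- 1 / p$outcome_se^2
  fit <- stats::lm.wfit(x = cbind(intercept = 1, slope = bx), y = by, w = w)
  coefs <- fit$coefficients
  rss <- sum(w * fit$residuals^2)
  sigma2 <- rss / (j - 2)
  scale2 <- max(1, sigma2)
  xtx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  ses <- sqrt(scale2 * diag(xtx_inv))
  tvals <- coefs / ses
  pvals <- 2 * stats::pt(-abs(tvals), df = j - 2)
  new_mr_estimate("egger_slope", unname(coefs[2]), unname(ses[2]),
                  unname(pvals[2]), j,
                  extras = list(intercept = unname(coefs[1]),
                                intercept_se = unname(ses[1]),
                                intercept_pval = unname(pvals[1]),
                                scale = sqrt(scale2)))
}

# Weighted-quantile interpolation over ordered Wald ratios: midpoint
# cumulative weights s_j = (cumsum(w) - w/2) / sum(w), with the estimate
# interpolated linearly at s = q.
weighted_quantile_theta <- function(theta, weight, q = 0.5) {
  ord <- order(theta)
  th <- theta[ord]
  w <- weight[ord] / sum(weight)
  s <- cumsum(w) - w / 2
  if (q <= s[1]) return(th[1])
  n <- length(th)
  if (q >= s[n]) return(th[n])
  hi <- which(s >= q)[1]
  lo <- hi - 1
  th[lo] + (th[hi] - th[lo]) * (q - s[lo]) / (s[hi] - s[lo])
}

boot_draws <- function(p, n_boot) {
  j <- nrow(p)
  list(bx = matrix(stats::rnorm(j * n_boot, p$exposure_beta, p$exposure_se),
                   nrow = j),
       by = matrix(stats::rnorm(j * n_boot, p$outcome_beta, p$outcome_se),
                   nrow = j))
}

#' Weighted-median causal estimate
#'
#' Orders the Wald ratios and takes the inverse-variance weighted median
#' by linear interpolation of the midpoint cumulative weight function at
#' 0.5. Consistent when instruments carrying at least half of the total
#' weight are valid. The standard error comes from a parametric
#' bootstrap: exposure and outcome effects are redrawn from their
#' normal sampling distributions, the weighted median recomputed, and
#' the SD over draws taken.
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap draws (default 1000; fewer than 100 warns).
#' @param seed integer seed for the bootstrap (mandatory; there is no
#'   hidden global-RNG default).
#' @return an `mr_estimate`; `extras$n_boot` and `extras$seed` record
#'   the bootstrap settings.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable",
                            call. = FALSE)
  p <- as_pairs(set)
  if (nrow(p) < 3L) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  wr <- wald_ratios(p)
  beta <- weighted_quantile_theta(wr$theta, wr$weight)
  se <- with_local_seed(seed, {
    d <- boot_draws(p, n_boot)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- d$bx[, b]
      th <- d$by[, b] / bx
      wt <- (bx / p$outcome_se)^2
      weighted_quantile_theta(th, wt)
    }, numeric(1))
    stats::sd(est)
  })
  pval <- pval_from_effect(beta, se)
  new_mr_estimate("weighted_median", beta, se, pval, nrow(p),
                  extras = list(n_boot = n_boot, seed = seed))
}

# Modal bandwidth: modified Silverman rule on the Wald ratios,
# h0 = 0.9 * min(sd, mad) * J^(-1/5) (mad with the normal-consistency
# constant). Fixed so a given seed reproduces bit-for-bit.
mode_bandwidth <- function(theta) {
  s <- min(stats::sd(theta), stats::mad(theta))
  if (s == 0) s <- stats::sd(theta)  # mad degenerate, sd may not be
  0.9 * s * length(theta)^(-1 / 5)
}

weighted_kde <- function(x, theta, w_norm, h) {
  vapply(x, function(m) sum(w_norm * stats::dnorm((m - theta) / h)) / h,
         numeric(1))
}

kde_mode <- function(theta, weight, h) {
  w <- weight / sum(weight)
  if (h <= 0 || stats::sd(theta) == 0) return(theta[which.max(w)])
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 2048)
  dens <- weighted_kde(grid, theta, w, h)
  i <- which.max(dens)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(m) weighted_kde(m, theta, w, h),
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-12)
  m <- opt$maximum
  # Newton polish on the density score for full double precision
  for (it in 1:8) {
    z <- (m - theta) / h
    phi <- stats::dnorm(z)
    d1 <- -sum(w * z * phi) / h^2
    d2 <- sum(w * (z^2 - 1) * phi) / h^3
    if (!is.finite(d1) || !is.finite(d2) || d2 == 0) break
    step <- d1 / d2
    m_new <- m - step
    if (!is.finite(m_new) || abs(step) > h) break
    m <- m_new
    if (abs(step) < 1e-14 * max(1, abs(m))) break
  }
  m
}

#' Weighted-mode causal estimate
#'
#' Takes as the causal estimate the maximizer of an inverse-variance
#' weighted Gaussian kernel density over the Wald ratios, so the largest
#' cluster of agreeing instruments determines the answer (consistent
#' under the ZEMPA assumption that the modal group is valid). The
#' bandwidth is `bandwidth_factor` times a modified Silverman
#' rule-of-thumb, `0.9 min(sd, mad) J^(-1/5)`, computed on the ratios.
#' SE by parametric bootstrap as in [mr_weighted_median()].
#'
#' @param set a `harmonized_set` with at least 3 instruments.
#' @param bandwidth_factor positive multiplier on the rule-of-thumb
#'   bandwidth (default 1).
#' @param n_boot bootstrap draws.
#' @param seed integer seed (mandatory).
#' @return an `mr_estimate`; `extras$bandwidth` records the bandwidth
#'   actually used.
#' @export
mr_weighted_mode <- function(set, bandwidth_factor = 1, n_boot = 1000, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (bandwidth_factor <= 0) stop("bandwidth must be positive", call. = FALSE)
  p <- as_pairs(set)
  if (nrow(p) < 3L) {
    stop("weighted mode requires at least 3 instruments", call. = FALSE)
  }
  wr <- wald_ratios(p)
  h <- bandwidth_factor * mode_bandwidth(wr$theta)
  beta <- kde_mode(wr$theta, wr$weight, h)
  se <- with_local_seed(seed, {
    d <- boot_draws(p, n_boot)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- d$bx[, b]
      th <- d$by[, b] / bx
      wt <- (bx / p$outcome_se)^2
      hb <- bandwidth_factor * mode_bandwidth(th)
      kde_mode(th, wt, hb)
    }, numeric(1))
    stats::sd(est)
  })
  pval <- pval_from_effect(beta, se)
  new_mr_estimate("weighted_mode", beta, se, pval, nrow(p),
                  extras = list(bandwidth = h, n_boot = n_boot, seed = seed))
}

#' Multivariable IVW regression
#'
#' Regresses outcome effects on a matrix of exposure effects without an
#' intercept, weights `1/outcome_se^2`, giving each exposure's
#' conditional direct effect given the others. Residual-scale inflation
#' (floored at 1) as in [mr_ivw()]; p-values two-sided normal.
#'
#' @param outcome_beta,outcome_se aligned outcome effects and SEs, one
#'   per SNP.
#' @param exposure_betas numeric matrix, one column per exposure, rows
#'   aligned with `outcome_beta` and harmonized to a common allele.
#' @return a list of `mr_estimate`, one per exposure (column).
#' @export
mvmr_ivw <- function(outcome_beta, outcome_se, exposure_betas) {
  x <- as.matrix(exposure_betas)
  j <- length(outcome_beta)
  k <- ncol(x)
  stopifnot(nrow(x) == j, length(outcome_se) == j)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("exposure_", seq_len(k))
  # An exposure with no effect at any instrument carries no information:
  # it is excluded from the fit (a degenerate estimate is reported for
  # it) rather than making the design singular.
  zero_col <- apply(x, 2, function(v) all(v == 0))
  xf <- x[, !zero_col, drop = FALSE]
  kf <- ncol(xf)
  if (kf == 0L) stop("all exposure columns are zero", call. = FALSE)
  if (j < kf + 1) {
    stop("need at least ", kf + 1, " SNPs for ", kf, " exposures",
         call. = FALSE)
  }
  if (qr(xf)$rank < kf) stop("collinear exposures", call. = FALSE)
  w <- 1 / outcome_se^2
  xw <- xf * sqrt(w)
  yw <- outcome_beta * sqrt(w)
  xtx <- crossprod(xw)
  coefs_f <- drop(solve(xtx, crossprod(xw, yw)))
  resid <- outcome_beta - drop(xf %*% coefs_f)
  sigma2 <- sum(w * resid^2) / (j - kf)
  scale2 <- max(1, sigma2)
  ses_f <- sqrt(scale2 * diag(solve(xtx)))
  fit_idx <- cumsum(!zero_col)
  lapply(seq_len(k), function(i) {
    if (zero_col[i]) {
      e <- new_mr_estimate("mvmr_ivw", 0, Inf, 1, j,
                           extras = list(exposure = nm[i],
                                         degenerate = TRUE,
                                         n_exposures = k))
      return(e)
    }
    ii <- fit_idx[i]
    new_mr_estimate("mvmr_ivw", unname(coefs_f[ii]), unname(ses_f[ii]),
                    pval_from_effect(coefs_f[ii], ses_f[ii]), j,
                    extras = list(exposure = nm[i], scale = sqrt(scale2),
                                  n_exposures = k))
  })
}

#' Convert a log-odds estimate to the odds-ratio scale
#'
#' Exponentiates the point estimate and both 95% interval bounds.
#' Display rounding (half-even, 3 decimals) is applied only by
#' `format = TRUE`; the returned numbers are full precision otherwise.
#'
#' @param est an `mr_estimate` whose beta is a log-odds ratio.
#' @param format if `TRUE`, return 3-decimal character strings.
#' @return named vector `or`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(est, format = FALSE) {
  stopifnot(inherits(est, "mr_estimate"))
  out <- c(or = exp(est$beta), ci_low = exp(est$ci_low),
           ci_high = exp(est$ci_high))
  if (format) {
    vapply(out, function(v) formatC(round(v, 3), format = "f", digits = 3),
           character(1))
  } else out
}

#' Run all univariable estimators on one instrument set
#'
#' Convenience wrapper running IVW, MR-Egger (when J >= 3), weighted
#' median and weighted mode with seeds split deterministically from
#' `seed`.
#'
#' @param set a `harmonized_set`.
#' @param seed master integer seed for the bootstrap stages.
#' @param n_boot bootstrap draws for the median/mode SEs.
#' @param ivw_model IVW variance model.
#' @return named list of `mr_estimate` objects.
#' @export
mr_all_methods <- function(set, seed, n_boot = 1000,
                           ivw_model = "multiplicative_random") {
  j <- nrow(kept_pairs(set))
  out <- list(ivw = mr_ivw(set, model = ivw_model))
  if (j >= 3) {
    out$egger <- mr_egger(set)
    out$weighted_median <- mr_weighted_median(set, n_boot = n_boot,
                                              seed = split_seed(seed, 1))
    out$weighted_mode <- mr_weighted_mode(set, n_boot = n_boot,
                                          seed = split_seed(seed, 2))
  }
  out
}

#' Serialize estimates to a tidy table
#'
#' @param estimates list of `mr_estimate` objects.
#' @param or_scale also include exponentiated columns.
#' @return data frame, one row per method.
#' @export
estimates_table <- function(estimates, or_scale = TRUE) {
  rows <- lapply(estimates, function(e) {
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta,
               se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (or_scale) {
    out$or <- exp(out$beta)
    out$or_ci_low <- exp(out$ci_low)
    out$or_ci_high <- exp(out$ci_high)
  }
  out
}
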